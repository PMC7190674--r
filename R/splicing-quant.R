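# PSI quantification and differential splicing calls from junction counts.
#
# Events are the five canonical alternative-splicing types: SE (exon
# skipping), A5/A3 (alternative 5'/3' splice sites), MX (mutually exclusive
# exons) and IR (intron retention). For every event and sample we observe an
# inclusion junction count I and a skipping count S; PSI is the
# length-normalized inclusion fraction.

AS_TYPES <- c("SE", "A5", "A3", "MX", "IR")

#' Percent spliced in (PSI) from inclusion/skipping counts
#'
#' Computes \eqn{\psi = (I/l_I) / (I/l_I + S/l_S)}, the length-normalized
#' fraction of transcripts supporting the inclusion form. Events with
#' \code{I + S == 0} are not quantifiable in that sample and return \code{NA}.
#'
#' @param inclusion,skipping Non-negative integer count vectors.
#' @param len_inc,len_skip Effective lengths (bp) of the inclusion and
#'   skipping forms. Default 1 (no length normalization), used when no
#'   annotation-derived lengths are available.
#' @return Numeric vector of PSI values in \[0, 1\], \code{NA} where
#'   \code{inclusion + skipping == 0}.
#' @examples
#' compute_psi(10, 10)            # 0.5
#' compute_psi(10, 10, 2, 1)      # 1/3
#' @export
compute_psi <- function(inclusion, skipping, len_inc = 1, len_skip = 1) {
  if (any(inclusion < 0, na.rm = TRUE) || any(skipping < 0, na.rm = TRUE))
    stop_("counts must be non-negative")
  if (any(len_inc < 1) || any(len_skip < 1))
    stop_("effective lengths must be >= 1")
  num <- inclusion / len_inc
  den <- num + skipping / len_skip
  psi <- ifelse(inclusion + skipping > 0, num / den, NA_real_)
  psi
}

# binomial log-likelihood, safe at p in {0,1}
.binom_ll <- function(x, n, p) {
  ll <- numeric(length(x))
  ok1 <- x > 0
  ok0 <- (n - x) > 0
  ll[ok1] <- x[ok1] * log(p[ok1])
  ll[ok0] <- ll[ok0] + (n[ok0] - x[ok0]) * log1p(-p[ok0])
  ll
}

#' Differential splicing test for a table of events
#'
#' For each event, pools inclusion/skipping counts within each group and
#' compares a shared-inclusion-rate binomial model against a two-rate model
#' with a likelihood-ratio test (1 df, chi-squared asymptotics).
#' \eqn{\Delta\psi} is the difference of replicate-mean PSI, group B minus
#' group A (group order = factor level order).
#'
#' @param inclusion,skipping Integer matrices, events x samples.
#' @param groups Factor (or coercible) of length \code{ncol(inclusion)} with
#'   exactly two levels; the first level is group A.
#' @param len_inc,len_skip Effective lengths per event (recycled; default 1).
#' @return A data.frame with one row per event: mean PSI per group
#'   (\code{psi_a}, \code{psi_b}), \code{dpsi}, LR statistic, \code{p},
#'   BH \code{q}, \code{direction} ("up"/"down" in group B), and
#'   \code{quantifiable} (FALSE when some group had no quantifiable
#'   replicate; such events carry NA statistics).
#' @export
differential_splicing <- function(inclusion, skipping, groups,
                                  len_inc = 1, len_skip = 1) {
  inclusion <- as.matrix(inclusion); skipping <- as.matrix(skipping)
  stopifnot(identical(dim(inclusion), dim(skipping)))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop_("`groups` must have exactly two levels")
  if (length(groups) != ncol(inclusion))
    stop_("`groups` length must equal the number of samples")
  a <- groups == levels(groups)[1L]
  b <- !a

  psi <- compute_psi(inclusion, skipping,
                     matrix(len_inc, nrow(inclusion), ncol(inclusion)),
                     matrix(len_skip, nrow(inclusion), ncol(inclusion)))
  psi_a <- rowMeans(psi[, a, drop = FALSE], na.rm = TRUE)
  psi_b <- rowMeans(psi[, b, drop = FALSE], na.rm = TRUE)
  n_q_a <- rowSums(!is.na(psi[, a, drop = FALSE]))
  n_q_b <- rowSums(!is.na(psi[, b, drop = FALSE]))
  quantifiable <- n_q_a >= 1L & n_q_b >= 1L

  ia <- rowSums(inclusion[, a, drop = FALSE]); sa <- rowSums(skipping[, a, drop = FALSE])
  ib <- rowSums(inclusion[, b, drop = FALSE]); sb <- rowSums(skipping[, b, drop = FALSE])
  na_ <- ia + sa; nb <- ib + sb
  p0 <- (ia + ib) / pmax(na_ + nb, 1)
  pa <- ifelse(na_ > 0, ia / na_, 0)
  pb <- ifelse(nb > 0, ib / nb, 0)
  ll0 <- .binom_ll(ia, na_, p0) + .binom_ll(ib, nb, p0)
  ll1 <- .binom_ll(ia, na_, pa) + .binom_ll(ib, nb, pb)
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  stat[!quantifiable] <- NA_real_
  p[!quantifiable] <- NA_real_
  psi_a[!quantifiable] <- NA_real_
  psi_b[!quantifiable] <- NA_real_
  dpsi <- psi_b - psi_a

  res <- data.frame(
    event_id = rownames(inclusion) %||% paste0("event_", seq_len(nrow(inclusion))),
    psi_a = psi_a, psi_b = psi_b, dpsi = dpsi,
    statistic = stat, p = p,
    q = bh_fdr(p),
    direction = ifelse(is.na(dpsi) | dpsi == 0, "none",
                       ifelse(dpsi > 0, "up", "down")),
    quantifiable = quantifiable,
    row.names = NULL, stringsAsFactors = FALSE
  )
  n_skip <- sum(!quantifiable)
  if (n_skip > 0)
    message(n_skip, " event(s) had no quantifiable replicate in a group; skipped")
  res
}

#' Differential splicing test for a single event
#'
#' Convenience wrapper around [differential_splicing()] for one event given
#' per-replicate counts in two groups.
#'
#' @param inc_a,skip_a,inc_b,skip_b Integer count vectors per replicate.
#' @inheritParams differential_splicing
#' @return One-row data.frame as in [differential_splicing()].
#' @export
differential_event <- function(inc_a, skip_a, inc_b, skip_b,
                               len_inc = 1, len_skip = 1) {
  inclusion <- matrix(c(inc_a, inc_b), nrow = 1)
  skipping <- matrix(c(skip_a, skip_b), nrow = 1)
  groups <- factor(rep(c("A", "B"), c(length(inc_a), length(inc_b))))
  differential_splicing(inclusion, skipping, groups, len_inc, len_skip)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_i = \min_{j \ge rank(i)} p_{(j)} m / j},
#' capped at 1. NA p-values propagate to NA q-values and do not count toward
#' the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1)))
    stop_("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially spliced events (DSEs)
#'
#' An event is called significant iff \eqn{|\Delta\psi| >} \code{dpsi_threshold}
#' and \eqn{q <} \code{q_threshold} (the study-wide cutoff
#' \eqn{\Delta PSI > 0.1}, FDR < 0.1).
#'
#' @param results data.frame from [differential_splicing()]; an optional
#'   \code{type} column (one of SE/A5/A3/MX/IR) enables per-type summaries.
#' @param dpsi_threshold,q_threshold Gates applied as strict inequalities.
#' @return \code{results} with a logical \code{called} column, carrying the
#'   thresholds as attributes.
#' @export
call_dse <- function(results, dpsi_threshold = 0.1, q_threshold = 0.1) {
  stopifnot(is.data.frame(results), all(c("dpsi", "q") %in% names(results)))
  results$called <- !is.na(results$dpsi) & !is.na(results$q) &
    abs(results$dpsi) > dpsi_threshold & results$q < q_threshold
  attr(results, "dpsi_threshold") <- dpsi_threshold
  attr(results, "q_threshold") <- q_threshold
  results
}

#' Per-type DSE landscape across comparisons
#'
#' Tabulates called events by AS type for each comparison and reports
#' fold changes of per-type counts against a named reference comparison,
#' mirroring the comparative presentation of splicing-landscape figures.
#'
#' @param comparisons Named list of data.frames from [call_dse()], each with
#'   \code{type} and \code{called} columns (optionally \code{gene_id} for the
#'   gene-collapsed counts).
#' @param reference Name of the reference comparison for fold changes.
#' @return List with \code{counts} (comparison x type matrix of DSE counts,
#'   plus \code{total}), \code{fold_change} (same shape, count ratios vs the
#'   reference; NA where the reference count is 0), and \code{gene_counts}
#'   (number of distinct genes with >= 1 DSE, where gene ids are present).
#' @export
landscape_summary <- function(comparisons, reference = names(comparisons)[1L]) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1L)
  if (is.null(names(comparisons)) || any(names(comparisons) == ""))
    stop_("`comparisons` must be a named list")
  if (!reference %in% names(comparisons))
    stop_(sprintf("reference comparison '%s' absent", reference))
  counts <- t(vapply(comparisons, function(d) {
    stopifnot(all(c("type", "called") %in% names(d)))
    tab <- table(factor(d$type[d$called], levels = AS_TYPES))
    c(as.numeric(tab), total = sum(tab))
  }, numeric(length(AS_TYPES) + 1L)))
  colnames(counts) <- c(AS_TYPES, "total")
  ref <- counts[reference, ]
  fc <- sweep(counts, 2, ref, "/")
  fc[, ref == 0] <- NA_real_
  gene_counts <- vapply(comparisons, function(d) {
    if (!"gene_id" %in% names(d)) return(NA_integer_)
    length(unique(d$gene_id[d$called]))
  }, integer(1))
  list(counts = counts, fold_change = fc, gene_counts = gene_counts,
       reference = reference)
}
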