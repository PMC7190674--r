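# Gene-set overlap and expression-shift statistics: chi-squared enrichment
# of one set in another over an explicit universe (e.g. IR-bearing genes vs
# NMD targets), paired Z-shift tests, and a simple fold-change + Welch-t DEG
# caller for synthetic expression data.

#' Chi-squared overlap of two gene sets over a universe
#'
#' Builds the 2x2 table (in both / A only / B only / neither) over a stated
#' universe and applies Pearson's chi-squared test with 1 df (no Yates
#' correction by default).
#'
#' @param set_a,set_b Character vectors, both subsets of \code{universe}.
#' @param universe Character vector of all eligible genes.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List: \code{table} (2x2), \code{statistic}, \code{p} (two-tailed),
#'   \code{overlap_fraction} (|A and B| / |A|).
#' @export
set_overlap_chi2 <- function(set_a, set_b, universe, correct = FALSE) {
  if (length(universe) == 0L) stop_("empty universe")
  if (anyDuplicated(universe)) stop_("universe ids must be unique")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_("both sets must be subsets of the universe")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, 2,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       overlap_fraction = if (sum(in_a) > 0) sum(in_a & in_b) / sum(in_a) else NA_real_)
}

#' Paired expression-shift test between two conditions
#'
#' Two-tailed paired Student's t-test on per-gene Z-score differences for a
#' gene set measured in two conditions (e.g. genes with retained introns,
#' tumor vs normal). Genes with both up- and downregulated IR events should
#' be removed beforehand with [filter_bidirectional_ir_genes()].
#'
#' @param z1,z2 Named numeric vectors of per-gene Z-scores in the two
#'   conditions; names must match as sets.
#' @param genes Optional gene subset to test (default: all shared genes).
#' @return List: \code{t}, \code{p}, \code{mean_shift} (z2 - z1), \code{n}.
#' @export
paired_shift_test <- function(z1, z2, genes = NULL) {
  if (is.null(names(z1)) || is.null(names(z2))) stop_("vectors must be named by gene")
  if (!setequal(names(z1), names(z2))) stop_("gene sets differ between conditions")
  genes <- genes %||% names(z1)
  if (!all(genes %in% names(z1))) stop_("`genes` not all present")
  if (length(genes) < 3L) stop_("need >= 3 genes for a paired t-test")
  d <- z2[genes] - z1[genes]
  if (stats::sd(d) == 0) {
    # degenerate: all per-gene differences identical
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_stat, p = if (mean(d) == 0) 1 else 0,
                mean_shift = mean(d), n = length(genes)))
  }
  tt <- stats::t.test(z2[genes], z1[genes], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_shift = mean(d),
       n = length(genes))
}

#' Simple differential-expression caller for log2 expression matrices
#'
#' Per gene: log2 fold change (group B minus group A mean), Welch t-test on
#' the log2 values, BH q-values. A gene is called iff |FC| >=
#' \code{fc_threshold} (linear scale) AND q < \code{q_threshold} AND its
#' mean linear-scale expression across all samples is >= \code{min_mean}.
#' This is a deliberately plain caller for synthetic data (the study-style
#' gates: FC >= 1.5 & FDR < 0.1, or FC >= 2 & FDR < 0.05 & baseMean > 10).
#'
#' @param expr_a,expr_b Genes x samples log2 matrices with identical
#'   rownames; >= 2 samples each.
#' @param fc_threshold Linear fold-change gate (default 2).
#' @param q_threshold FDR gate (default 0.05), strict inequality.
#' @param min_mean Minimum mean linear-scale expression (default 10).
#' @return data.frame: gene, log2fc, mean_expr (linear), t, p, q, called.
#' @export
deg_call <- function(expr_a, expr_b, fc_threshold = 2, q_threshold = 0.05,
                     min_mean = 10) {
  expr_a <- as.matrix(expr_a); expr_b <- as.matrix(expr_b)
  if (!identical(rownames(expr_a), rownames(expr_b)))
    stop_("matrices must share rownames (genes)")
  if (ncol(expr_a) < 2L || ncol(expr_b) < 2L)
    stop_("need >= 2 replicates per group")
  log2fc <- rowMeans(expr_b) - rowMeans(expr_a)
  mean_expr <- rowMeans(2^cbind(expr_a, expr_b))
  n1 <- ncol(expr_a); n2 <- ncol(expr_b)
  v1 <- apply(expr_a, 1, stats::var); v2 <- apply(expr_b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  q <- bh_fdr(p)
  data.frame(gene = rownames(expr_a), log2fc = log2fc, mean_expr = mean_expr,
             t = t_stat, p = p, q = q,
             called = abs(log2fc) >= log2(fc_threshold) & q < q_threshold &
               mean_expr >= min_mean,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter genes with bidirectional IR events
#'
#' Keeps genes whose significant intron-retention events are all in one
#' direction; genes with both up- and downregulated IR events are removed.
#'
#' @param ir_events data.frame with columns \code{gene_id} and
#'   \code{direction} ("up"/"down"), one row per significant IR event.
#' @return Character vector of retained gene ids.
#' @export
filter_bidirectional_ir_genes <- function(ir_events) {
  stopifnot(all(c("gene_id", "direction") %in% names(ir_events)))
  dirs <- split(ir_events$direction, ir_events$gene_id)
  names(dirs)[vapply(dirs, function(d) length(unique(d)) == 1L, logical(1))]
}
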