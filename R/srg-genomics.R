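# Genomic-alteration landscape statistics for a catalog of splicing-
# regulatory genes (SRGs): per-gene and cumulative alteration frequencies,
# top-altered rankings, co-occurrence tests, CNV-expression association and
# Gleason-grade association.

ALTERATION_CALLS <- c("amp", "del", "mut", "none")

#' Build an alteration matrix from a flattened call table
#'
#' One call per patient-gene cell. Multiple calls for the same cell (e.g. a
#' cBioPortal-style multi-track export) are collapsed with precedence
#' amp > del > mut.
#'
#' @param calls data.frame with columns \code{patient}, \code{gene},
#'   \code{call} (amp/del/mut; absent pairs are "none").
#' @param patients,genes Optional full id sets (so unaltered patients/genes
#'   appear as all-"none").
#' @return Character matrix patients x genes of calls.
#' @export
alteration_matrix <- function(calls, patients = NULL, genes = NULL) {
  stopifnot(all(c("patient", "gene", "call") %in% names(calls)))
  if (!all(calls$call %in% c("amp", "del", "mut")))
    stop_("calls must be among amp/del/mut")
  patients <- patients %||% sort(unique(calls$patient))
  genes <- genes %||% sort(unique(calls$gene))
  if (anyDuplicated(patients) || anyDuplicated(genes))
    stop_("patient and gene ids must be unique")
  m <- matrix("none", length(patients), length(genes),
              dimnames = list(patients, genes))
  prec <- c(amp = 1L, del = 2L, mut = 3L, none = 4L)
  for (i in seq_len(nrow(calls))) {
    cur <- m[calls$patient[i], calls$gene[i]]
    if (prec[calls$call[i]] < prec[cur])
      m[calls$patient[i], calls$gene[i]] <- calls$call[i]
  }
  m
}

.check_gene <- function(matrix, gene) {
  if (!gene %in% colnames(matrix)) stop_(sprintf("gene '%s' absent", gene))
}

#' Per-gene alteration frequencies
#'
#' @param matrix Alteration matrix (patients x genes).
#' @param gene Gene id.
#' @return Named numeric vector: amp, del, mut, any (fractions of cohort).
#' @export
gene_alteration_freq <- function(matrix, gene) {
  .check_gene(matrix, gene)
  col <- matrix[, gene]
  n <- nrow(matrix)
  c(amp = sum(col == "amp") / n, del = sum(col == "del") / n,
    mut = sum(col == "mut") / n, any = sum(col != "none") / n)
}

#' Cumulative alteration frequency over a gene set
#'
#' Fraction of patients with at least one alteration in any gene of the set
#' (each patient counted once).
#'
#' @param matrix Alteration matrix.
#' @param gene_set Character vector of gene ids.
#' @param types Alteration types counted (default all three).
#' @return Fraction in \[0, 1\]; empty set gives 0 with a warning.
#' @export
cumulative_freq <- function(matrix, gene_set, types = c("amp", "del", "mut")) {
  if (length(gene_set) == 0L) {
    warn_("empty gene set; cumulative frequency is 0")
    return(0)
  }
  for (g in gene_set) .check_gene(matrix, g)
  sub <- matrix[, gene_set, drop = FALSE]
  mean(apply(sub, 1, function(r) any(r %in% types)))
}

#' Top altered genes
#'
#' @param matrix Alteration matrix.
#' @param n Number of genes to return (all if n exceeds the gene count).
#' @param by "amp", "del", "mut" or "any".
#' @return data.frame of gene and frequency, sorted descending; ties broken
#'   by gene name ascending.
#' @export
top_altered <- function(matrix, n = 15L, by = c("any", "amp", "del", "mut")) {
  by <- match.arg(by)
  freqs <- vapply(colnames(matrix), function(g) gene_alteration_freq(matrix, g)[by],
                  numeric(1))
  d <- data.frame(gene = colnames(matrix), freq = unname(freqs),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$freq, d$gene), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, n)
}

#' One-sided Fisher co-occurrence p from 2x2 counts
#'
#' Tests enrichment of co-alteration (hypergeometric upper tail) given the
#' table both / A-only / B-only / neither.
#'
#' @param both,a_only,b_only,neither Non-negative integer cell counts.
#' @return List: \code{p} (one-sided, alternative = co-occurrence),
#'   \code{odds_ratio} (sample OR; \code{Inf}/0 reported for zero cells),
#'   \code{table} (2x2 matrix).
#' @export
fisher_cooccurrence <- function(both, a_only, b_only, neither) {
  tab <- matrix(c(both, a_only, b_only, neither), 2, 2,
                dimnames = list(A = c("alt", "wt"), B = c("alt", "wt")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  or <- if (a_only == 0 || b_only == 0) {
    if (both == 0) NA_real_ else Inf
  } else (both * neither) / (a_only * b_only)
  list(p = ft$p.value, odds_ratio = or, table = tab)
}

#' Co-occurrence of alterations between two genes
#'
#' @param matrix Alteration matrix.
#' @param gene_a,gene_b Gene ids.
#' @param types Alteration types defining "altered" (default all).
#' @return As [fisher_cooccurrence()], plus the gene ids.
#' @export
cooccurrence <- function(matrix, gene_a, gene_b, types = c("amp", "del", "mut")) {
  .check_gene(matrix, gene_a); .check_gene(matrix, gene_b)
  a <- matrix[, gene_a] %in% types
  b <- matrix[, gene_b] %in% types
  res <- fisher_cooccurrence(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  res$genes <- c(gene_a, gene_b)
  res
}

#' Expression by CNV status
#'
#' Compares a gene's expression between amplified vs copy-neutral and
#' deleted vs copy-neutral patients with two-sided Wilcoxon rank-sum tests.
#' Groups with fewer than 3 patients are flagged and return NA.
#'
#' @param expr Genes x patients log2 expression matrix.
#' @param matrix Alteration matrix (patients x genes; patients must match
#'   \code{colnames(expr)}).
#' @param gene Gene id.
#' @return data.frame with one row per comparison (amp, del): n, group
#'   mean, neutral mean, p, flag.
#' @export
expression_by_cnv <- function(expr, matrix, gene) {
  .check_gene(matrix, gene)
  if (!gene %in% rownames(expr)) stop_(sprintf("gene '%s' absent from expression", gene))
  pts <- intersect(colnames(expr), rownames(matrix))
  calls <- matrix[pts, gene]
  x <- expr[gene, pts]
  neutral <- x[calls == "none"]
  one <- function(type) {
    grp <- x[calls == type]
    if (length(grp) < 3L || length(neutral) < 3L)
      return(data.frame(comparison = type, n = length(grp),
                        mean_group = if (length(grp)) mean(grp) else NA_real_,
                        mean_neutral = mean(neutral), p = NA_real_,
                        flag = "group too small", stringsAsFactors = FALSE))
    data.frame(comparison = type, n = length(grp), mean_group = mean(grp),
               mean_neutral = mean(neutral),
               p = stats::wilcox.test(grp, neutral)$p.value, flag = "",
               stringsAsFactors = FALSE)
  }
  rbind(one("amp"), one("del"))
}

#' Gleason-grade association with an alteration group
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of Gleason scores between
#' members and non-members of a patient group (e.g. amplified vs not).
#'
#' @param in_group Logical vector (or patient id vector with
#'   \code{patients}) marking group membership.
#' @param gleason Numeric Gleason scores, aligned with \code{patients}.
#' @param patients Optional patient ids when \code{in_group} is an id vector.
#' @return List: \code{p}, \code{median_in}, \code{median_out}, \code{n}.
#' @export
grade_association <- function(in_group, gleason, patients = NULL) {
  if (!is.logical(in_group)) {
    if (is.null(patients)) stop_("supply `patients` when `in_group` holds ids")
    in_group <- patients %in% in_group
  }
  g_in <- gleason[in_group]; g_out <- gleason[!in_group]
  if (length(g_in) == 0L || length(g_out) == 0L) stop_("one group is empty")
  if (length(g_in) < 3L || length(g_out) < 3L) stop_("each group needs >= 3 patients")
  list(p = stats::wilcox.test(g_in, g_out, exact = FALSE)$p.value,
       median_in = stats::median(g_in), median_out = stats::median(g_out),
       n = c(in_group = length(g_in), out_group = length(g_out)))
}
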