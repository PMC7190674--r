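# Z-score standardization against a reference sample set and composite
# gene-signature scoring: the 20-gene androgen-receptor (AR) activity score
# with +/-7 fractionation, the 13-gene prognostic splicing-gene signatures,
# median splits, and top/bottom-k extreme selection.

#' Default gene signatures
#'
#' \code{ar_target_genes}: 20 experimentally validated androgen-induced AR
#' target genes whose Z-score sum defines the AR activity score.
#' \code{srg_unfavorable_genes} / \code{srg_favorable_genes}: the 13-gene
#' unfavorable and favorable prognostic splicing-regulatory-gene signatures.
#'
#' @format Character vectors of gene symbols.
#' @name default_signatures
NULL

#' @rdname default_signatures
#' @export
ar_target_genes <- c(
  "KLK3", "KLK2", "TMPRSS2", "ELL2", "CENPN", "GNMT", "MAF", "NNMT",
  "MED28", "EAF2", "MPHOSPH9", "PTGER4", "HERC3", "ZBTB10", "ACSL3",
  "FKBP5", "C1orf116", "NKX3-1", "ABCC4", "PMEPA1"
)

#' @rdname default_signatures
#' @export
srg_unfavorable_genes <- c(
  "SRSF1", "KHDRBS3", "ESRP1", "HNRNPH1", "U2SURP", "LSM5", "TIA1",
  "CHERP", "HNRNPR", "HNRNPH2", "HNRNPH3", "HNRNPAB", "KHDRBS1"
)

#' @rdname default_signatures
#' @export
srg_favorable_genes <- c(
  "MFAP1", "SF3A2", "GPATCH1", "XAB2", "CELF2", "SF3A1", "SAP18",
  "SRP54", "PPIL2", "SF1", "MATR3", "ELAVL4", "CDK10"
)

#' Gene signature constructor
#'
#' @param name Signature name.
#' @param genes Unique, non-empty character vector of member genes.
#' @param direction "unfavorable", "favorable" or "neutral".
#' @return Object of class \code{gene_signature}.
#' @export
gene_signature <- function(name, genes,
                           direction = c("neutral", "unfavorable", "favorable")) {
  direction <- match.arg(direction)
  if (length(genes) == 0L) stop_("signature must contain at least one gene")
  if (anyDuplicated(genes)) stop_("signature genes must be unique")
  structure(list(name = name, genes = genes, direction = direction),
            class = "gene_signature")
}

#' Z-score expression against a reference sample set
#'
#' Standardizes each gene as Z = (x - mean_ref) / sd_ref, where the mean and
#' SD come from the designated reference samples (e.g. normal prostate).
#' When \code{reference} is NULL the whole cohort is used (cohort-wide
#' standardization, for cohorts without normal samples). Genes with zero
#' reference SD are excluded with a warning and listed in the
#' \code{excluded} attribute.
#'
#' @param expr Numeric genes x samples matrix, log2 scale.
#' @param reference Column names (or indices) of the reference samples;
#'   >= 3 required when given.
#' @return Z matrix (class \code{zmatrix}) with attributes \code{ref_mean},
#'   \code{ref_sd}, \code{reference}, \code{excluded}.
#' @export
zscore_vs_reference <- function(expr, reference = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop_("`expr` needs gene rownames")
  ref <- if (is.null(reference)) seq_len(ncol(expr)) else reference
  if (!is.null(reference) && length(ref) < 3L)
    stop_("need >= 3 reference samples")
  ref_expr <- expr[, ref, drop = FALSE]
  mu <- rowMeans(ref_expr)
  sdv <- apply(ref_expr, 1, stats::sd)
  excluded <- rownames(expr)[sdv == 0 | is.na(sdv)]
  if (length(excluded))
    warn_(sprintf("%d gene(s) with zero reference variance excluded: %s",
                  length(excluded), paste(utils::head(excluded, 5), collapse = ", ")))
  keep <- !(rownames(expr) %in% excluded)
  z <- (expr[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  structure(z, class = c("zmatrix", "matrix", "array"),
            ref_mean = mu[keep], ref_sd = sdv[keep],
            reference = if (is.null(reference)) "cohort" else reference,
            excluded = excluded)
}

#' Composite signature score per sample
#'
#' The score is the sum of Z-scores over the signature's member genes that
#' are present in the Z matrix (a linear combination with unit weights; the
#' +/-7 AR fractionation cutoff is defined on this sum scale).
#'
#' @param z Z matrix from [zscore_vs_reference()] (genes x samples).
#' @param signature A [gene_signature()] or character vector of genes.
#' @return data.frame: sample, score, n_genes (detected member genes, same
#'   for all samples).
#' @export
composite_score <- function(z, signature) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  present <- intersect(genes, rownames(z))
  if (length(present) == 0L) stop_("no signature genes detected in the Z matrix")
  if (length(present) < length(genes))
    message(length(genes) - length(present), " signature gene(s) not detected; ",
            "scoring over the remaining ", length(present))
  score <- colSums(z[present, , drop = FALSE])
  data.frame(sample = colnames(z) %||% as.character(seq_along(score)),
             score = unname(score), n_genes = length(present),
             stringsAsFactors = FALSE)
}

#' Fractionate samples by AR activity score
#'
#' High = score >= \code{hi}; low = score <= \code{lo}; the rest are
#' unassigned. Inclusive comparison by default (the >=7 / <=-7 rule); set
#' \code{inclusive = FALSE} for strict inequalities.
#'
#' @param scores data.frame from [composite_score()] (or named numeric
#'   vector).
#' @param hi,lo Cutoffs, default +7 and -7.
#' @param inclusive Include scores equal to the cutoff (default TRUE).
#' @return List of sample id vectors: \code{high}, \code{low},
#'   \code{unassigned}.
#' @export
ar_activity_fractionate <- function(scores, hi = 7, lo = -7, inclusive = TRUE) {
  sc <- .as_score_df(scores)
  high <- if (inclusive) sc$score >= hi else sc$score > hi
  low <- if (inclusive) sc$score <= lo else sc$score < lo
  if (!any(high) && !any(low))
    warn_("no samples reach either cutoff; both groups empty")
  list(high = sc$sample[high], low = sc$sample[low],
       unassigned = sc$sample[!high & !low])
}

.as_score_df <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("sample", "score") %in% names(scores)))
    scores
  } else {
    data.frame(sample = names(scores) %||% as.character(seq_along(scores)),
               score = as.numeric(scores), stringsAsFactors = FALSE)
  }
}

#' Median split of signature scores
#'
#' High = score > median, low = score <= median (ties go low).
#'
#' @param scores data.frame from [composite_score()] or named numeric vector.
#' @return List of sample id vectors \code{high} and \code{low}.
#' @export
median_split <- function(scores) {
  sc <- .as_score_df(scores)
  if (nrow(sc) < 4L) stop_("need >= 4 samples for a median split")
  med <- stats::median(sc$score)
  high <- sc$score > med
  if (!any(high)) warn_("all scores equal the median; high group empty")
  list(high = sc$sample[high], low = sc$sample[!high])
}

#' Select top-k and bottom-k samples by signature score
#'
#' @param scores data.frame from [composite_score()] or named numeric vector.
#' @param k Number per extreme (default 20); requires 2k <= n.
#' @return List of sample id vectors \code{top} and \code{bottom}. Ties at
#'   the boundary are broken by sample id ascending.
#' @export
select_extremes <- function(scores, k = 20L) {
  sc <- .as_score_df(scores)
  if (2L * k > nrow(sc)) stop_("2k exceeds the number of samples")
  ord_top <- order(-sc$score, sc$sample)
  ord_bot <- order(sc$score, sc$sample)
  list(top = sc$sample[ord_top[seq_len(k)]],
       bottom = sc$sample[ord_bot[seq_len(k)]])
}
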