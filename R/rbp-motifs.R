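# IUPAC consensus-motif scanning for RNA-binding proteins (RBPs) and the
# binding-score ranking used to shortlist candidate IR regulators.
#
# Scanning is strand-agnostic on the provided sense-strand sequence: RNA
# binding happens on the transcript, so no reverse-complement scan is done.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# motif string -> list of allowed base sets per position (U == T)
.iupac_sets <- function(motif) {
  chars <- strsplit(toupper(gsub("U", "T", motif)), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad))
    stop_(sprintf("invalid IUPAC character(s): %s", paste(unique(bad), collapse = ", ")))
  IUPAC_DNA[chars]
}

#' Count IUPAC motif occurrences in sequences
#'
#' Counts all (overlapping) match start positions of an IUPAC consensus
#' motif in each sequence. Pattern ambiguity codes match the corresponding
#' concrete bases; sequence bases are taken literally. U and T are
#' equivalent on both sides.
#'
#' @param motif IUPAC motif string (length >= 1).
#' @param seqs Character vector of sequences (DNA or RNA alphabet).
#' @return Integer vector of occurrence counts, one per sequence.
#' @export
iupac_match_count <- function(motif, seqs) {
  .iupac_sets(motif)  # validates characters
  if (any(nchar(seqs) == 0L)) stop_("sequences must be non-empty")
  pat <- Biostrings::DNAString(toupper(gsub("U", "T", motif)))
  subj <- Biostrings::DNAStringSet(toupper(gsub("U", "T", seqs)))
  Biostrings::vcountPattern(pat, subj, fixed = c(pattern = FALSE, subject = TRUE))
}

#' RBP motif object
#'
#' @param rbp_name Factor (RBP) name.
#' @param motif IUPAC consensus string, length >= 3.
#' @return Object of class \code{rbp_motif}.
#' @export
rbp_motif <- function(rbp_name, motif) {
  if (nchar(motif) < 3L) stop_("motif length must be >= 3")
  .iupac_sets(motif)
  structure(list(rbp_name = rbp_name, motif = toupper(gsub("U", "T", motif))),
            class = "rbp_motif")
}

#' Binding statistics of one motif over a sequence group
#'
#' Binding frequency f = fraction of sequences with at least one motif
#' occurrence; mean appearance count c = mean occurrence count over the
#' matching sequences (0 when none match); binding score B = f * c.
#'
#' @param motif An [rbp_motif()] or IUPAC string.
#' @param seqs Character vector of sequences (>= 1).
#' @param count_mode "matching" (default; mean count over sequences with
#'   >= 1 hit) or "all" (mean over all sequences).
#' @return One-row data.frame: rbp, f, c_bar, B, n_seqs.
#' @export
motif_group_stats <- function(motif, seqs, count_mode = c("matching", "all")) {
  count_mode <- match.arg(count_mode)
  if (length(seqs) == 0L) stop_("empty sequence group")
  m <- if (inherits(motif, "rbp_motif")) motif else rbp_motif(deparse(substitute(motif)), motif)
  counts <- iupac_match_count(m$motif, seqs)
  f <- mean(counts >= 1L)
  c_bar <- if (f == 0) 0 else if (count_mode == "matching")
    mean(counts[counts >= 1L]) else mean(counts)
  data.frame(rbp = m$rbp_name, f = f, c_bar = c_bar, B = f * c_bar,
             n_seqs = length(seqs), stringsAsFactors = FALSE)
}

#' Binding statistics for a motif table over a sequence group
#'
#' @param motifs data.frame with columns \code{rbp_name} and \code{motif}
#'   (IUPAC strings).
#' @param seqs Character vector of sequences.
#' @inheritParams motif_group_stats
#' @return data.frame with one row per RBP: rbp, f, c_bar, B.
#' @export
motif_table_stats <- function(motifs, seqs, count_mode = c("matching", "all")) {
  count_mode <- match.arg(count_mode)
  stopifnot(all(c("rbp_name", "motif") %in% names(motifs)))
  do.call(rbind, lapply(seq_len(nrow(motifs)), function(i)
    motif_group_stats(rbp_motif(motifs$rbp_name[i], motifs$motif[i]),
                      seqs, count_mode)))
}

#' Rank RBPs by binding score
#'
#' Keeps factors with binding frequency strictly above \code{f_min} (the
#' 70% gate), sorts by binding score B descending, and returns the top
#' \code{top_n}. Ties in B are broken by f descending, then RBP name
#' ascending.
#'
#' @param stats data.frame from [motif_table_stats()] (columns rbp, f, B).
#' @param f_min Minimum binding frequency (exclusive). Default 0.70.
#' @param top_n Shortlist size. Default 20.
#' @return The filtered, ranked rows with a \code{rank} column.
#' @export
rank_rbps <- function(stats, f_min = 0.70, top_n = 20L) {
  stopifnot(all(c("rbp", "f", "B") %in% names(stats)))
  keep <- stats[stats$f > f_min, , drop = FALSE]
  keep <- keep[order(-keep$B, -keep$f, keep$rbp), , drop = FALSE]
  keep <- utils::head(keep, top_n)
  if (nrow(keep)) keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}

#' Differential RBP binding between two sequence groups
#'
#' Joins per-RBP binding statistics computed on two groups (e.g. retained
#' vs constitutive introns) and reports the binding-score ratio A/B. RBPs
#' binding only one group are flagged "A-exclusive"/"B-exclusive".
#'
#' @param stats_a,stats_b data.frames from [motif_table_stats()] computed
#'   with the same motif set.
#' @return data.frame sorted by B in group A: rbp, f_a, c_bar_a, B_a, f_b,
#'   c_bar_b, B_b, ratio, status.
#' @export
differential_binding <- function(stats_a, stats_b) {
  if (!setequal(stats_a$rbp, stats_b$rbp))
    stop_("the two groups must use the same motif set")
  m <- merge(stats_a, stats_b, by = "rbp", suffixes = c("_a", "_b"))
  m$ratio <- ifelse(m$B_b > 0, m$B_a / m$B_b,
                    ifelse(m$B_a > 0, Inf, NA_real_))
  m$status <- ifelse(m$B_a > 0 & m$B_b == 0, "A-exclusive",
                     ifelse(m$B_b > 0 & m$B_a == 0, "B-exclusive",
                            ifelse(m$B_a == 0 & m$B_b == 0, "absent", "shared")))
  m <- m[order(-m$B_a), , drop = FALSE]
  rownames(m) <- NULL
  m
}
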