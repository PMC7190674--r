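# The "splicing code" of intron retention: which sequence features separate
# retained from constitutive introns. Features are intron length, GC content
# and donor/acceptor splice-site strength under a retrainable
# maximum-entropy model; groups are compared with Wilcoxon rank-sum tests.

DONOR_WIDTH <- 9L      # 3 exonic + 6 intronic bases around the 5' splice site
ACCEPTOR_WIDTH <- 21L  # 20 intronic + 1 exonic base around the 3' splice site

#' Select constitutive introns from a \eqn{\Delta\psi}-sorted event list
#'
#' Constitutive (reference) introns are defined as the n events with
#' \eqn{\Delta\psi = 0} located nearest the center of the
#' \eqn{\Delta\psi}-sorted list (default n = 300). Ties in distance to the
#' center go to the lower sorted index.
#'
#' @param events data.frame with a \code{dpsi} column.
#' @param n Number of introns to select.
#' @return The selected rows of \code{events} (sorted-order indices as
#'   attribute \code{sorted_index}). Warns and returns all zero-\eqn{\Delta\psi}
#'   events when fewer than \code{n} exist.
#' @export
select_constitutive_introns <- function(events, n = 300L) {
  stopifnot(is.data.frame(events), "dpsi" %in% names(events))
  ord <- order(events$dpsi)
  sorted <- events[ord, , drop = FALSE]
  zero_pos <- which(sorted$dpsi == 0)
  if (length(zero_pos) == 0L) stop_("no events with dpsi == 0")
  if (length(zero_pos) < n) {
    warn_(sprintf("only %d zero-dpsi events available (requested %d); returning all",
                  length(zero_pos), n))
    sel <- zero_pos
  } else {
    center <- (nrow(sorted) + 1) / 2
    sel <- zero_pos[order(abs(zero_pos - center), zero_pos)][seq_len(n)]
    sel <- sort(sel)
  }
  out <- sorted[sel, , drop = FALSE]
  attr(out, "sorted_index") <- sel
  out
}

#' Extract donor and acceptor splice-site windows for an intron
#'
#' The donor window is the 9-mer spanning the 5' splice site (last 3 exonic
#' bases + first 6 intronic bases); the acceptor window is the 21-mer
#' spanning the 3' splice site (last 20 intronic bases + first 1 exonic
#' base). Windows are reported 5'->3' on the sense strand; minus-strand
#' introns are reverse-complemented.
#'
#' @param start,end Intron coordinates, 0-based half-open on the scaffold.
#' @param strand "+" or "-".
#' @param seq Scaffold sequence (character or \code{Biostrings::DNAString}).
#' @param id Intron identifier used in error messages.
#' @return List with \code{donor} (9-mer) and \code{acceptor} (21-mer).
#' @export
extract_site_windows <- function(start, end, strand, seq, id = "intron") {
  seq <- as.character(seq)
  len <- nchar(seq)
  stopifnot(strand %in% c("+", "-"), end > start)
  if (strand == "+") {
    d0 <- start - 3L; d1 <- start + 6L   # 0-based half-open donor window
    a0 <- end - 20L;  a1 <- end + 1L
  } else {
    d0 <- end - 6L;   d1 <- end + 3L
    a0 <- start - 1L; a1 <- start + 20L
  }
  if (d0 < 0L || a0 < 0L || d1 > len || a1 > len)
    stop_(sprintf("splice-site window out of sequence bounds for '%s'", id))
  donor <- substr(seq, d0 + 1L, d1)
  acceptor <- substr(seq, a0 + 1L, a1)
  if (strand == "-") {
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    donor <- rc(donor); acceptor <- rc(acceptor)
  }
  list(donor = donor, acceptor = acceptor)
}

#' Intron length and GC content
#'
#' GC = (#G + #C) / (#A + #C + #G + #T); N bases are excluded from both
#' numerator and denominator. Length counts all bases including N.
#'
#' @param seq Character vector of intron sequences (A/C/G/T/N).
#' @return data.frame with columns \code{length} and \code{gc}.
#' @export
intron_features <- function(seq) {
  if (any(nchar(seq) == 0L)) stop_("empty sequence")
  ss <- Biostrings::DNAStringSet(seq)
  freq <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  if (any(acgt == 0)) stop_("sequence contains no A/C/G/T bases")
  data.frame(length = nchar(seq), gc = (freq[, "G"] + freq[, "C"]) / acgt)
}

## ---- maximum-entropy splice-site model ------------------------------------
# The model is the maximum-entropy distribution over fixed-width windows
# subject to empirical positional marginals (order 0) or positional +
# adjacent-pair marginals (order 1). For these constraint sets the solution
# factorizes along the position chain, so the distribution is stored as chain
# factors and fitted by iterative proportional fitting (IPF) with model
# marginals recomputed exactly each sweep. This keeps the 4^21 acceptor
# window space tractable.

BASES <- c("A", "C", "G", "T")

# windows (character vector) -> integer matrix n x w of base indices 1..4
.window_matrix <- function(windows) {
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop_("inconsistent window lengths")
  m <- matrix(match(unlist(strsplit(toupper(windows), "")), BASES),
              ncol = w, byrow = TRUE)
  if (anyNA(m)) stop_("windows must contain only A/C/G/T")
  m
}

# empirical marginals with pseudocount: pos = list of length w (each len 4),
# pair = list of length w-1 (each 4x4) when order 1
.empirical_marginals <- function(mat, order, pseudocount) {
  w <- ncol(mat)
  pos <- lapply(seq_len(w), function(i) {
    f <- tabulate(mat[, i], 4L) + pseudocount
    f / sum(f)
  })
  pair <- NULL
  if (order >= 1L) {
    pair <- lapply(seq_len(w - 1L), function(i) {
      f <- matrix(pseudocount / 4, 4, 4)
      for (a in 1:4) for (b in 1:4)
        f[a, b] <- f[a, b] + sum(mat[, i] == a & mat[, i + 1L] == b)
      f / sum(f)
    })
  }
  list(pos = pos, pair = pair)
}

# chain model: factors phi (list of w vectors) and, for order 1, pair factors
# psi (list of w-1 4x4 matrices). Model marginals by forward-backward.
.chain_marginals <- function(phi, psi, w) {
  if (is.null(psi)) {
    pos <- lapply(phi, function(f) f / sum(f))
    return(list(pos = pos, pair = NULL, logZ = sum(log(vapply(phi, sum, 1)))))
  }
  # unnormalized potentials: node phi_i, edge psi_i
  fwd <- vector("list", w)   # alpha_i(x) = sum over x_1..x_{i-1}
  fwd[[1]] <- phi[[1]]
  for (i in 2:w) fwd[[i]] <- phi[[i]] * as.vector(crossprod(psi[[i - 1L]], fwd[[i - 1L]]))
  bwd <- vector("list", w)
  bwd[[w]] <- rep(1, 4)
  for (i in (w - 1L):1L) bwd[[i]] <- as.vector(psi[[i]] %*% (phi[[i + 1L]] * bwd[[i + 1L]]))
  Z <- sum(fwd[[w]])
  pos <- lapply(seq_len(w), function(i) fwd[[i]] * bwd[[i]] / Z)
  pair <- lapply(seq_len(w - 1L), function(i) {
    m <- outer(fwd[[i]], phi[[i + 1L]] * bwd[[i + 1L]]) * psi[[i]] / Z
    m
  })
  list(pos = pos, pair = pair, logZ = log(Z))
}

# fit one chain-factorized maxent distribution to marginal constraints
.fit_chain <- function(target, order, w, tol, max_iter) {
  phi <- lapply(seq_len(w), function(i) rep(0.25, 4))
  psi <- if (order >= 1L) lapply(seq_len(w - 1L), function(i) matrix(1, 4, 4)) else NULL
  dev <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mm <- .chain_marginals(phi, psi, w)
    devs <- max(vapply(seq_len(w), function(i) max(abs(mm$pos[[i]] - target$pos[[i]])), 1))
    if (order >= 1L)
      devs <- max(devs, vapply(seq_len(w - 1L), function(i)
        max(abs(mm$pair[[i]] - target$pair[[i]])), 1))
    dev <- devs
    if (dev < tol) break
    # IPF sweep: scale node factors, then edge factors
    for (i in seq_len(w)) {
      mm <- .chain_marginals(phi, psi, w)
      phi[[i]] <- phi[[i]] * target$pos[[i]] / pmax(mm$pos[[i]], 1e-300)
    }
    if (order >= 1L) for (i in seq_len(w - 1L)) {
      mm <- .chain_marginals(phi, psi, w)
      psi[[i]] <- psi[[i]] * target$pair[[i]] / pmax(mm$pair[[i]], 1e-300)
    }
  }
  if (dev >= tol)
    stop_(sprintf("IPF did not converge: max marginal deviation %.3g after %d iterations",
                  dev, it))
  list(phi = phi, psi = psi, iterations = it, max_dev = dev)
}

# log2 probability of each window under a fitted chain
.chain_log2prob <- function(fit, mat, w) {
  mm <- .chain_marginals(fit$phi, fit$psi, w)
  n <- nrow(mat)
  lp <- log2(pmax(mm$pos[[1]][mat[, 1]], 1e-300))
  if (is.null(fit$psi)) {
    if (w > 1) for (i in 2:w) lp <- lp + log2(pmax(mm$pos[[i]][mat[, i]], 1e-300))
  } else {
    if (w > 1) for (i in 2:w) {
      cond <- mm$pair[[i - 1L]] / pmax(rowSums(mm$pair[[i - 1L]]), 1e-300)
      lp <- lp + log2(pmax(cond[cbind(mat[, i - 1L], mat[, i])], 1e-300))
    }
  }
  lp
}

#' Fit a maximum-entropy splice-site model
#'
#' Fits maximum-entropy distributions for a signal set (real splice-site
#' windows) and a background set (e.g. shuffled or decoy windows) of equal
#' width, subject to positional marginals (\code{order = 0}) or positional +
#' adjacent-pair marginals (\code{order = 1}), by iterative proportional
#' fitting until the largest deviation between model and empirical marginals
#' is below \code{tol}. Site strength is then the signal/background log-odds
#' (see [score_site()]).
#'
#' @param signal,background Character vectors of A/C/G/T windows, all of one
#'   width (donor 9-mers or acceptor 21-mers in the standard geometry).
#' @param order 0 (positional independence) or 1 (adds adjacent-pair
#'   dependencies).
#' @param pseudocount Added per cell when forming empirical marginal
#'   constraints (default 0.5); keeps log-odds finite for unseen bases.
#' @param min_signal Minimum number of signal windows (default 50).
#' @param tol IPF convergence tolerance on marginals (default 1e-6).
#' @param max_iter IPF iteration cap (default 10000).
#' @return Object of class \code{maxent_model} with the two fitted chains,
#'   window width, order, and fit diagnostics (\code{iterations},
#'   \code{max_dev} per distribution).
#' @export
fit_maxent <- function(signal, background, order = 1L, pseudocount = 0.5,
                       min_signal = 50L, tol = 1e-6, max_iter = 10000L) {
  if (length(signal) < min_signal)
    stop_(sprintf("need >= %d signal windows, got %d", min_signal, length(signal)))
  if (!order %in% c(0L, 1L)) stop_("`order` must be 0 or 1")
  ms <- .window_matrix(signal); mb <- .window_matrix(background)
  if (ncol(ms) != ncol(mb)) stop_("inconsistent window lengths between signal and background")
  w <- ncol(ms)
  tgt_s <- .empirical_marginals(ms, order, pseudocount)
  tgt_b <- .empirical_marginals(mb, order, pseudocount)
  fit_s <- .fit_chain(tgt_s, order, w, tol, max_iter)
  fit_b <- .fit_chain(tgt_b, order, w, tol, max_iter)
  structure(list(
    width = w, order = as.integer(order), pseudocount = pseudocount,
    signal = fit_s, background = fit_b,
    constraints = list(signal = tgt_s, background = tgt_b),
    diagnostics = list(
      signal = list(iterations = fit_s$iterations, max_dev = fit_s$max_dev),
      background = list(iterations = fit_b$iterations, max_dev = fit_b$max_dev))
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maximum-entropy splice-site model: width %d, order %d\n",
              x$width, x$order))
  cat(sprintf("  signal fit: %d IPF iterations, max marginal dev %.2g\n",
              x$diagnostics$signal$iterations, x$diagnostics$signal$max_dev))
  cat(sprintf("  background fit: %d IPF iterations, max marginal dev %.2g\n",
              x$diagnostics$background$iterations, x$diagnostics$background$max_dev))
  invisible(x)
}

#' Score splice-site windows under a fitted model
#'
#' Score = log2(P_signal(window) / P_background(window)), in bits. Windows
#' containing N (or any non-ACGT base) are not scored and return NA with a
#' warning.
#'
#' @param model A [fit_maxent()] model.
#' @param windows Character vector of windows of the model's width.
#' @return Numeric vector of scores in bits (NA for unscorable windows).
#' @export
score_site <- function(model, windows) {
  stopifnot(inherits(model, "maxent_model"))
  if (any(nchar(windows) != model$width))
    stop_(sprintf("windows must have width %d", model$width))
  clean <- grepl("^[ACGTacgt]+$", windows)
  out <- rep(NA_real_, length(windows))
  if (any(!clean))
    warn_(sprintf("%d window(s) contain non-ACGT bases; not scored", sum(!clean)))
  if (any(clean)) {
    mat <- .window_matrix(windows[clean])
    out[clean] <- .chain_log2prob(model$signal, mat, model$width) -
      .chain_log2prob(model$background, mat, model$width)
  }
  out
}

#' Enumerate the full model distribution (small widths only)
#'
#' Utility for verifying that the fitted distribution is a proper probability
#' distribution over the window space; practical for width <= 8.
#'
#' @param model A [fit_maxent()] model.
#' @param which "signal" or "background".
#' @return Named numeric vector of probabilities over all 4^width windows.
#' @export
maxent_distribution <- function(model, which = c("signal", "background")) {
  which <- match.arg(which)
  w <- model$width
  if (4^w > 1e6) stop_("window space too large to enumerate")
  kmers <- do.call(expand.grid, rep(list(1:4), w))[, w:1, drop = FALSE]
  mat <- as.matrix(kmers)
  lp <- .chain_log2prob(model[[which]], mat, w)
  p <- 2^lp
  names(p) <- apply(mat, 1, function(r) paste(BASES[r], collapse = ""))
  p
}

#' Compare intron feature distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum tests per feature (length, GC, donor score
#' S5, acceptor score S3) between, e.g., retained and constitutive introns.
#'
#' @param features_a,features_b data.frames with (a subset of) columns
#'   \code{length}, \code{gc}, \code{s5}, \code{s3}; only shared columns are
#'   compared.
#' @param exact Passed to [stats::wilcox.test()]; default NULL (exact for
#'   small samples without ties).
#' @return data.frame: feature, median_a, median_b, p.
#' @export
compare_intron_groups <- function(features_a, features_b, exact = NULL) {
  feats <- intersect(intersect(names(features_a), names(features_b)),
                     c("length", "gc", "s5", "s3"))
  if (length(feats) == 0L) stop_("no shared feature columns")
  if (nrow(features_a) < 3L || nrow(features_b) < 3L)
    stop_("each group must have >= 3 introns")
  do.call(rbind, lapply(feats, function(f) {
    xa <- features_a[[f]]; xb <- features_b[[f]]
    p <- stats::wilcox.test(xa, xb, exact = exact)$p.value
    data.frame(feature = f, median_a = stats::median(xa),
               median_b = stats::median(xb), p = p,
               stringsAsFactors = FALSE)
  }))
}
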