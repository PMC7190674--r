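# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Benjamini-Hochberg step-up by literal definition:
# q_i = min_{j >= rank(i)} p_(j) * m / j, capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (r in seq_len(m)) {
    js <- r:m
    q_sorted[r] <- min(pmin(p[o][js] * m / js, 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# one-sided (co-occurrence enrichment) p by exhaustive hypergeometric sum
hyper_enumeration_p <- function(both, a_only, b_only, neither) {
  m <- both + a_only          # A-altered
  n <- b_only + neither       # A-wildtype
  k <- both + b_only          # B-altered
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= both])
}

# exact two-sided rank-sum p by enumeration over all rank assignments
wilcox_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2  # observed U for x
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(pooled[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# positional log-odds score from smoothed empirical frequencies (order-0
# maxent oracle, computed without the package's chain machinery)
positional_logodds <- function(signal, background, windows, pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  freq <- function(set) {
    mat <- do.call(rbind, strsplit(set, ""))
    sapply(seq_len(ncol(mat)), function(i) {
      f <- table(factor(mat[, i], levels = bases)) + pseudocount
      as.numeric(f / sum(f))
    })
  }
  fs <- freq(signal); fb <- freq(background)
  vapply(windows, function(wd) {
    ch <- match(strsplit(wd, "")[[1]], bases)
    sum(log2(fs[cbind(ch, seq_along(ch))] / fb[cbind(ch, seq_along(ch))]))
  }, numeric(1), USE.NAMES = FALSE)
}

# mutate a consensus 9-mer at the given per-base rate
mutate_consensus <- function(consensus, rate = 0.15) {
  ch <- strsplit(consensus, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

random_windows <- function(n, w) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""),
    character(1))
}
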