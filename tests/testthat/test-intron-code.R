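test_that("constitutive intron selection takes central zero-dPSI events", {
  ev <- data.frame(dpsi = c(-0.3, -0.1, 0, 0, 0, 0.2),
                   id = paste0("e", 1:6))
  sel <- select_constitutive_introns(ev, n = 3)
  expect_equal(sort(sel$id), c("e3", "e4", "e5"))
  # 400 zeros among flanks: the n nearest the sorted-list center, ties low
  ev2 <- data.frame(dpsi = c(rep(-0.5, 50), rep(0, 400), rep(0.5, 50)))
  sel2 <- select_constitutive_introns(ev2, n = 300)
  idx <- attr(sel2, "sorted_index")
  center <- (500 + 1) / 2
  # direct index arithmetic: chosen = 300 zero-positions closest to center
  zero_pos <- 51:450
  expected <- sort(zero_pos[order(abs(zero_pos - center), zero_pos)][1:300])
  expect_equal(idx, expected)
  # shortage warns and returns all zeros
  ev3 <- data.frame(dpsi = c(rep(0, 50), runif(100, 0.1, 0.5)))
  expect_warning(sel3 <- select_constitutive_introns(ev3, n = 300), "only 50")
  expect_equal(nrow(sel3), 50)
  expect_error(select_constitutive_introns(data.frame(dpsi = c(0.1, 0.2))), "dpsi == 0")
})

test_that("splice-site windows: donor 9-mer and acceptor 21-mer, strand-aware", {
  exon1 <- "GATTACACATTAGCCCAG"           # ends ...CAG
  intron <- paste0("GTAAGT", strrep("ACGT", 20), "TTTTTTTTTTTCAG")  # GT...AG
  exon2 <- "GCCATTTTAGCAAGGCAT"
  seqp <- paste0(exon1, intron, exon2)
  s <- nchar(exon1); e <- s + nchar(intron)  # 0-based half-open intron
  win <- extract_site_windows(s, e, "+", seqp)
  expect_equal(win$donor, "CAGGTAAGT")
  expect_equal(nchar(win$acceptor), 21)
  expect_equal(win$acceptor, paste0(substr(intron, nchar(intron) - 19, nchar(intron)),
                                    substr(exon2, 1, 1)))
  # minus strand: reverse-complement the scaffold, same windows expected
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqp)))
  L <- nchar(seqp)
  win_m <- extract_site_windows(L - e, L - s, "-", rc)
  expect_equal(win_m$donor, win$donor)
  expect_equal(win_m$acceptor, win$acceptor)
  # out-of-bounds window names the intron
  expect_error(extract_site_windows(0, 40, "+", seqp, id = "intron_7"), "intron_7")
})

test_that("intron length and GC follow the stated conventions", {
  f <- intron_features(c("GCGC", "ATAT", "GATC"))
  expect_equal(f$length, c(4, 4, 4))
  expect_equal(f$gc, c(1, 0, 0.5))
  # N excluded from numerator and denominator; length keeps N
  fn <- intron_features("GCNNAT")
  expect_equal(fn$length, 6)
  expect_equal(fn$gc, 0.5)
  # GC invariant under reverse complement
  set.seed(3)
  for (i in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    expect_equal(intron_features(sq)$gc, intron_features(rc)$gc)
  }
  expect_error(intron_features(""), "empty")
})

test_that("maxent order-0 model equals the product of positional frequencies", {
  set.seed(8)
  sig <- vapply(1:100, function(i) mutate_consensus("CAGGTAAGT"), "")
  bg <- random_windows(100, 9)
  m <- fit_maxent(sig, bg, order = 0)
  # scores equal independent positional log-odds sums
  test_w <- random_windows(20, 9)
  expect_equal(score_site(m, test_w),
               positional_logodds(sig, bg, test_w), tolerance = 1e-9)
  # distribution over the window space sums to 1 (enumerable at width 5)
  m5 <- fit_maxent(substr(sig, 1, 5), substr(bg, 1, 5), order = 0)
  expect_equal(sum(maxent_distribution(m5, "signal")), 1, tolerance = 1e-9)
  expect_equal(sum(maxent_distribution(m5, "background")), 1, tolerance = 1e-9)
})

test_that("maxent fitted marginals match empirical constraints; order-1 respects pairs", {
  set.seed(9)
  sig <- vapply(1:150, function(i) mutate_consensus("CAGGTAAGT", 0.25), "")
  bg <- random_windows(150, 9)
  m <- fit_maxent(sig, bg, order = 1)
  expect_lt(m$diagnostics$signal$max_dev, 1e-6)
  expect_lt(m$diagnostics$background$max_dev, 1e-6)
  # recompute marginals from the enumerated distribution at width 5
  sig5 <- substr(sig, 1, 5); bg5 <- substr(bg, 1, 5)
  m5 <- fit_maxent(sig5, bg5, order = 1)
  d <- maxent_distribution(m5, "signal")
  kmers <- names(d)
  for (pos in 1:5) {
    got <- vapply(c("A", "C", "G", "T"), function(b)
      sum(d[substr(kmers, pos, pos) == b]), numeric(1))
    want <- m5$constraints$signal$pos[[pos]]
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
  for (pos in 1:4) {  # adjacent-pair marginals
    pair_emp <- m5$constraints$signal$pair[[pos]]
    for (a in 1:4) for (b in 1:4) {
      ab <- paste0(c("A", "C", "G", "T")[a], c("A", "C", "G", "T")[b])
      got <- sum(d[substr(kmers, pos, pos + 1) == ab])
      expect_equal(got, pair_emp[a, b], tolerance = 1e-6)
    }
  }
})

test_that("maxent scoring edge cases", {
  set.seed(10)
  train <- random_windows(200, 9)
  # identical signal and background training sets: all scores 0 bits
  m <- fit_maxent(train, train, order = 1)
  expect_equal(score_site(m, random_windows(10, 9)), rep(0, 10), tolerance = 1e-9)
  # strong consensus vs shuffled background: clear score gap
  sig <- vapply(1:200, function(i) mutate_consensus("CAGGTAAGT"), "")
  m2 <- fit_maxent(sig, random_windows(200, 9), order = 1)
  gap <- mean(score_site(m2, sig)) - mean(score_site(m2, random_windows(200, 9)))
  expect_gt(gap, 2)
  # windows with N flagged, wrong width rejected, too few signal rejected
  expect_warning(sc <- score_site(m2, c("CAGGTAAGT", "CAGGTANGT")), "non-ACGT")
  expect_true(is.na(sc[2]) && !is.na(sc[1]))
  expect_error(score_site(m2, "ACGT"), "width")
  expect_error(fit_maxent(sig[1:10], random_windows(10, 9)), ">= 50")
})

test_that("group comparison: exact small-sample Wilcoxon matches enumeration", {
  fa <- data.frame(length = c(5, 9, 12, 20, 31, 44),
                   gc = c(0.2, 0.5, 0.31, 0.44, 0.6, 0.35))
  # identical groups: p = 1 (ties make the exact method fall back, harmless)
  cmp <- suppressWarnings(compare_intron_groups(fa, fa))
  expect_true(all(cmp$p == 1))
  # n <= 8 per group: exact p equals brute-force enumeration over rank splits
  set.seed(12)
  for (i in 1:5) {
    xa <- data.frame(gc = runif(7)); xb <- data.frame(gc = runif(6))
    got <- compare_intron_groups(xa, xb)$p
    expect_equal(got, wilcox_enumeration_p(xa$gc, xb$gc), tolerance = 1e-12)
  }
  # planted GC shift is detected
  set.seed(13)
  ga <- data.frame(gc = rbeta(300, 10, 10))
  gb <- data.frame(gc = rbeta(300, 10, 10) * 0.7 + 0.15 + 0.15)
  expect_lt(compare_intron_groups(ga, gb)$p, 1e-6)
  expect_error(compare_intron_groups(fa[1:2, ], fa), ">= 3")
})

test_that("same-distribution intron groups rarely show significant features", {
  set.seed(14)
  sigs <- replicate(40, {
    n <- 60
    fa <- data.frame(length = rlnorm(n, 6, 1), gc = rbeta(n, 8, 10))
    fb <- data.frame(length = rlnorm(n, 6, 1), gc = rbeta(n, 8, 10))
    any(compare_intron_groups(fa, fb, exact = FALSE)$p < 0.01)
  })
  expect_lte(mean(sigs), 0.15)
})
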