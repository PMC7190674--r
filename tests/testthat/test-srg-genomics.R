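mk_alt_matrix <- function(n_patients, genes, probs = c(amp = 0.1, del = 0.1, mut = 0.02),
                          seed = 1) {
  withr::with_seed(seed, {
    matrix(sample(c("amp", "del", "mut", "none"), n_patients * length(genes),
                  replace = TRUE,
                  prob = c(probs, 1 - sum(probs))),
           n_patients, length(genes),
           dimnames = list(sprintf("p%03d", seq_len(n_patients)), genes))
  })
}

test_that("alteration matrix construction collapses multi-calls by precedence", {
  calls <- data.frame(patient = c("p1", "p1", "p2", "p3", "p3"),
                      gene = c("g1", "g1", "g1", "g2", "g2"),
                      call = c("mut", "del", "amp", "mut", "amp"))
  m <- alteration_matrix(calls, patients = c("p1", "p2", "p3"),
                         genes = c("g1", "g2"))
  expect_equal(m["p1", "g1"], "del")   # del beats mut
  expect_equal(m["p3", "g2"], "amp")   # amp beats mut
  expect_equal(m["p2", "g2"], "none")
  expect_error(alteration_matrix(data.frame(patient = "p", gene = "g",
                                            call = "gain")), "amp/del/mut")
})

test_that("per-gene and cumulative frequencies count patients once", {
  m <- matrix("none", 100, 3, dimnames = list(sprintf("p%03d", 1:100),
                                              c("g1", "g2", "g3")))
  m[1:8, "g1"] <- "amp"; m[9:11, "g1"] <- "del"
  fr <- gene_alteration_freq(m, "g1")
  expect_equal(unname(fr["amp"]), 0.08)
  expect_equal(unname(fr["del"]), 0.03)
  expect_equal(unname(fr["any"]), 0.11)
  expect_equal(unname(gene_alteration_freq(m, "g2")), rep(0, 4))
  # one patient altered in every gene counts once
  m2 <- m; m2["p001", ] <- "mut"
  expect_equal(cumulative_freq(m2[1, , drop = FALSE], c("g1", "g2", "g3")), 1)
  expect_warning(cf0 <- cumulative_freq(m, character(0)), "empty")
  expect_equal(cf0, 0)
  # bounds: cumulative >= max per-gene any-freq and <= sum of them
  cum <- cumulative_freq(m2, c("g1", "g2", "g3"))
  anyf <- vapply(c("g1", "g2", "g3"), function(g)
    gene_alteration_freq(m2, g)["any"], numeric(1))
  expect_gte(cum, max(anyf))
  expect_lte(cum, sum(anyf))
  expect_error(gene_alteration_freq(m, "nope"), "absent")
})

test_that("independent alterations match the closed-form cumulative frequency", {
  g <- sprintf("g%03d", 1:274)
  m <- mk_alt_matrix(500, g, probs = c(amp = 0.01, del = 0.005, mut = 0.005),
                     seed = 7)
  expected <- 1 - (1 - 0.02)^274
  expect_equal(cumulative_freq(m, g), expected, tolerance = 0.02)
})

test_that("top_altered ranks by frequency with alphabetical ties", {
  m <- matrix("none", 20, 3, dimnames = list(sprintf("p%02d", 1:20),
                                             c("zeta", "alpha", "beta")))
  m[1:2, "zeta"] <- "amp"; m[1:2, "alpha"] <- "del"; m[1, "beta"] <- "mut"
  top <- top_altered(m, n = 3, by = "any")
  expect_equal(top$gene, c("alpha", "zeta", "beta"))  # tie at 0.10 alphabetical
  expect_equal(nrow(top_altered(m, n = 10)), 3)       # n > gene count -> all
  expect_equal(top_altered(m, n = 1, by = "amp")$gene, "zeta")
})

test_that("one-sided Fisher co-occurrence equals hypergeometric enumeration", {
  # zero co-occurrences with nonzero margins: p = 1
  expect_equal(fisher_cooccurrence(0, 5, 5, 10)$p, 1)
  # margins forcing a unique table
  expect_equal(fisher_cooccurrence(3, 0, 0, 0)$p, 1)
  set.seed(70)
  for (i in 1:100) {
    cells <- as.vector(stats::rmultinom(1, sample(1:20, 1), rep(0.25, 4)))
    got <- fisher_cooccurrence(cells[1], cells[2], cells[3], cells[4])$p
    want <- hyper_enumeration_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
  # symmetry under swapping gene labels
  expect_equal(fisher_cooccurrence(4, 2, 7, 9)$p, fisher_cooccurrence(4, 7, 2, 9)$p)
})

test_that("cooccurrence on a matrix is invariant under patient permutation", {
  m <- mk_alt_matrix(80, c("gA", "gB"), probs = c(amp = 0.3, del = 0.1, mut = 0.05),
                     seed = 8)
  r1 <- cooccurrence(m, "gA", "gB")
  r2 <- cooccurrence(m[sample(rownames(m)), ], "gA", "gB")
  expect_equal(r1$p, r2$p)
  expect_equal(sum(r1$table), 80)
  # planted co-deletion is detected as enrichment
  m2 <- matrix("none", 100, 2, dimnames = list(sprintf("p%03d", 1:100), c("gA", "gB")))
  m2[1:30, ] <- "del"; m2[31:35, "gA"] <- "del"; m2[36:40, "gB"] <- "del"
  expect_lt(cooccurrence(m2, "gA", "gB")$p, 1e-6)
})

test_that("CNV-expression association detects the planted shift and flags small groups", {
  cfg <- sim_config(seed = 81, cohort = list(n_patients = 200, delta = 2))
  ch <- simulate_cohort(cfg, srg_unfavorable_genes)
  res <- expression_by_cnv(ch$expr, ch$alterations, "SRSF1")
  amp_row <- res[res$comparison == "amp", ]
  expect_lt(amp_row$p, 0.01)
  expect_equal(amp_row$mean_group - amp_row$mean_neutral, 2, tolerance = 0.7)
  del_row <- res[res$comparison == "del", ]
  expect_lt(del_row$mean_group - del_row$mean_neutral, 0)
  # no amplified patients -> NA with flag
  m <- ch$alterations; m[, "SRSF1"] <- ifelse(m[, "SRSF1"] == "amp", "none", m[, "SRSF1"])
  res2 <- expression_by_cnv(ch$expr, m, "SRSF1")
  expect_true(is.na(res2$p[res2$comparison == "amp"]))
  expect_match(res2$flag[res2$comparison == "amp"], "too small")
})

test_that("grade association: null is calibrated and planted shifts are found", {
  set.seed(82)
  null_p <- vapply(1:100, function(i) {
    gl <- sample(6:10, 120, replace = TRUE)
    grade_association(rep(c(TRUE, FALSE), each = 60), gl)$p
  }, numeric(1))
  expect_gte(mean(null_p >= 0.01), 0.90)
  gl <- c(sample(7:10, 100, replace = TRUE), sample(6:9, 100, replace = TRUE))
  ga <- grade_association(rep(c(TRUE, FALSE), each = 100), gl)
  expect_lt(ga$p, 0.01)
  expect_gte(ga$median_in, ga$median_out)
  expect_error(grade_association(rep(TRUE, 10), sample(6:10, 10, TRUE)), "empty")
})
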