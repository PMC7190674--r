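test_that("sim_config validates ranges and degenerate designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(exons_per_gene = c(1, 3)), "intron-bearing")
  expect_error(sim_config(gc_target = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(event_design = data.frame(
    type = "SE", n = 5, psi_a = 1.4, psi_b = 0.5)), "\\[0, 1\\]")
  expect_error(sim_config(cohort = list(p_amp = 0.6, p_del = 0.6)), "sum")
})

test_that("annotation generator: intron counts, boundaries, GC target, determinism", {
  cfg <- sim_config(seed = 2, n_genes = 10, exons_per_gene = c(3, 3),
                    gc_target = 0.6, intron_len = c(200, 400))
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$introns), 20)  # 10 genes x (3 exons - 1)
  one <- generate_annotation(sim_config(seed = 2, n_genes = 1,
                                        exons_per_gene = c(2, 2)))
  expect_equal(nrow(one$introns), 1)
  # canonical GT...AG on the sense strand
  for (i in seq_len(nrow(ann$introns))) {
    intr <- ann$introns[i, ]
    s <- as.character(ann$genome[[intr$gene_id]])
    sub <- substr(s, intr$start, intr$end)
    if (intr$strand == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_equal(substr(sub, 1, 2), "GT")
    expect_equal(substr(sub, nchar(sub) - 1, nchar(sub)), "AG")
  }
  # recomputed GC of generated introns near the target
  gc <- sapply(seq_len(nrow(ann$introns)), function(i) {
    intr <- ann$introns[i, ]
    sub <- substr(as.character(ann$genome[[intr$gene_id]]), intr$start, intr$end)
    intron_features(sub)$gc
  })
  expect_equal(mean(gc), 0.6, tolerance = 0.05)
  # same seed => identical output (after serialization)
  ann2 <- generate_annotation(cfg)
  expect_identical(ann$annotation, ann2$annotation)
  expect_identical(as.character(ann$genome), as.character(ann2$genome))
})

test_that("annotation round-trips through GTF", {
  cfg <- sim_config(seed = 4, n_genes = 3)
  ann <- generate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(ann$annotation, path)
  back <- rtracklayer::import(path, format = "gtf")
  ex <- back[back$type == "exon"]
  expect_equal(length(ex), sum(ann$annotation$type == "exon"))
  expect_equal(GenomicRanges::start(ex),
               ann$annotation$start[ann$annotation$type == "exon"])
})

test_that("junction counts follow the binomial/Poisson model and the seed", {
  truth <- data.frame(event_id = paste0("e", 1:1000), psi_a = 0.5, psi_b = 1)
  jc <- simulate_junction_counts(truth, depth = 200, n_replicates = 2, seed = 9)
  # psi = 1 group: skipping identically 0
  expect_true(all(jc$skipping[, jc$groups == "B"] == 0))
  # psi = 0.5 group: empirical inclusion fraction near 0.5
  a <- jc$groups == "A"
  frac <- sum(jc$inclusion[, a]) / sum(jc$inclusion[, a] + jc$skipping[, a])
  expect_equal(frac, 0.5, tolerance = 0.01)
  expect_equal(mean(jc$inclusion + jc$skipping), 200, tolerance = 2)
  expect_identical(jc, simulate_junction_counts(truth, 200, 2, seed = 9))
  expect_error(simulate_junction_counts(truth, depth = -5, 2), "depth")
})

test_that("motif planting is exact under rescan", {
  bg <- random_sequences(100, 80, seed = 21, exclude_motif = "TGCATG")
  expect_true(all(iupac_match_count("TGCATG", bg) == 0))
  pl <- plant_motifs(bg, "TGCATG", fraction = 1, per_seq = 1, seed = 22)
  expect_true(all(iupac_match_count("TGCATG", pl$seqs) == 1))
  # fractional planting recovers the design frequency on rescan
  pl80 <- plant_motifs(bg, "TGCATG", fraction = 0.8, per_seq = 2, seed = 23)
  hits <- iupac_match_count("TGCATG", pl80$seqs)
  expect_equal(mean(hits >= 1), 0.8)
  expect_equal(sum(hits), 0.8 * 100 * 2)
  expect_equal(sort(unique(pl80$truth$seq)), sort(which(hits > 0)))
  # empty design: unchanged
  pl0 <- plant_motifs(bg, "TGCATG", fraction = 0, seed = 1)
  expect_identical(pl0$seqs, bg)
  expect_equal(nrow(pl0$truth), 0)
  expect_error(plant_motifs("ACGT", "ACGTACGT"), "longer")
})

test_that("cohort generator plants recoverable alteration and expression structure", {
  cfg <- sim_config(seed = 31, cohort = list(n_patients = 500, p_amp = 0.05,
                                             p_del = 0.03, p_mut = 0.02))
  ch <- simulate_cohort(cfg, srg_unfavorable_genes)
  # per-gene alteration frequency near design
  freqs <- colMeans(ch$alterations != "none")
  expect_equal(mean(freqs), 0.10, tolerance = 0.03)
  # amp shifts expression by +delta on average
  g <- "SRSF1"
  amp <- ch$alterations[, g] == "amp"; neu <- ch$alterations[, g] == "none"
  expect_equal(mean(ch$expr[g, amp]) - mean(ch$expr[g, neu]), 2, tolerance = 0.3)
  # censoring fraction near target
  expect_equal(mean(ch$clinical$event == 0), 0.30, tolerance = 0.08)
  expect_error(sim_config(cohort = list(censoring = 1.5)), "\\[0, 1\\]")
})

test_that("null-hazard cohorts reject at about the nominal rate under median split", {
  rejected <- vapply(1:100, function(i) {
    cfg <- sim_config(seed = 1000 + i,
                      cohort = list(n_patients = 100, hazard_coef = 0))
    ch <- simulate_cohort(cfg, srg_unfavorable_genes)
    rep <- signature_survival_report(ch$clinical$score, ch$clinical$time,
                                     ch$clinical$event, split = "median")
    rep$logrank$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.005)
  expect_lte(mean(rejected), 0.12)
})
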