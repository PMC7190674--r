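# Configuration-driven end-to-end runs: simulate -> quantify -> call DSEs ->
# score signatures -> survival stratification -> report, plus the
# parameter-recovery suite that checks every planted parameter against its
# downstream estimate.

.config_schema <- list(
  scenario = "character", seed = "numeric",
  events = c("n_events", "n_true", "dpsi", "psi_a", "depth", "n_replicates"),
  thresholds = c("dpsi", "fdr"),
  cohort = c("n_patients", "p_amp", "p_del", "p_mut", "delta",
             "hazard_coef", "baseline_rate", "censoring"),
  out_dir = "character"
)

.suggest_key <- function(key, known) {
  d <- utils::adist(key, known)
  if (min(d) <= 2) sprintf(" (did you mean '%s'?)", known[which.min(d)]) else ""
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML config, rejects unknown keys (with a nearest-key
#' suggestion), and checks value ranges. See the packaged example config
#' \code{system.file("extdata", "smoke.yaml", package = "splicescape")}.
#'
#' @param path Path to a YAML file.
#' @return Validated config list of class \code{run_config}.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_(sprintf("config file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  for (key in names(cfg)) {
    if (!key %in% names(.config_schema)) {
      errs <- c(errs, sprintf("unknown key '%s'%s", key,
                              .suggest_key(key, names(.config_schema))))
      next
    }
    block <- .config_schema[[key]]
    if (length(block) > 1L || !block %in% c("character", "numeric")) {
      for (sub in names(cfg[[key]]))
        if (!sub %in% block)
          errs <- c(errs, sprintf("unknown key '%s.%s'%s", key, sub,
                                  .suggest_key(sub, block)))
    }
  }
  defaults <- list(
    scenario = "smoke", seed = 1L,
    events = list(n_events = 200L, n_true = 20L, dpsi = 0.3, psi_a = 0.4,
                  depth = 200, n_replicates = 3L),
    thresholds = list(dpsi = 0.1, fdr = 0.1),
    cohort = list(n_patients = 40L, p_amp = 0.1, p_del = 0.1, p_mut = 0.02,
                  delta = 2, hazard_coef = log(3), baseline_rate = 0.1,
                  censoring = 0.3),
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, cfg)
  ev <- cfg$events
  if (ev$depth <= 0) errs <- c(errs, "events.depth must be > 0")
  if (ev$n_replicates < 1) errs <- c(errs, "events.n_replicates must be >= 1")
  if (ev$n_true > ev$n_events) errs <- c(errs, "events.n_true exceeds events.n_events")
  if (ev$psi_a + ev$dpsi > 1 || ev$psi_a < 0)
    errs <- c(errs, "events.psi_a + events.dpsi must stay in [0, 1]")
  th <- cfg$thresholds
  if (th$dpsi < 0 || th$dpsi > 1) errs <- c(errs, "thresholds.dpsi must be in [0, 1]")
  if (th$fdr <= 0 || th$fdr > 1) errs <- c(errs, "thresholds.fdr must be in (0, 1]")
  co <- cfg$cohort
  for (p in c("p_amp", "p_del", "p_mut", "censoring"))
    if (co[[p]] < 0 || co[[p]] > 1) errs <- c(errs, sprintf("cohort.%s must be in [0, 1]", p))
  if (co$n_patients < 4) errs <- c(errs, "cohort.n_patients must be >= 4")
  if (length(errs)) stop_("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

.event_config <- function(cfg) {
  ev <- cfg$events
  sim_config(
    seed = cfg$seed,
    event_design = data.frame(
      type = c("IR", "SE"),
      n = c(ev$n_true, ev$n_events - ev$n_true),
      psi_a = ev$psi_a,
      psi_b = c(ev$psi_a + ev$dpsi, ev$psi_a)
    ),
    depth = ev$depth, n_replicates = ev$n_replicates,
    cohort = cfg$cohort
  )
}

#' Run the end-to-end pipeline
#'
#' Simulates a splicing-event truth set and a patient cohort from the
#' config, quantifies PSI and calls DSEs, scores the unfavorable signature,
#' stratifies survival by median split, and (when \code{out_dir} is set)
#' writes stage outputs as TSV plus a JSON report. Deterministic given
#' \code{seed}.
#'
#' @param config A [validate_config()] result (or path to a YAML file).
#' @return Run report (list, class \code{run_report}): one section per
#'   executed stage plus a parameter echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] seed=%d in=%d out=%d", stage, config$seed, n_in, n_out))

  scfg <- .event_config(config)
  truth <- event_truth(scfg)
  counts <- simulate_junction_counts(truth, scfg$depth, scfg$n_replicates,
                                     seed = config$seed)
  log_stage("simulate", nrow(truth), length(counts$groups) * nrow(truth))

  res <- differential_splicing(counts$inclusion, counts$skipping, counts$groups)
  res$type <- truth$type
  res$gene_id <- truth$gene_id
  called <- call_dse(res, config$thresholds$dpsi, config$thresholds$fdr)
  log_stage("quantify", nrow(res), sum(called$called))

  cohort <- simulate_cohort(scfg, srg_unfavorable_genes)
  z <- zscore_vs_reference(cohort$expr)
  sc <- composite_score(z, gene_signature("unfavorable", srg_unfavorable_genes,
                                          "unfavorable"))
  rep_surv <- signature_survival_report(sc$score, cohort$clinical$time,
                                        cohort$clinical$event, split = "median")
  log_stage("survive", nrow(sc), 2L)

  report <- list(
    scenario = config$scenario,
    parameters = unclass(config),
    version = as.character(utils::packageVersion("splicescape")),
    stages = list(
      simulate = list(n_events = nrow(truth), n_samples = length(counts$groups),
                      n_patients = config$cohort$n_patients),
      quantify = list(n_tested = sum(!is.na(res$p)), n_called = sum(called$called),
                      by_type = as.list(table(called$type[called$called]))),
      signature = list(n_samples = nrow(sc), n_genes = sc$n_genes[1],
                       score_range = range(sc$score)),
      survival = list(split = rep_surv$split, p = rep_surv$logrank$p,
                      direction = rep_surv$direction)
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(called, file.path(config$out_dir, "dse_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sc, file.path(config$out_dir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$clinical, file.path(config$out_dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report[names(report) != "elapsed_s"],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Parameter-recovery suite
#'
#' Re-derives every planted generator parameter from the generator's own
#' output through the corresponding downstream estimator and verdicts each
#' against its tolerance: PSI recovery error, DSE sensitivity and false
#' discovery proportion, CNV expression shift, per-gene alteration
#' frequency, and signature survival direction.
#'
#' @param config A [validate_config()] result (or path to YAML).
#' @return data.frame: check, planted, recovered, tolerance, pass.
#' @export
recovery_suite <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  if (config$events$n_replicates < 1L)
    stop_("recovery suite requires at least one replicate per group")
  scfg <- .event_config(config)
  truth <- event_truth(scfg)
  counts <- simulate_junction_counts(truth, scfg$depth, scfg$n_replicates,
                                     seed = config$seed)
  res <- differential_splicing(counts$inclusion, counts$skipping, counts$groups)
  called <- call_dse(res, config$thresholds$dpsi, config$thresholds$fdr)
  is_true <- truth$dpsi != 0
  sens <- if (any(is_true)) mean(called$called[is_true]) else NA_real_
  fdp <- if (sum(called$called)) mean(!is_true[called$called]) else 0
  psi_err <- mean(abs(res$psi_a - truth$psi_a), na.rm = TRUE)

  cohort <- simulate_cohort(scfg, srg_unfavorable_genes)
  g <- srg_unfavorable_genes[1]
  amp <- cohort$alterations[, g] == "amp"
  neu <- cohort$alterations[, g] == "none"
  delta_hat <- if (sum(amp) >= 3)
    mean(cohort$expr[g, amp]) - mean(cohort$expr[g, neu]) else NA_real_
  freq_hat <- mean(cohort$alterations[, g] != "none")
  freq_true <- with(config$cohort, p_amp + p_del + p_mut)

  sc <- composite_score(zscore_vs_reference(cohort$expr),
                        srg_unfavorable_genes)
  dir_ok <- tryCatch(
    signature_survival_report(sc$score, cohort$clinical$time,
                              cohort$clinical$event)$direction == "unfavorable",
    error = function(e) NA)

  checks <- data.frame(
    check = c("psi_recovery_mae", "dse_sensitivity", "dse_fdp",
              "cnv_delta_shift", "alteration_freq", "signature_direction"),
    planted = c(0, 1, 0, config$cohort$delta, freq_true,
                as.numeric(config$cohort$hazard_coef > 0)),
    recovered = c(psi_err, sens, fdp, delta_hat, freq_hat,
                  as.numeric(isTRUE(dir_ok))),
    tolerance = c(0.03, 0.15, 0.15, 0.5, 0.05, 0),
    stringsAsFactors = FALSE
  )
  checks$pass <- abs(checks$recovered - checks$planted) <= checks$tolerance |
    (checks$check %in% c("dse_sensitivity") &
       checks$recovered >= checks$planted - checks$tolerance)
  checks
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("splicescape run '%s' (seed %d)\n", x$scenario, x$parameters$seed))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                paste(names(s), vapply(s, function(v) paste(format(unlist(v), digits = 4), collapse = ","), ""),
                      sep = "=", collapse = "  ")))
  }
  invisible(x)
}
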