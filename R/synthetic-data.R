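# Synthetic cohorts with planted ground truth.
#
# Every downstream stage (PSI quantification, intron feature analysis, motif
# scoring, signatures, survival, alteration statistics) is exercised on data
# generated here, so each generator records the parameters it planted and the
# corresponding estimator must recover them.

#' Simulation configuration
#'
#' Validated container of generator parameters. Defaults define the standard
#' study conditions used throughout the package's tests: 3 replicates per
#' group at read depth 200 per event, cohorts of 200 patients with 10%
#' per-gene alteration probability, a 2 log2-unit expression effect of copy
#' number, a log-hazard of log(3) per SD of composite signature score, and
#' 30% censoring.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_genes Number of genes for annotation simulation.
#' @param exons_per_gene Integer range (length 2) of exons per gene; at least
#'   2 so every gene has introns.
#' @param exon_len,intron_len Length ranges (bp).
#' @param gc_target Target GC fraction of generated sequence.
#' @param event_design data.frame with columns \code{type} (SE/A5/A3/MX/IR),
#'   \code{n} (event count), \code{psi_a}, \code{psi_b} (true group PSI);
#'   NULL for the default mixed design.
#' @param depth Expected junction reads per event (Poisson mean).
#' @param n_replicates Replicates per group.
#' @param cohort List: \code{n_patients}, \code{p_amp}, \code{p_del},
#'   \code{p_mut} (per-gene alteration probabilities), \code{delta}
#'   (log2 expression shift of amp; deletions shift by -delta),
#'   \code{hazard_coef} (log hazard per SD of composite score),
#'   \code{baseline_rate} (exponential baseline hazard),
#'   \code{censoring} (target censored fraction).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(80L, 200L),
                       intron_len = c(100L, 1000L),
                       gc_target = 0.45,
                       event_design = NULL,
                       depth = 200,
                       n_replicates = 3L,
                       cohort = list()) {
  stopifnot(is_count(n_genes), n_genes >= 1)
  exons_per_gene <- as.integer(exons_per_gene)
  if (length(exons_per_gene) != 2L || any(exons_per_gene < 2L) ||
      exons_per_gene[1] > exons_per_gene[2])
    stop_("`exons_per_gene` must be an increasing range with minimum >= 2 (intron-bearing genes)")
  if (any(exon_len <= 0) || any(intron_len <= 0))
    stop_("lengths must be > 0")
  check_prob(gc_target, "gc_target")
  if (depth <= 0) stop_("`depth` must be > 0")
  stopifnot(is_count(n_replicates), n_replicates >= 1)
  if (is.null(event_design)) {
    event_design <- data.frame(
      type = AS_TYPES,
      n = c(60L, 20L, 20L, 10L, 90L),
      psi_a = 0.5, psi_b = 0.5
    )
  }
  stopifnot(all(c("type", "n", "psi_a", "psi_b") %in% names(event_design)))
  if (!all(event_design$type %in% AS_TYPES))
    stop_("event_design types must be among ", paste(AS_TYPES, collapse = "/"))
  check_prob(event_design$psi_a, "psi_a"); check_prob(event_design$psi_b, "psi_b")

  co <- utils::modifyList(list(
    n_patients = 200L, p_amp = 0.10, p_del = 0.10, p_mut = 0.02,
    delta = 2, hazard_coef = log(3), baseline_rate = 0.1, censoring = 0.30
  ), cohort)
  check_prob(co$p_amp, "p_amp"); check_prob(co$p_del, "p_del")
  check_prob(co$p_mut, "p_mut"); check_prob(co$censoring, "censoring")
  if (co$p_amp + co$p_del + co$p_mut > 1)
    stop_("per-gene alteration probabilities must sum to <= 1")
  if (!is.finite(co$hazard_coef)) stop_("hazard_coef out of range")
  if (co$baseline_rate <= 0) stop_("baseline_rate must be > 0")

  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = exons_per_gene, exon_len = exon_len,
    intron_len = intron_len, gc_target = gc_target,
    event_design = event_design, depth = depth,
    n_replicates = as.integer(n_replicates), cohort = co
  ), class = "sim_config")
}

# sample() that never treats a length-1 vector as 1:n
.resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# iid sequence with P(G)=P(C)=gc/2
.random_dna <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate gene annotation and genome sequence
#'
#' Each gene is placed on its own scaffold with alternating exons and introns;
#' introns carry canonical GT...AG boundaries. Coordinates in the returned
#' annotation are 1-based inclusive (GTF convention).
#'
#' @param config A [sim_config()].
#' @return List with \code{annotation} (data.frame: seqnames, start, end,
#'   strand, type = gene/exon, gene_id, transcript_id), \code{genome}
#'   (named \code{Biostrings::DNAStringSet}, one scaffold per gene) and
#'   \code{introns} (data.frame: gene_id, intron start/end 1-based inclusive,
#'   strand).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(config$seed, {
    ann <- list(); intr <- list(); seqs <- character(config$n_genes)
    for (g in seq_len(config$n_genes)) {
      n_ex <- .resample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
      ex_len <- .resample(seq(config$exon_len[1], config$exon_len[2]), n_ex)
      in_len <- .resample(seq(config$intron_len[1], config$intron_len[2]), n_ex - 1L)
      strand <- sample(c("+", "-"), 1L)
      pieces <- character(0); pos <- 1L
      ex_coord <- matrix(0L, n_ex, 2); in_coord <- matrix(0L, n_ex - 1L, 2)
      for (i in seq_len(n_ex)) {
        pieces <- c(pieces, .random_dna(ex_len[i], config$gc_target))
        ex_coord[i, ] <- c(pos, pos + ex_len[i] - 1L)
        pos <- pos + ex_len[i]
        if (i < n_ex) {
          body <- .random_dna(in_len[i] - 4L, config$gc_target)
          # canonical boundaries on the sense strand
          intron_seq <- paste0("GT", body, "AG")
          if (strand == "-")
            intron_seq <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(intron_seq)))
          pieces <- c(pieces, intron_seq)
          in_coord[i, ] <- c(pos, pos + in_len[i] - 1L)
          pos <- pos + in_len[i]
        }
      }
      gene_id <- sprintf("gene_%03d", g)
      seqs[g] <- paste(pieces, collapse = "")
      ann[[g]] <- data.frame(
        seqnames = gene_id,
        start = c(1L, ex_coord[, 1]),
        end = c(pos - 1L, ex_coord[, 2]),
        strand = strand,
        type = c("gene", rep("exon", n_ex)),
        gene_id = gene_id,
        transcript_id = paste0(gene_id, ".t1"),
        stringsAsFactors = FALSE
      )
      if (n_ex > 1L)
        intr[[g]] <- data.frame(
          gene_id = gene_id, start = in_coord[, 1], end = in_coord[, 2],
          strand = strand, stringsAsFactors = FALSE
        )
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("gene_%03d", seq_len(config$n_genes))
    list(annotation = do.call(rbind, ann), genome = genome,
         introns = do.call(rbind, intr))
  })
}

#' Write a simulated annotation as GTF
#'
#' @param annotation data.frame from [generate_annotation()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqnames,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$type,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    source = "splicescape"
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Simulate a splicing event truth set from a design
#'
#' @param config A [sim_config()] whose \code{event_design} gives per-type
#'   event counts and true group PSI values.
#' @return data.frame (the truth set): event_id, type, gene_id, true
#'   \code{psi_a}, \code{psi_b}, \code{dpsi}.
#' @export
event_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$event_design
  truth <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    if (d$n[i] == 0L) return(NULL)
    data.frame(type = d$type[i], psi_a = d$psi_a[i], psi_b = d$psi_b[i],
               stringsAsFactors = FALSE)[rep(1L, d$n[i]), , drop = FALSE]
  }))
  truth$event_id <- sprintf("event_%05d", seq_len(nrow(truth)))
  truth$gene_id <- sprintf("gene_%05d", seq_len(nrow(truth)))
  truth$dpsi <- truth$psi_b - truth$psi_a
  rownames(truth) <- NULL
  truth[, c("event_id", "gene_id", "type", "psi_a", "psi_b", "dpsi")]
}

#' Simulate junction counts for a truth set
#'
#' Per event and sample, the total junction count is Poisson(\code{depth})
#' and the inclusion count is Binomial(total, true PSI of that sample's
#' group); skipping = total - inclusion.
#'
#' @param truth data.frame with \code{event_id}, \code{psi_a}, \code{psi_b}
#'   (e.g. from [event_truth()]).
#' @param depth Expected total reads per event per sample (> 0).
#' @param n_replicates Replicates per group.
#' @param seed Integer seed.
#' @return List with matrices \code{inclusion} and \code{skipping}
#'   (events x samples, rownames = event ids) and a \code{groups} factor
#'   (levels A, B).
#' @export
simulate_junction_counts <- function(truth, depth, n_replicates, seed = 1L) {
  if (depth <= 0) stop_("`depth` must be > 0")
  check_prob(truth$psi_a, "psi_a"); check_prob(truth$psi_b, "psi_b")
  n_ev <- nrow(truth)
  n_s <- 2L * n_replicates
  groups <- factor(rep(c("A", "B"), each = n_replicates))
  psi_true <- cbind(matrix(truth$psi_a, n_ev, n_replicates),
                    matrix(truth$psi_b, n_ev, n_replicates))
  with_seed_(seed, {
    total <- matrix(stats::rpois(n_ev * n_s, depth), n_ev, n_s)
    incl <- matrix(stats::rbinom(n_ev * n_s, total, psi_true), n_ev, n_s)
  })
  skip <- total - incl
  dimnames(incl) <- dimnames(skip) <-
    list(truth$event_id, paste0(rep(c("A", "B"), each = n_replicates),
                                seq_len(n_replicates)))
  list(inclusion = incl, skipping = skip, groups = groups)
}

#' Random background sequences, optionally scrubbed of a motif
#'
#' @param n,len Number and length of sequences.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @param exclude_motif Optional IUPAC motif; generated sequences are
#'   re-drawn at matching positions until motif-free (so later planting is
#'   exact).
#' @return Character vector of sequences.
#' @export
random_sequences <- function(n, len, gc = 0.45, seed = 1L, exclude_motif = NULL) {
  with_seed_(seed, {
    seqs <- vapply(seq_len(n), function(i) .random_dna(len, gc), character(1))
    if (!is.null(exclude_motif)) {
      for (tries in 1:100) {
        hits <- iupac_match_count(exclude_motif, seqs)
        if (all(hits == 0)) break
        seqs[hits > 0] <- vapply(which(hits > 0), function(i)
          .random_dna(len, gc), character(1))
      }
      if (any(iupac_match_count(exclude_motif, seqs) > 0))
        stop_("could not generate motif-free background (motif too permissive)")
    }
    seqs
  })
}

# one concrete realization of an IUPAC motif
.realize_iupac <- function(motif) {
  sets <- .iupac_sets(motif)
  paste(vapply(sets, function(s) sample(s, 1L), character(1)), collapse = "")
}

#' Plant motif occurrences into sequences
#'
#' Inserts concrete realizations of an IUPAC motif at random non-overlapping
#' positions. After insertion each sequence is rescanned; if substitution
#' created matches beyond the planted ones, the insertion is retried so the
#' recorded truth exactly matches a rescan.
#'
#' @param seqs Character vector of sequences.
#' @param motif IUPAC motif string (U allowed; treated as T).
#' @param fraction Fraction of sequences to receive occurrences.
#' @param per_seq Occurrences planted per selected sequence.
#' @param seed Integer seed.
#' @return List with \code{seqs} (modified sequences) and \code{truth}
#'   (data.frame: seq index, planted position (1-based), realization).
#'   \code{fraction = 0} or \code{per_seq = 0} returns the input unchanged
#'   with empty truth.
#' @export
plant_motifs <- function(seqs, motif, fraction = 1, per_seq = 1L, seed = 1L) {
  check_prob(fraction, "fraction")
  stopifnot(is_count(per_seq))
  w <- nchar(motif)
  if (any(nchar(seqs) < w))
    stop_("motif longer than at least one sequence")
  if (fraction == 0 || per_seq == 0L)
    return(list(seqs = seqs, truth = data.frame(
      seq = integer(0), pos = integer(0), realization = character(0))))
  with_seed_(seed, {
    n_sel <- round(fraction * length(seqs))
    chosen <- sample(seq_along(seqs), n_sel)
    truth <- vector("list", length(chosen))
    for (k in seq_along(chosen)) {
      i <- chosen[k]
      base_hits <- iupac_match_count(motif, seqs[i])
      for (try in 1:200) {
        len <- nchar(seqs[i])
        # non-overlapping start positions
        starts <- integer(0); cand <- seq_len(len - w + 1L)
        while (length(starts) < per_seq && length(cand)) {
          s <- sample(cand, 1L)
          starts <- c(starts, s)
          cand <- setdiff(cand, seq(s - w + 1L, s + w - 1L))
        }
        if (length(starts) < per_seq) stop_("sequence too short for requested occurrences")
        new_seq <- seqs[i]
        real <- vapply(starts, function(s) .realize_iupac(motif), character(1))
        for (j in seq_along(starts))
          substr(new_seq, starts[j], starts[j] + w - 1L) <- real[j]
        if (iupac_match_count(motif, new_seq) == base_hits + per_seq) {
          seqs[i] <- new_seq
          truth[[k]] <- data.frame(seq = i, pos = sort(starts),
                                   realization = real[order(starts)],
                                   stringsAsFactors = FALSE)
          break
        }
        if (try == 200) stop_("could not plant motif without creating extra matches")
      }
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
}

# horizon of uniform administrative censoring achieving a target censored
# fraction for the drawn event times (numeric solve; deterministic given T)
.censor_horizon <- function(t_event, target) {
  if (target == 0) return(Inf)
  f <- function(tau) mean(pmin(t_event / tau, 1)) - target
  upper <- max(t_event) * 2
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(min(t_event) / 1e3, upper))$root
}

#' Simulate a patient cohort with alterations, expression and survival
#'
#' Per patient and gene, an alteration call in \{amp, del, mut, none\} is
#' drawn independently; amp/del shift that gene's log2 expression by
#' +delta/-delta on average. Survival times follow an exponential
#' proportional-hazards model whose log hazard is \code{hazard_coef} per SD
#' of the composite signature score (sum of cohort-standardized Z over
#' signature genes); censoring is uniform administrative censoring with the
#' horizon solved to match the configured censored fraction.
#'
#' @param config A [sim_config()]; cohort parameters are in \code{config$cohort}.
#' @param signature_genes Character vector of signature member gene names.
#' @param n_background Extra non-signature genes simulated (default 30).
#' @return List: \code{expr} (genes x patients log2 matrix),
#'   \code{alterations} (patients x genes character matrix),
#'   \code{clinical} (data.frame: patient, time, event, gleason, score),
#'   \code{truth} (planted parameters incl. per-patient true hazard).
#' @export
simulate_cohort <- function(config, signature_genes, n_background = 30L) {
  stopifnot(inherits(config, "sim_config"))
  co <- config$cohort
  genes <- unique(c(signature_genes, sprintf("bg_%03d", seq_len(n_background))))
  n_p <- co$n_patients; n_g <- length(genes)
  with_seed_(config$seed, {
    calls <- matrix(sample(c("amp", "del", "mut", "none"), n_p * n_g,
                           replace = TRUE,
                           prob = c(co$p_amp, co$p_del, co$p_mut,
                                    1 - co$p_amp - co$p_del - co$p_mut)),
                    n_p, n_g, dimnames = list(sprintf("pt_%03d", seq_len(n_p)), genes))
    base_mu <- stats::rnorm(n_g, mean = 8, sd = 1)
    expr <- matrix(stats::rnorm(n_g * n_p, base_mu, 1), n_g, n_p,
                   dimnames = list(genes, rownames(calls)))
    expr <- expr + t(ifelse(calls == "amp", co$delta,
                            ifelse(calls == "del", -co$delta, 0)))
    z <- zscore_vs_reference(expr)
    score <- composite_score(z, gene_signature("sim", signature_genes))$score
    zs <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0
    hazard <- co$baseline_rate * exp(co$hazard_coef * zs)
    t_event <- stats::rexp(n_p, rate = hazard)
    tau <- .censor_horizon(t_event, co$censoring)
    c_time <- if (is.finite(tau)) stats::runif(n_p, 0, tau) else rep(Inf, n_p)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    gleason <- sample(6:10, n_p, replace = TRUE,
                      prob = c(0.25, 0.40, 0.20, 0.10, 0.05))
    clinical <- data.frame(
      patient = rownames(calls), time = time, event = event,
      gleason = gleason, score = score, stringsAsFactors = FALSE
    )
    list(expr = expr, alterations = calls, clinical = clinical,
         truth = list(hazard = hazard, hazard_coef = co$hazard_coef,
                      delta = co$delta,
                      p_amp = co$p_amp, p_del = co$p_del, p_mut = co$p_mut,
                      censor_horizon = tau))
  })
}
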