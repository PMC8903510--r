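# Multi-plex TMT experiment simulator with a known ground truth.
#
# Emulates the reference study design: four 10-plexes, each with 8
# individual patient channels (control / PDR), one validation-pool aliquot
# and one pooled bridge channel used as the reference, plus per-protein
# phenotype effects, per-plex batch shifts, two dropout mechanisms, and a
# minority of annotated plasma / erythroid proteins.

#' Simulation configuration
#'
#' All tunables of the synthetic multi-plex TMT generator, with defaults
#' emulating the reference vitreous study design: 4 x 10-plex, 10 control
#' and 22 PDR individuals, a pooled bridge (reference) channel and a
#' validation-pool channel per plex.
#'
#' @param n_plexes number of TMT plexes (default 4).
#' @param channels_per_plex reporter channels per plex (default 10).
#' @param n_ctl,n_pdr individually analyzed control / PDR samples
#'   (defaults 10 and 22); must fit the per-plex budget of
#'   `channels_per_plex - 2` individual channels.
#' @param n_proteins number of simulated protein entries (default 1157).
#' @param peptides_per_protein mean peptides per protein (counts are
#'   `1 + Poisson(mean - 1)`; default 3).
#' @param psms_per_peptide mean PSMs per peptide per plex (default 1.5).
#' @param n_runs MS runs (fractions) per plex (default 2).
#' @param pi0 fraction of null proteins (no phenotype effect; default 0.25).
#' @param effect_size_sd SD of the standardized effect (Hedges'-g scale) for
#'   non-null proteins, drawn `N(0, effect_size_sd)` (default 3.0).
#' @param protein_sd between-sample biological SD, log2 scale (default 0.35).
#' @param tech_sd PSM-level reporter noise SD per channel, log2 scale
#'   (default 0.2).
#' @param psm_sd PSM-to-PSM loading offset SD, log2 (cancels in ratios;
#'   default 0.5).
#' @param plex_shift_sd per-plex per-protein additive log2 batch shift SD,
#'   applied to every channel of the plex including the reference
#'   (default 0.3).
#' @param baseline_mean,baseline_sd log2-normal protein baseline abundance
#'   parameters (defaults 16 and 2.2).
#' @param purity_shape1,purity_shape2 Beta parameters of precursor purity
#'   (defaults 5 and 1.5).
#' @param frac_unlabeled fraction of PSMs without a TMT label (default 0.01).
#' @param frac_contaminant fraction of extra PSMs mapping to external
#'   contaminant proteins (default 0.01).
#' @param interplex_dropout_rate probability a protein is wholly absent from
#'   at least one plex (default 390/1157).
#' @param intraplex_dropout_rate probability a protein is missing for a
#'   strict subset of samples within one plex (default 40/1157).
#' @param n_plasma,n_rbc sizes of the plasma / erythroid annotation sets
#'   (defaults 23 and 7); plasma proteins get no phenotype effect, erythroid
#'   proteins get a PDR-specific additive upshift.
#' @param rbc_pdr_upshift log2 upshift of erythroid proteins in PDR samples
#'   (default 2).
#' @param ms1_meanlog,ms1_sdlog log-normal MS1 precursor intensity
#'   parameters (defaults `log(1e7)` and 1).
#' @param seed master seed; per-plex substreams are derived from it so that
#'   adding a plex never perturbs earlier plexes.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_plexes = 4, channels_per_plex = 10,
                       n_ctl = 10, n_pdr = 22,
                       n_proteins = 1157,
                       peptides_per_protein = 3, psms_per_peptide = 1.5,
                       n_runs = 2,
                       pi0 = 0.25, effect_size_sd = 3.0,
                       protein_sd = 0.35, tech_sd = 0.2, psm_sd = 0.5,
                       plex_shift_sd = 0.3,
                       baseline_mean = 16, baseline_sd = 2.2,
                       purity_shape1 = 5, purity_shape2 = 1.5,
                       frac_unlabeled = 0.01, frac_contaminant = 0.01,
                       interplex_dropout_rate = 390 / 1157,
                       intraplex_dropout_rate = 40 / 1157,
                       n_plasma = 23, n_rbc = 7, rbc_pdr_upshift = 2,
                       ms1_meanlog = log(1e7), ms1_sdlog = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  rates <- c(pi0 = pi0, frac_unlabeled = frac_unlabeled,
             frac_contaminant = frac_contaminant,
             interplex = interplex_dropout_rate,
             intraplex = intraplex_dropout_rate)
  if (any(rates < 0 | rates > 1)) pb_stop("config_error", "rates must lie in [0,1]")
  if (interplex_dropout_rate + intraplex_dropout_rate > 1) {
    pb_stop("config_error", "dropout rates must sum to <= 1")
  }
  if (n_ctl + n_pdr > n_plexes * (channels_per_plex - 2)) {
    pb_stop("config_error",
            "channel budget exceeded: %d individuals > %d slots",
            n_ctl + n_pdr, n_plexes * (channels_per_plex - 2))
  }
  if (n_proteins < n_plasma + n_rbc) {
    pb_stop("config_error", "n_proteins smaller than annotation sets")
  }
  stopifnot(n_proteins > 0, peptides_per_protein >= 1, psms_per_peptide >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic layout of individuals, pools and channels; no RNG
sim_design <- function(cfg) {
  capacity <- cfg$channels_per_plex - 2
  ctl_ids <- sprintf("CTL%02d", seq_len(cfg$n_ctl))
  pdr_ids <- sprintf("PDR%02d", seq_len(cfg$n_pdr))
  # controls round-robin over plexes, PDR fills the remaining slots
  plex_ids <- sprintf("plex%d", seq_len(cfg$n_plexes))
  slots <- rep(capacity, cfg$n_plexes)
  assign_plex <- integer(cfg$n_ctl + cfg$n_pdr)
  k <- 1
  for (i in seq_len(cfg$n_ctl)) {
    while (slots[k] == 0) k <- k %% cfg$n_plexes + 1
    assign_plex[i] <- k; slots[k] <- slots[k] - 1
    k <- k %% cfg$n_plexes + 1
  }
  for (i in seq_len(cfg$n_pdr)) {
    k2 <- which(slots > 0)[1]
    assign_plex[cfg$n_ctl + i] <- k2; slots[k2] <- slots[k2] - 1
  }
  channels <- c("126", "127N", "127C", "128N", "128C",
                "129N", "129C", "130N", "130C", "131")
  if (cfg$channels_per_plex != 10) {
    channels <- sprintf("ch%02d", seq_len(cfg$channels_per_plex))
  }
  rows <- list()
  ids <- c(ctl_ids, pdr_ids)
  phen <- c(rep("CTL", cfg$n_ctl), rep("PDR", cfg$n_pdr))
  for (p in seq_len(cfg$n_plexes)) {
    here <- which(assign_plex == p)
    here <- here[order(phen[here], ids[here])]
    n_here <- length(here)
    rows[[p]] <- data.frame(
      plex_id = plex_ids[p],
      channel = channels[seq_len(n_here + 2)],
      sample_id = c(ids[here], sprintf("pool1.%d", p), sprintf("pool2.%d", p)),
      role = c(rep("individual", n_here), "validation_pool", "reference"),
      phenotype = c(phen[here], NA, NA),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  plex_design(d$plex_id, d$channel, d$sample_id, d$role, d$phenotype)
}

# hemoglobin concentration bands; subphenotype mix follows the reference
# cohort proportions (10 L : 6 M : 6 H of 22 PDR samples)
sim_clinical <- function(cfg, design) {
  ind <- design[design$role == "individual", , drop = FALSE]
  pdr <- ind$sample_id[ind$phenotype == "PDR"]
  n <- length(pdr)
  n_l <- round(n * 10 / 22); n_m <- round(n * 6 / 22)
  n_h <- n - n_l - n_m
  sub <- rep(c("L", "M", "H"), times = c(n_l, n_m, n_h))[seq_len(n)]
  hb <- numeric(n)
  for (i in seq_len(n)) {
    band <- HB_BANDS[[sub[i]]]
    hb[i] <- stats::runif(1, band[1], band[2])
  }
  data.frame(
    sample_id = ind$sample_id,
    phenotype = ind$phenotype,
    hemoglobin = ifelse(ind$phenotype == "PDR",
                        hb[match(ind$sample_id, pdr)], NA_real_),
    bilirubin = ifelse(ind$phenotype == "PDR",
                       stats::runif(nrow(ind), 0.002, 0.009), NA_real_),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-plex TMT experiment
#'
#' Generates PSM-level quantification tables for every plex of the
#' configured design, together with the plex design, clinical annotations
#' (hemoglobin drawn per subphenotype band) and the per-protein ground
#' truth.  The model: protein baselines are log2-normal; PDR samples carry
#' the protein's true log2 fold change; pooled bridge (reference) and
#' validation channels are exact linear mixtures of the simulated
#' individual-sample true abundances (all individuals and controls only,
#' respectively) before technical noise; every channel of a plex, including
#' the reference, receives the same per-plex per-protein additive log2
#' shift (invisible in ratio space); reporter intensities add peptide-,
#' PSM- and channel-level log2-normal noise; inter- and intra-plex dropout
#' are injected after quantification according to each protein's dropout
#' class.  Deterministic for a fixed seed, with an independent substream
#' per plex.
#'
#' @param cfg a [sim_config()].
#' @return list with `psms` (canonical PSM `data.frame`, all plexes),
#'   `design` (`plex_design`), `clinical`, and `truth` (list with the
#'   per-protein `truth` table, `plex_shifts`, and the true sample
#'   abundance matrix `x_true`).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  design <- sim_design(cfg)
  plexes <- unique(design$plex_id)
  np <- cfg$n_proteins

  ## substream 0: protein-level truth
  set.seed(pb_substream_seed(cfg$seed, 0L))
  sets <- blood_protein_sets()
  plasma_ids <- rep_len(sets$plasma, cfg$n_plasma)
  if (cfg$n_plasma > length(sets$plasma)) {
    plasma_ids <- make.unique(plasma_ids)
  }
  rbc_ids <- rep_len(sets$rbc, cfg$n_rbc)
  if (cfg$n_rbc > length(sets$rbc)) rbc_ids <- make.unique(rbc_ids)
  other_n <- np - cfg$n_plasma - cfg$n_rbc
  entry_ids <- c(if (cfg$n_plasma) plasma_ids, if (cfg$n_rbc) rbc_ids,
                 sprintf("PROT%04d", seq_len(other_n)))
  annotation <- c(rep("plasma", cfg$n_plasma), rep("rbc", cfg$n_rbc),
                  rep("other", other_n))

  baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
  is_null <- stats::runif(np) < cfg$pi0
  true_g <- ifelse(is_null, 0, stats::rnorm(np, 0, cfg$effect_size_sd))
  # annotated blood proteins override the generic effect model
  is_null[annotation == "plasma"] <- TRUE
  true_g[annotation == "plasma"] <- 0
  is_null[annotation == "rbc"] <- FALSE
  true_g[annotation == "rbc"] <- cfg$rbc_pdr_upshift / cfg$protein_sd
  true_log2fc <- true_g * cfg$protein_sd

  u <- stats::runif(np)
  dropout_class <- ifelse(u < cfg$intraplex_dropout_rate, "intraplex",
                   ifelse(u < cfg$intraplex_dropout_rate +
                              cfg$interplex_dropout_rate, "interplex",
                          "complete"))
  # realized dropout structure
  dropped_plexes <- vector("list", np)       # interplex: whole plexes absent
  intraplex_plex <- rep(NA_integer_, np)     # intraplex: one plex,
  intraplex_channels <- vector("list", np)   #   strict channel subset missing
  n_nonref <- cfg$channels_per_plex - 1
  for (i in which(dropout_class == "interplex")) {
    k <- sample.int(cfg$n_plexes - 1L, 1L)
    dropped_plexes[[i]] <- sort(sample.int(cfg$n_plexes, k))
  }
  for (i in which(dropout_class == "intraplex")) {
    intraplex_plex[i] <- sample.int(cfg$n_plexes, 1L)
    k <- sample.int(n_nonref - 1L, 1L)
    intraplex_channels[[i]] <- sort(sample.int(n_nonref, k))
  }
  plex_shifts <- matrix(stats::rnorm(np * cfg$n_plexes, 0, cfg$plex_shift_sd),
                        np, cfg$n_plexes,
                        dimnames = list(entry_ids, plexes))

  # peptide catalogue (shared across plexes)
  npep <- 1L + stats::rpois(np, cfg$peptides_per_protein - 1)
  pep_protein <- rep(seq_len(np), npep)
  n_pep <- length(pep_protein)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  pep_seq <- make.unique(vapply(seq_len(n_pep), function(i) {
    paste0(paste(sample(aa, 6 + i %% 7, replace = TRUE), collapse = ""), "K")
  }, character(1)), sep = "_")
  pep_offset <- stats::rnorm(n_pep, 0, 1)
  pep_ms1 <- stats::rlnorm(n_pep, cfg$ms1_meanlog, cfg$ms1_sdlog)

  ## substream 1: clinical + per-sample biological effects
  set.seed(pb_substream_seed(cfg$seed, 1L))
  clinical <- sim_clinical(cfg, design)
  ind <- design[design$role == "individual", , drop = FALSE]
  sample_ids <- ind$sample_id
  x_true <- matrix(0, np, length(sample_ids),
                   dimnames = list(entry_ids, sample_ids))
  for (s in seq_along(sample_ids)) {
    eff <- if (ind$phenotype[s] == "PDR") true_log2fc else 0
    x_true[, s] <- baseline + eff + stats::rnorm(np, 0, cfg$protein_sd)
  }
  # pooled channels: exact linear mixtures of the true abundances
  ref_true <- log2(rowMeans(2^x_true))
  ctl_cols <- which(ind$phenotype == "CTL")
  pool1_true <- if (length(ctl_cols)) {
    log2(rowMeans(2^x_true[, ctl_cols, drop = FALSE]))
  } else ref_true

  ## per-plex substreams: PSM emission
  psm_list <- vector("list", cfg$n_plexes)
  for (p in seq_len(cfg$n_plexes)) {
    set.seed(pb_substream_seed(cfg$seed, 1L + p))
    psm_list[[p]] <- sim_plex_psms(
      cfg, p, plexes[p], design, entry_ids, x_true, ref_true, pool1_true,
      plex_shifts[, p], pep_protein, pep_seq, pep_offset, pep_ms1,
      dropped_plexes, intraplex_plex, intraplex_channels)
  }
  psms <- do.call(rbind, psm_list)
  rownames(psms) <- NULL

  truth <- data.frame(entry_id = entry_ids,
                      true_log2fc = true_log2fc, is_null = is_null,
                      true_g = true_g, dropout_class = dropout_class,
                      annotation = annotation, stringsAsFactors = FALSE)
  list(psms = psms, design = design, clinical = clinical,
       truth = list(truth = truth, plex_shifts = plex_shifts,
                    x_true = x_true, ref_true = ref_true,
                    pool1_true = pool1_true))
}

# emit the PSM table of one plex (vectorized over PSMs x channels)
sim_plex_psms <- function(cfg, p, plex, design, entry_ids, x_true, ref_true,
                          pool1_true, shift_p, pep_protein, pep_seq,
                          pep_offset, pep_ms1, dropped_plexes,
                          intraplex_plex, intraplex_channels) {
  np <- cfg$n_proteins
  present <- rep(TRUE, np)
  for (i in seq_len(np)) {
    if (p %in% dropped_plexes[[i]]) present[i] <- FALSE
  }
  pep_here <- which(present[pep_protein])
  n_psm_per_pep <- 1L + stats::rpois(length(pep_here), cfg$psms_per_peptide - 1)
  pep_row <- rep(pep_here, n_psm_per_pep)
  prot_row <- pep_protein[pep_row]
  n_psm <- length(pep_row)

  d <- design[design$plex_id == plex, , drop = FALSE]
  n_chan <- nrow(d)
  # truth per channel: individuals from x_true, pools from exact mixtures
  chan_truth <- matrix(0, np, n_chan)
  for (ci in seq_len(n_chan)) {
    chan_truth[, ci] <- switch(d$role[ci],
      individual = x_true[, d$sample_id[ci]],
      validation_pool = pool1_true,
      bridge_pool = ref_true,
      reference = ref_true)
  }

  run <- sprintf("%s_run%d", plex, sample.int(cfg$n_runs, n_psm, replace = TRUE))
  charge <- sample(2:3, n_psm, replace = TRUE)
  psm_off <- stats::rnorm(n_psm, 0, cfg$psm_sd)
  ms1 <- pep_ms1[pep_row] * stats::rlnorm(n_psm, 0, 0.3)
  purity <- stats::rbeta(n_psm, cfg$purity_shape1, cfg$purity_shape2)
  labeled <- stats::runif(n_psm) >= cfg$frac_unlabeled

  log2_int <- chan_truth[prot_row, , drop = FALSE] +
    shift_p[prot_row] + pep_offset[pep_row] + psm_off +
    matrix(stats::rnorm(n_psm * n_chan, 0, cfg$tech_sd), n_psm, n_chan)
  reporter <- 2^log2_int
  reporter[!labeled, ] <- NA_real_

  # intraplex dropout: chosen non-reference channels go missing for all
  # PSMs of the protein in this plex
  nonref_idx <- which(d$role != "reference")
  for (i in which(intraplex_plex == p)) {
    rows <- prot_row == i
    if (any(rows)) {
      reporter[rows, nonref_idx[intraplex_channels[[i]]]] <- NA_real_
    }
  }

  psm <- data.frame(plex = plex, run = run,
                    spectrum = sprintf("%s.%06d", plex, seq_len(n_psm)),
                    peptide = pep_seq[pep_row], charge = charge,
                    entry = entry_ids[prot_row],
                    assignment = ifelse(stats::runif(n_psm) < 0.85,
                                        "unique", "razor"),
                    contaminant = FALSE, tmt_labeled = labeled,
                    ms1_intensity = ms1, purity = purity,
                    probability = stats::runif(n_psm, 0.9, 1),
                    stringsAsFactors = FALSE)
  colnames(reporter) <- psm_reporter_cols(n_chan)
  psm <- cbind(psm, as.data.frame(reporter))

  # external contaminant PSMs (removed by the contaminant filter rule)
  n_cont <- round(cfg$frac_contaminant * n_psm)
  if (n_cont > 0) {
    cont_rep <- 2^matrix(stats::rnorm(n_cont * n_chan, cfg$baseline_mean, 1),
                         n_cont, n_chan)
    colnames(cont_rep) <- psm_reporter_cols(n_chan)
    cont <- data.frame(plex = plex,
                       run = sprintf("%s_run%d", plex,
                                     sample.int(cfg$n_runs, n_cont, TRUE)),
                       spectrum = sprintf("%s.c%05d", plex, seq_len(n_cont)),
                       peptide = sprintf("CONTPEP%03d", seq_len(n_cont)),
                       charge = 2L,
                       entry = sprintf("CONTAM%d", 1L + (seq_len(n_cont) %% 3L)),
                       assignment = "unique", contaminant = TRUE,
                       tmt_labeled = TRUE,
                       ms1_intensity = stats::rlnorm(n_cont, cfg$ms1_meanlog,
                                                     cfg$ms1_sdlog),
                       purity = stats::rbeta(n_cont, cfg$purity_shape1,
                                             cfg$purity_shape2),
                       probability = stats::runif(n_cont, 0.9, 1),
                       stringsAsFactors = FALSE)
    psm <- rbind(psm, cbind(cont, as.data.frame(cont_rep)))
  }
  psm
}

#' Tabulate the simulation ground truth
#'
#' @param truth the `truth` element returned by [simulate_experiment()].
#' @return per-protein `data.frame` (`entry_id`, `true_log2fc`, `is_null`,
#'   `true_g`, `dropout_class`, `annotation`) joinable to DE and effect-size
#'   outputs by `entry_id`.
#' @export
truth_summary <- function(truth) {
  if (is.data.frame(truth)) truth else truth$truth
}
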