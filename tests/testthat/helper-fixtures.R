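# Shared fixture builders.  All synthetic; nothing is read from disk except
# the packaged cohort table.

# minimal design: one or more 10-channel plexes, channel 10 = reference,
# channel 9 = validation pool, channels 1..8 individuals
toy_design <- function(n_plexes = 1, n_channels = 10) {
  rows <- lapply(seq_len(n_plexes), function(p) {
    n_ind <- n_channels - 2
    data.frame(
      plex_id = paste0("plex", p),
      channel = sprintf("ch%02d", seq_len(n_channels)),
      sample_id = c(sprintf("p%d_s%d", p, seq_len(n_ind)),
                    sprintf("pool1.%d", p), sprintf("pool2.%d", p)),
      role = c(rep("individual", n_ind), "validation_pool", "reference"),
      phenotype = c(rep(c("CTL", "PDR"), length.out = n_ind), NA, NA),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  plex_design(d$plex_id, d$channel, d$sample_id, d$role, d$phenotype)
}

# build a canonical PSM data.frame from per-PSM reporter rows
toy_psms <- function(reporters, plex = "plex1", entry = "G1", peptide = "PEPK",
                     run = "r1", charge = 2L, purity = 1, ms1 = 100,
                     labeled = TRUE, contaminant = FALSE, spectrum = NULL) {
  reporters <- if (is.matrix(reporters)) reporters else matrix(reporters, nrow = 1)
  n <- nrow(reporters)
  rec <- function(x) rep_len(x, n)
  df <- data.frame(plex = rec(plex), run = rec(run),
                   spectrum = spectrum %||% sprintf("sp%05d", seq_len(n)),
                   peptide = rec(peptide), charge = rec(charge),
                   entry = rec(entry), assignment = "unique",
                   contaminant = rec(contaminant), tmt_labeled = rec(labeled),
                   ms1_intensity = rec(ms1), purity = rec(purity),
                   probability = 0.99, stringsAsFactors = FALSE)
  colnames(reporters) <- paste0("reporter_", seq_len(ncol(reporters)))
  cbind(df, as.data.frame(reporters))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Straight-line transcription of the normalization formula chain, kept
# deliberately independent of the production code path: explicit loops,
# no shared helpers.  Input: ratio matrix R (entries x samples), per-entry
# reference intensities REF.  Output: normalized ratios and abundances.
oracle_normalize <- function(R, REF = NULL) {
  n <- ncol(R); p <- nrow(R)
  M <- numeric(n); MAD <- numeric(n)
  RC <- R
  for (i in seq_len(n)) {
    M[i] <- stats::median(R[, i], na.rm = TRUE)
    RC[, i] <- R[, i] - M[i]
    MAD[i] <- stats::median(abs(RC[, i]), na.rm = TRUE)
  }
  M0 <- stats::median(M)
  MAD0 <- stats::median(MAD)
  RN <- R
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      RN[j, i] <- (RC[j, i] / MAD[i]) * MAD0 + M0
    }
  }
  A <- NULL
  if (!is.null(REF)) {
    A <- RN
    for (j in seq_len(p)) A[j, ] <- RN[j, ] + log2(REF[j])
  }
  list(RN = RN, A = A, M = M, MAD = MAD, M0 = M0, MAD0 = MAD0)
}

# generator configuration with no PSM-level quality losses: every emitted
# PSM survives filtering, so realized missingness equals injected dropout
lossless_config <- function(...) {
  sim_config(purity_shape1 = 60, purity_shape2 = 1, frac_unlabeled = 0,
             frac_contaminant = 0, ...)
}

run_lossless_pipeline <- function(sim, level = "gene") {
  normalize_plexes(sim$psms, sim$design, level = level,
                   intensity_percentile = 0)
}
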