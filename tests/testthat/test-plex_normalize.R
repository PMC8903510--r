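# Ratio construction, IQR trimming, summarization, MAD scaling,
# reference intensities and abundance assembly.

test_that("ratios are log2 channel minus log2 reference", {
  design <- toy_design()
  rep <- c(400, rep(100, 9))        # channel 1 = 400, reference (ch10) = 100
  r <- compute_ratios(toy_psms(rep), design)
  obs <- r$observations
  expect_equal(obs$ratio[obs$sample_id == "p1_s1"], 2)         # log2(4)
  expect_equal(obs$ratio[obs$sample_id == "p1_s2"], 0)         # equal to ref
  expect_equal(nrow(obs), 9)
})

test_that("missing and zero channel intensities yield missing observations", {
  design <- toy_design()
  rep <- c(NA, 0, rep(100, 8))
  r <- compute_ratios(toy_psms(rep), design)
  expect_equal(nrow(r$observations), 7)
  # zero reference: PSM skipped and counted
  rep0 <- c(rep(100, 9), 0)
  r0 <- compute_ratios(toy_psms(rep0), design)
  expect_equal(nrow(r0$observations), 0)
  expect_equal(r0$n_zero_reference, 1)
})

test_that("iqr_trim matches hand-computed boundaries", {
  expect_equal(iqr_trim(c(-0.1, 0, 0.1, 0.2, 2.0)), c(-0.1, 0, 0.1, 0.2))
  expect_equal(iqr_trim(5), 5)
  expect_equal(iqr_trim(c(0, 0, 0, 0, 10)), c(0, 0, 0, 0))
  expect_error(iqr_trim(numeric(0)), class = "domain_error")
})

test_that("summarization takes the median of trimmed ratios per cell", {
  design <- toy_design(2)
  mk <- function(vals, plex, sp) {
    # PSMs whose channel-1 ratio to reference is exactly `vals`
    do.call(rbind, lapply(seq_along(vals), function(i) {
      toy_psms(c(100 * 2^vals[i], rep(100, 9)), plex = plex,
               spectrum = sprintf("%s%02d", sp, i), run = paste0("r", i))
    }))
  }
  psms <- rbind(mk(c(0, 0.1, 0.3), "plex1", "a"),   # odd count -> 0.1
                mk(c(0, 0.2), "plex2", "b"))        # even count -> 0.1
  rm_ <- summarize_entry(compute_ratios(psms, design), design)
  expect_equal(unname(rm_["G1", "p1_s1"]), 0.1)
  expect_equal(unname(rm_["G1", "p2_s1"]), 0.1)
  # channels with only reference-equal PSMs summarize to 0
  expect_equal(unname(rm_["G1", "p1_s2"]), 0)
})

test_that("entries absent from a plex give wholly missing columns there", {
  design <- toy_design(2)
  psms <- toy_psms(matrix(c(1:10) * 10, nrow = 1), plex = "plex1")
  rm_ <- summarize_entry(compute_ratios(psms, design), design)
  plex2_cols <- validate_design(design)$samples[10:18]
  expect_true(all(is.na(rm_["G1", plex2_cols])))
  expect_true(all(!is.na(rm_["G1", validate_design(design)$samples[1:9]])))
})

test_that("MAD normalization reproduces the worked two-sample example", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out <- mad_normalize(quant_matrix(m, "gene", "ratio"))
  expect_equal(unname(out$params$M_i), c(2, 4))
  expect_equal(unname(out$params$MAD_i), c(1, 2))
  expect_equal(out$params$M_0, 3)
  expect_equal(out$params$MAD_0, 1.5)
  expect_equal(unname(unclass(out$normalized)),
               matrix(c(1.5, 3, 4.5, 1.5, 3, 4.5), ncol = 2),
               ignore_attr = TRUE)
  # single sample: identity transform
  single <- mad_normalize(quant_matrix(m[, 1, drop = FALSE], "gene", "ratio"))
  expect_equal(unname(unclass(single$normalized)[, 1]), c(1, 2, 3))
})

test_that("every normalized sample has median M0 and MAD MAD0 exactly", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  m[sample(200, 30)] <- NA
  m[, 1] <- abs(m[, 1]) + 0.1  # keep every column nonempty
  out <- mad_normalize(quant_matrix(m, "gene", "ratio"))
  rn <- unclass(out$normalized)
  meds <- apply(rn, 2, median, na.rm = TRUE)
  mads <- apply(abs(sweep(rn, 2, meds)), 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(out$params$M_0, 10))
  expect_equal(unname(mads), rep(out$params$MAD_0, 10))
  # strictly increasing affine map preserves within-sample ranks
  for (j in 1:10) {
    expect_identical(rank(rn[, j], na.last = "keep"),
                     rank(m[, j], na.last = "keep"))
  }
})

test_that("zero-MAD samples fall back to unit scale with a warning", {
  m <- matrix(c(1, 1, 1, 0, 1, 2), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("flat", "ok")))
  expect_warning(out <- mad_normalize(quant_matrix(m, "gene", "ratio")),
                 "MAD is zero")
  expect_equal(out$params$flagged_samples, "flat")
})

test_that("reference intensity takes the top-3 MS1 weighted shares", {
  design <- toy_design()
  # 4 PSMs, MS1 100/80/60/40; reference shares 0.1/0.2/0.3/0.4 of summed TMT
  share <- c(0.1, 0.2, 0.3, 0.4)
  rep4 <- t(vapply(share, function(w) c(rep((1 - w) * 100 / 9, 9), w * 100),
                   numeric(10)))
  psms <- toy_psms(rep4, ms1 = c(100, 80, 60, 40),
                   peptide = sprintf("PEP%dK", 1:4),
                   spectrum = sprintf("s%d", 1:4))
  ref <- reference_intensity(psms, design)
  expect_equal(unname(ref$REF_ik["G1", "plex1"]), 10 + 16 + 18)
  # single PSM: MS1 100, ref 50 of 200 summed
  one <- toy_psms(c(rep(150 / 9, 9), 50), ms1 = 100)
  expect_equal(unname(reference_intensity(one, design)$REF_ik["G1", "plex1"]),
               25)
})

test_that("missing plexes are imputed with the global minimum before averaging", {
  design <- toy_design(2)
  # entry A only in plex1 with REF 44; entry B in both with REF 4 and 4
  mk_ref <- function(entry, plex, ms1, share, sp) {
    toy_psms(c(rep((1 - share) * 100 / 9, 9), share * 100), entry = entry,
             plex = plex, ms1 = ms1, peptide = paste0(entry, "K"),
             spectrum = sp)
  }
  psms <- rbind(mk_ref("A", "plex1", 100, 0.44, "s1"),
                mk_ref("B", "plex1", 100, 0.04, "s2"),
                mk_ref("B", "plex2", 100, 0.04, "s3"))
  ref <- reference_intensity(psms, design)
  expect_equal(unname(ref$global_min), 4)
  expect_equal(unname(ref$REF_i["A"]), (44 + 4) / 2)
  expect_equal(unname(ref$REF_i["B"]), 4)
})

test_that("abundances add log2 reference intensity and preserve missingness", {
  rn <- quant_matrix(matrix(c(1.5, NA), 1, 2,
                            dimnames = list("G1", c("s1", "s2"))),
                     "gene", "normalized_ratio")
  a <- assemble_abundance(rn, c(G1 = 2))
  expect_equal(unname(unclass(a)["G1", "s1"]), 2.5)
  expect_true(is.na(unclass(a)["G1", "s2"]))
  ident <- assemble_abundance(rn, c(G1 = 1))
  expect_equal(unname(unclass(ident)["G1", "s1"]), 1.5)
})

test_that("plex-wide multiplicative reporter shifts cancel in ratio space", {
  sim <- simulate_experiment(lossless_config(n_proteins = 60, seed = 5))
  shifted <- sim$psms
  rep_cols <- paste0("reporter_", 1:10)
  sel <- shifted$plex == "plex2"
  shifted[sel, rep_cols] <- shifted[sel, rep_cols] * 7.3
  base <- normalize_plexes(sim$psms, sim$design, intensity_percentile = 0)
  shft <- normalize_plexes(shifted, sim$design, intensity_percentile = 0)
  expect_equal(unclass(base$ratio)[, ], unclass(shft$ratio)[, ],
               tolerance = 1e-12)
  expect_equal(unclass(base$normalized)[, ], unclass(shft$normalized)[, ],
               tolerance = 1e-12)
})

test_that("production normalization matches the straight-line oracle", {
  set.seed(11)
  for (case in 1:25) {
    p <- sample(2:5, 1); n <- sample(2:5, 1)
    m <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("g%d", 1:p), sprintf("s%d", 1:n)))
    REF <- stats::setNames(stats::runif(p, 0.5, 20), rownames(m))
    prod <- mad_normalize(quant_matrix(m, "gene", "ratio"))
    orac <- oracle_normalize(m, REF)
    expect_equal(unclass(prod$normalized)[, ], orac$RN[, ], tolerance = 1e-12)
    a <- assemble_abundance(prod$normalized, REF)
    expect_equal(unclass(a)[, ], orac$A[, ], tolerance = 1e-12)
  }
})
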