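# Correlation, PCA, clustering, Z-scores, dropout classes, subphenotypes,
# blood annotation.

toy_abundance <- function(m) {
  quant_matrix(m, level = "gene", kind = "abundance")
}

test_that("Spearman matrix handles ranks, ties and rank invariance", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 3, 1, 2), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  cc <- spearman_matrix(toy_abundance(m))
  expect_equal(unname(cc["s1", "s2"]), 1)
  expect_equal(unname(cc["s1", "s3"]), -0.5)
  expect_true(isSymmetric(cc))
  # strictly increasing transform leaves correlations unchanged
  m2 <- m; m2[, 1] <- exp(m2[, 1])
  cc2 <- spearman_matrix(toy_abundance(m2))
  expect_equal(cc, cc2)
})

test_that("sample pairs sharing < 3 entries give NA with a warning", {
  m <- matrix(c(1, 2, 3, NA, NA, 1, 1, 2, 3), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_warning(cc <- spearman_matrix(toy_abundance(m)), "share < 3")
  expect_true(is.na(cc["s1", "s2"]))
  expect_false(is.na(cc["s1", "s3"]))
})

test_that("PCA restricts to complete entries and reports rank-1 structure", {
  base <- c(1, 2, 3, 4)
  m <- rbind(base * 1, base * 2, base * -0.5)
  dimnames(m) <- list(c("a", "b", "c"), sprintf("s%d", 1:4))
  pc <- pca_scores(toy_abundance(m))
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)
  # a missing cell removes the entry from consideration
  m2 <- rbind(m, c(NA, 1, 1, 1)); rownames(m2)[4] <- "d"
  expect_equal(pca_scores(toy_abundance(m2))$n_complete_entries, 3)
})

test_that("duplicating a sample preserves the remaining score geometry", {
  set.seed(6)
  m <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  # full-rank scores: the score geometry is the centered-data geometry, so
  # adding a duplicate sample must leave the original pairwise distances
  # intact (a 2-D truncation would not be, since the subspace rotates)
  pc1 <- pca_scores(toy_abundance(m), n_components = 5)
  m2 <- cbind(m, s7 = m[, 6])
  pc2 <- pca_scores(toy_abundance(m2), n_components = 6)
  d1 <- dist(pc1$scores[1:6, ])
  d2 <- dist(pc2$scores[1:6, ])
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)
})

test_that("phenotypes separate on the leading components for strong effects", {
  cfg <- lossless_config(n_proteins = 300, seed = 41,
                         interplex_dropout_rate = 0,
                         intraplex_dropout_rate = 0)
  sim <- simulate_experiment(cfg)
  res <- run_lossless_pipeline(sim)
  trm <- trim_matrix(res$abundance, sim$design)
  pc <- pca_scores(trm$matrix)
  lab <- as.character(trm$groups)
  # mean silhouette of the phenotype labeling in PC1-2 space
  dd <- as.matrix(dist(pc$scores))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(dd[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(dd[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("Ward clustering merges nearest 1-D points and duplicates first", {
  m <- matrix(c(0, 0.1, 10), 1, 3,
              dimnames = list("g1", c("x", "y", "z")))
  hc <- ward_cluster(toy_abundance(m), axis = "samples")$hclust
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))  # 0 and 0.1 merge first
  m2 <- matrix(c(1, 5, 1, 2, 6, 2, 2, 6, 2), 3, 3,
               dimnames = list(letters[1:3], c("s1", "s2", "s3")))
  hc2 <- ward_cluster(toy_abundance(m2), axis = "samples")$hclust
  expect_equal(hc2$height[1], 0)                 # exact duplicates
  expect_setequal(abs(hc2$merge[1, ]), c(2, 3))
})

test_that("sample cluster labels are invariant to entry permutation", {
  set.seed(13)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
  a <- ward_cluster(toy_abundance(m), "samples", k = 3)$labels
  b <- ward_cluster(toy_abundance(m[sample(30), ]), "samples", k = 3)$labels
  expect_identical(a, b)
})

test_that("Z-scores standardize each sample and keep missing cells", {
  m <- matrix(c(1, 2, 3, 4, NA, 8), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  z <- zscore_by_sample(toy_abundance(m))
  expect_equal(unname(unclass(z)[, 1]), c(-1, 0, 1))
  expect_true(is.na(unclass(z)["b", "s2"]))
  zz <- unclass(z)
  expect_lt(abs(mean(zz[, 2], na.rm = TRUE)), 1e-12)
  expect_lt(abs(sd(zz[, 2], na.rm = TRUE) - 1), 1e-12)
  flat <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(zscore_by_sample(toy_abundance(flat)), class = "domain_error")
})

test_that("dropout classes follow the complete/inter/intra definitions", {
  design <- toy_design(2)
  samples <- validate_design(design)$samples
  m <- matrix(1, 3, 18, dimnames = list(c("comp", "inter", "intra"), samples))
  m["inter", 10:18] <- NA          # wholly absent from plex 2
  m["intra", 1] <- NA              # one sample of plex 1 missing
  out <- dropout_accounting(toy_abundance(m), design)
  expect_equal(unname(out$classes),
               c("complete", "interplex", "intraplex"))
  s <- out$summary
  expect_equal(s$n_complete + s$n_interplex + s$n_intraplex, s$n_total)
  # intraplex takes precedence when both patterns occur
  m2 <- m
  m2["intra", 10:18] <- NA
  out2 <- dropout_accounting(toy_abundance(m2), design)
  expect_equal(unname(out2$classes["intra"]), "intraplex")
})

test_that("dropout accounting recovers generator truth exactly", {
  cfg <- lossless_config(n_proteins = 250, seed = 77)
  sim <- simulate_experiment(cfg)
  res <- run_lossless_pipeline(sim)
  out <- dropout_accounting(res$abundance, sim$design)
  tr <- truth_summary(sim$truth)
  got <- out$classes[tr$entry_id]
  expect_true(all(!is.na(got)))
  expect_equal(unname(got), tr$dropout_class)
})

test_that("hemoglobin bands classify printed endpoint values correctly", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:6), phenotype = "PDR",
                   hemoglobin = c(1.0e-4, 1.7e-3, 8.4e-3, 2.0e-4,
                                  4.9e-3, 1.5e-4))
  expect_warning(out <- classify_subphenotype(cl), "unclassified")
  expect_equal(out$label,
               c("PDR-L", "PDR-M", "PDR-H", "PDR-M", "PDR-H", "unclassified"))
  neg <- data.frame(sample_id = "x", phenotype = "PDR", hemoglobin = -1)
  expect_error(classify_subphenotype(neg), class = "domain_error")
})

test_that("the packaged cohort reproduces its printed subphenotype labels", {
  cohort <- pdr_cohort_clinical()
  out <- classify_subphenotype(cohort)
  pdr <- out[out$phenotype == "PDR", ]
  expect_equal(pdr$label, pdr$subphenotype)
  expect_equal(sum(cohort$analyzed_individually == 1 &
                     cohort$phenotype == "PDR"), 22)
  expect_equal(sum(cohort$analyzed_individually == 1 &
                     cohort$phenotype == "CTL"), 10)
})

test_that("blood annotation labels plasma, erythroid and other entries", {
  sets <- blood_protein_sets()
  expect_length(sets$plasma, 23)
  expect_length(sets$rbc, 7)
  expect_length(unique(c(sets$plasma, sets$rbc)), 30)
  ann <- annotate_blood(c("ALB", "HBB", "NEO1"))
  expect_equal(unname(ann), c("plasma", "rbc", "other"))
  # rbc wins when a symbol appears in both supplied lists
  both <- annotate_blood("X", plasma_set = "X", rbc_set = "X")
  expect_equal(unname(both), "rbc")
})
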