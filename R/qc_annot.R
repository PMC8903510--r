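# QC, structure and annotation analyses on the unified abundance matrix.

#' Pairwise Spearman correlation between samples
#'
#' Each pair is computed over the entries nonmissing in both samples
#' (pairwise-complete), with ties resolved by average rank.  Pairs sharing
#' fewer than 3 entries get a missing cell with a warning.
#'
#' @param a an abundance `quant_matrix`.
#' @param samples optional subset of sample ids (default: all columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(a, samples = colnames(a)) {
  m <- as.matrix(a)[, samples, drop = FALSE]
  if (ncol(m) < 2) pb_stop("domain_error", "need >= 2 samples")
  cc <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))
  if (any(shared < 3)) {
    pb_warn("%d sample pairs share < 3 entries; cells set to NA",
            sum(shared[upper.tri(shared)] < 3))
    cc[shared < 3] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' PCA sample scores on the complete-entry submatrix
#'
#' Restricts to entries measured in all samples, centers each entry across
#' samples (no unit-variance scaling: abundances already share a common log2
#' scale after normalization), and returns sample scores and the fraction of
#' variance explained per component.
#'
#' @param a an abundance `quant_matrix`.
#' @param n_components number of components requested (default 2; reduced
#'   with a warning if fewer complete entries are available).
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions summing to <= 1), `n_complete_entries`.
#' @export
pca_scores <- function(a, n_components = 2) {
  m <- as.matrix(a)
  complete <- rowSums(is.na(m)) == 0
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 3) {
    pb_stop("domain_error", "need >= 2 complete entries and >= 3 samples")
  }
  k_max <- min(nrow(m), ncol(m) - 1)
  if (n_components > k_max) {
    pb_warn("only %d components available; reducing", k_max)
    n_components <- k_max
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve[seq_len(n_components)],
       n_complete_entries = nrow(m))
}

#' Ward hierarchical clustering of samples or entries
#'
#' Agglomerative clustering on Euclidean distance of the complete-entry
#' submatrix using Ward's minimum-variance method.  Deterministic given
#' input order; leaf order follows the standard tight-cluster-first
#' convention of [stats::hclust()].
#'
#' @param a an abundance `quant_matrix`.
#' @param axis `"samples"` (cluster columns) or `"entries"` (cluster rows).
#' @param k optional number of clusters for hard labels.
#' @param exclude optional entry ids to drop first (e.g. blood proteins);
#'   `only` restricts to the given entries instead.
#' @param only optional entry ids to keep exclusively.
#' @return list with `hclust` (dendrogram object) and `labels` (cluster
#'   labels when `k` is given).
#' @export
ward_cluster <- function(a, axis = c("samples", "entries"), k = NULL,
                         exclude = NULL, only = NULL) {
  axis <- match.arg(axis)
  m <- as.matrix(a)
  if (!is.null(only)) m <- m[rownames(m) %in% only, , drop = FALSE]
  if (!is.null(exclude)) m <- m[!(rownames(m) %in% exclude), , drop = FALSE]
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  if (!nrow(m)) pb_stop("domain_error", "no complete entries to cluster")
  x <- if (axis == "samples") t(m) else m
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels)
}

#' Per-sample Z-score normalization
#'
#' Subtracts each sample's mean and divides by its standard deviation
#' (n-1 denominator), over nonmissing entries; missing cells stay missing.
#'
#' @param a an abundance `quant_matrix`.
#' @return a `quant_matrix` of kind `"zscore"` (each sample mean 0, SD 1).
#' @export
zscore_by_sample <- function(a) {
  m <- as.matrix(a)
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sd_)) || any(sd_ == 0)) {
    pb_stop("domain_error", "sample(s) with zero or undefined SD: %s",
            paste(colnames(m)[!is.finite(sd_) | sd_ == 0], collapse = ", "))
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sd_, "/")
  quant_matrix(z, level = attr(a, "level"), kind = "zscore")
}

#' Dropout accounting across plexes
#'
#' Classifies every entry of the abundance matrix into one of three
#' mutually exclusive dropout classes:
#' `complete` (measured in all samples), `interplex` (within each plex
#' either fully measured or wholly absent, with at least one absent plex),
#' and `intraplex` (missing for a strict subset of samples within at least
#' one plex; takes precedence when both patterns occur).
#'
#' @param a an abundance `quant_matrix`.
#' @param design the `plex_design` mapping samples to plexes.
#' @return list with `summary` (`n_total`, `n_complete`, `n_interplex`,
#'   `n_intraplex`, `per_sample_measured`), `classes` (named factor per
#'   entry) and `membership` (entries x samples logical matrix of
#'   measurement, upset-style).
#' @export
dropout_accounting <- function(a, design) {
  m <- as.matrix(a)
  nonref <- design[design$role != "reference", , drop = FALSE]
  samples <- intersect(colnames(m), nonref$sample_id)
  m <- m[, samples, drop = FALSE]
  plex_of <- nonref$plex_id[match(samples, nonref$sample_id)]
  measured <- !is.na(m)
  present_any <- rowSums(measured) > 0
  m <- m[present_any, , drop = FALSE]
  measured <- measured[present_any, , drop = FALSE]
  classify <- function(row) {
    per_plex <- tapply(row, plex_of, function(v) {
      if (all(v)) "full" else if (any(v)) "partial" else "absent"
    })
    if (all(per_plex == "full")) "complete"
    else if (any(per_plex == "partial")) "intraplex"
    else "interplex"
  }
  classes <- apply(measured, 1, classify)
  summary <- list(n_total = nrow(m),
                  n_complete = sum(classes == "complete"),
                  n_interplex = sum(classes == "interplex"),
                  n_intraplex = sum(classes == "intraplex"),
                  per_sample_measured = colSums(measured))
  list(summary = summary,
       classes = stats::setNames(classes, rownames(m)),
       membership = measured)
}

# hemoglobin concentration bands (g/dL), endpoints inclusive
HB_BANDS <- list(L = c(0, 1.00e-4), M = c(2.00e-4, 1.70e-3),
                 H = c(4.90e-3, 8.40e-3))

#' Classify PDR samples into hemoglobin subphenotypes
#'
#' PDR samples are banded by vitreous hemoglobin concentration:
#' PDR-L at <= 1.00e-4 g/dL, PDR-M in \[2.00e-4, 1.70e-3\] g/dL, and PDR-H
#' in \[4.90e-3, 8.40e-3\] g/dL (band endpoints inclusive).  Values in the
#' gaps between bands, or above the highest band, map to `unclassified`
#' with a warning: the bands describe observed concentration ranges, and a
#' value between them has no defined label.  Controls keep the label `CTL`.
#'
#' @param clinical `data.frame` with `sample_id`, `phenotype`, `hemoglobin`.
#' @return the input with a `label` column (`CTL`, `PDR-L`, `PDR-M`,
#'   `PDR-H`, or `unclassified`).
#' @export
classify_subphenotype <- function(clinical) {
  hb <- clinical$hemoglobin
  if (any(hb < 0, na.rm = TRUE)) pb_stop("domain_error", "negative hemoglobin")
  lab <- ifelse(clinical$phenotype == "CTL", "CTL", "unclassified")
  pdr <- clinical$phenotype == "PDR"
  in_band <- function(v, band) !is.na(v) & v >= band[1] & v <= band[2]
  lab[pdr & in_band(hb, HB_BANDS$L)] <- "PDR-L"
  lab[pdr & in_band(hb, HB_BANDS$M)] <- "PDR-M"
  lab[pdr & in_band(hb, HB_BANDS$H)] <- "PDR-H"
  if (any(lab == "unclassified")) {
    pb_warn("%d sample(s) with hemoglobin outside all bands left unclassified",
            sum(lab == "unclassified"))
  }
  clinical$label <- lab
  clinical
}

#' Default blood-protein annotation sets
#'
#' Reconstructed gene-symbol lists standing in for the canonical annotation
#' sets: the 23 most abundant plasma proteins (together ~97% of plasma
#' protein mass) and 7 proteins expressed >= 1000-fold higher in erythroid
#' than non-erythroid cells.  These defaults are reconstructions assembled
#' from standard plasma/erythrocyte references, not a copy of any specific
#' supplementary table, and can be overridden with user-supplied lists.
#'
#' @return list with character vectors `plasma` (23 symbols) and `rbc` (7).
#' @export
blood_protein_sets <- function() {
  list(
    plasma = c("ALB", "IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHM",
               "IGKC", "TF", "HP", "HPX", "A2M", "SERPINA1", "FGA", "FGB",
               "FGG", "APOA1", "APOA2", "APOB", "C3", "C4A", "ORM1", "TTR"),
    rbc = c("HBA1", "HBB", "HBD", "CA1", "CA2", "AHSP", "SLC4A1")
  )
}

#' Annotate entries as plasma, erythroid (RBC), or other
#'
#' @param entries character vector of entry ids (gene symbols).
#' @param plasma_set,rbc_set annotation lists; default [blood_protein_sets()].
#'   An entry present in both lists is resolved rbc-first.
#' @return named character vector (`plasma` / `rbc` / `other`) over `entries`.
#' @export
annotate_blood <- function(entries,
                           plasma_set = blood_protein_sets()$plasma,
                           rbc_set = blood_protein_sets()$rbc) {
  ann <- rep("other", length(entries))
  ann[entries %in% plasma_set] <- "plasma"
  ann[entries %in% rbc_set] <- "rbc"
  stats::setNames(ann, entries)
}

#' Packaged clinical table of the reference vitreous cohort
#'
#' Clinical annotations for the reference cohort: 10 control and 22 PDR
#' vitrectomy samples analyzed individually across four 10-plexes, plus one
#' pool-only PDR donor.  Columns: `plex`, `sample_id`, `phenotype`,
#' `subphenotype` (assigned label), `hemoglobin` (g/dL; blank for
#' controls), `bilirubin` (mg/dL), `in_pool2`, `analyzed_individually`.
#'
#' @return `data.frame` of the cohort table.
#' @export
pdr_cohort_clinical <- function() {
  path <- system.file("extdata", "pdr_cohort_clinical.tsv",
                      package = "plexbridge", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"),
                         colClasses = c(hemoglobin = "numeric",
                                        bilirubin = "numeric"))
  d
}

#' Vitreous-to-blood hemoglobin comparison
#'
#' Expresses a vitreous hemoglobin concentration relative to the reference
#' whole-blood concentration (~15 g/dL): how many times lower it is, and
#' what percentage of the blood concentration it represents.
#'
#' @param hb vitreous hemoglobin concentration (g/dL).
#' @param blood_hb reference blood hemoglobin (default 15 g/dL).
#' @return list with `ratio` (blood / vitreous) and `percent`
#'   (vitreous as % of blood).
#' @export
hb_blood_comparison <- function(hb, blood_hb = 15) {
  if (any(hb <= 0)) pb_stop("domain_error", "hemoglobin must be positive")
  list(ratio = blood_hb / hb, percent = 100 * hb / blood_hb)
}
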