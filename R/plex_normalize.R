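# Reference-scaled ratio construction, summarization and MAD normalization:
# the machinery that ties several TMT plexes into one abundance matrix.

entry_key <- function(psms, level) {
  if (level == "peptide") psms$peptide else psms$entry
}

#' Convert filtered PSMs to log2 ratios against the reference channel
#'
#' For every PSM, each reporter-channel intensity is log2 transformed and the
#' log2 reference-channel intensity subtracted, giving one ratio observation
#' per (PSM, non-reference channel).  Zero or missing channel intensities
#' yield missing observations (never `-Inf`): a zero reporter intensity
#' indicates non-detection in that channel.  PSMs with a zero reference
#' intensity are skipped entirely (log2 undefined) and counted.
#'
#' @param psms filtered, collapsed PSM `data.frame`.
#' @param design the `plex_design`.
#' @return list with `observations` (`data.frame`: `entry`, `peptide`,
#'   `plex`, `run`, `spectrum`, `sample_id`, `ratio`) and
#'   `n_zero_reference` (count of skipped PSMs).
#' @export
compute_ratios <- function(psms, design) {
  n_channels <- max(table(design$plex_id))
  rep_cols <- psm_reporter_cols(n_channels)
  obs <- vector("list", length(unique(psms$plex)))
  zero_ref <- 0L
  for (pi in seq_along(unique(psms$plex))) {
    plex <- unique(psms$plex)[pi]
    d <- design[design$plex_id == plex, , drop = FALSE]
    ref_idx <- which(d$role == "reference")
    p <- psms[psms$plex == plex, , drop = FALSE]
    ref_int <- p[[rep_cols[ref_idx]]]
    bad_ref <- !is.na(ref_int) & ref_int == 0
    zero_ref <- zero_ref + sum(bad_ref)
    p <- p[!bad_ref, , drop = FALSE]
    ref_log <- log2(p[[rep_cols[ref_idx]]])
    chan_idx <- setdiff(seq_len(n_channels), ref_idx)
    per_chan <- lapply(chan_idx, function(ci) {
      ch <- p[[rep_cols[ci]]]
      ok <- !is.na(ch) & ch > 0
      if (!any(ok)) return(NULL)
      data.frame(entry = p$entry[ok], peptide = p$peptide[ok],
                 plex = plex, run = p$run[ok], spectrum = p$spectrum[ok],
                 sample_id = d$sample_id[ci],
                 ratio = log2(ch[ok]) - ref_log[ok],
                 stringsAsFactors = FALSE)
    })
    obs[[pi]] <- do.call(rbind, per_chan)
  }
  out <- do.call(rbind, obs)
  if (is.null(out)) {
    out <- data.frame(entry = character(), peptide = character(),
                      plex = character(), run = character(),
                      spectrum = character(), sample_id = character(),
                      ratio = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  list(observations = out, n_zero_reference = zero_ref)
}

#' Interquartile-range outlier trimming
#'
#' Keeps values `v` with `Q1 - 1.5*IQR <= v <= Q3 + 1.5*IQR`, where the
#' quartiles are linear-interpolation sample quantiles of the input.
#'
#' @param values numeric vector (at least one finite value).
#' @return the retained values, in input order.
#' @export
iqr_trim <- function(values) {
  if (!length(values) || all(is.na(values))) {
    pb_stop("domain_error", "iqr_trim needs at least one finite value")
  }
  q <- pb_quantile(values[!is.na(values)], c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  values[!is.na(values) & values >= lo & values <= hi]
}

#' Summarize ratio observations per entry and sample
#'
#' Groups PSM-level ratio observations at the requested level (`gene` /
#' `protein` pool PSMs by the protein-group or gene identifier, assigned as
#' unique or razor peptides; `peptide` by peptide string), trims outliers per
#' (entry, sample) group with [iqr_trim()], and takes the median of the
#' remaining ratios as the sample's ratio for that entry.  Cells with no
#' observations are missing.
#'
#' @param ratios result of [compute_ratios()] (or its `observations` field).
#' @param design the `plex_design`.
#' @param level summarization level.
#' @return a `quant_matrix` of kind `"ratio"` spanning all non-reference
#'   samples of all plexes.
#' @export
summarize_entry <- function(ratios, design, level = c("gene", "protein", "peptide")) {
  level <- match.arg(level)
  obs <- if (is.data.frame(ratios)) ratios else ratios$observations
  samples <- validate_design(design)$samples
  entry <- if (level == "peptide") obs$peptide else obs$entry
  entries <- sort(unique(entry))
  m <- matrix(NA_real_, nrow = length(entries), ncol = length(samples),
              dimnames = list(entries, samples))
  if (nrow(obs)) {
    key <- paste(entry, obs$sample_id, sep = "\r")
    med <- vapply(split(obs$ratio, key), function(v) stats::median(iqr_trim(v)),
                  numeric(1))
    parts <- strsplit(names(med), "\r", fixed = TRUE)
    ei <- match(vapply(parts, `[[`, "", 1L), entries)
    si <- match(vapply(parts, `[[`, "", 2L), samples)
    ok <- !is.na(si)
    m[cbind(ei[ok], si[ok])] <- med[ok]
  }
  quant_matrix(m, level = level, kind = "ratio")
}

#' Median-absolute-deviation normalization of a ratio matrix
#'
#' Scales every sample (column) of a log2 ratio matrix to a common location
#' and spread.  Per sample i: the median ratio `M_i` over nonmissing entries
#' is subtracted (`RC_ij = R_ij - M_i`), the median absolute deviation
#' `MAD_i = median(|RC_ij|)` computed (no consistency constant), and the
#' centered values rescaled to the global scale:
#' `RN_ij = (RC_ij / MAD_i) * MAD_0 + M_0`, where `M_0 = median(M_i)` and
#' `MAD_0 = median(MAD_i)` over all samples of all plexes jointly.
#' Missing cells stay missing.  A sample with `MAD_i = 0` is flagged and its
#' scale factor set to 1.
#'
#' @param r a ratio `quant_matrix` (samples as columns).
#' @return list with `normalized` (`quant_matrix` of kind
#'   `"normalized_ratio"`) and `params` (`M_i`, `MAD_i`, `M_0`, `MAD_0`,
#'   `flagged_samples`).
#' @export
mad_normalize <- function(r) {
  if (any(colSums(!is.na(r)) == 0)) {
    pb_stop("matrix_error", "every sample needs at least one nonmissing entry")
  }
  M_i <- apply(r, 2, stats::median, na.rm = TRUE)
  centered <- sweep(r, 2, M_i, "-")
  MAD_i <- apply(abs(centered), 2, stats::median, na.rm = TRUE)
  M_0 <- stats::median(M_i)
  MAD_0 <- stats::median(MAD_i)
  flagged <- names(MAD_i)[MAD_i == 0]
  if (length(flagged)) {
    pb_warn("MAD is zero for sample(s) %s; scale factor set to 1",
            paste(flagged, collapse = ", "))
  }
  scale_i <- ifelse(MAD_i == 0, 1, MAD_0 / MAD_i)
  rn <- sweep(centered, 2, scale_i, "*") + M_0
  params <- list(M_i = M_i, MAD_i = MAD_i, M_0 = M_0, MAD_0 = MAD_0,
                 flagged_samples = flagged)
  list(normalized = quant_matrix(unclass(rn), level = attr(r, "level"),
                                 kind = "normalized_ratio"),
       params = params)
}

#' Estimate per-entry reference-channel intensities
#'
#' For entry i in plex k, the reference intensity `REF_ik` is the weighted
#' sum of the MS1 precursor intensities of the (up to) 3 most MS1-intense
#' peptide ions quantified for that entry in that plex, each weighted by the
#' proportion of the reference-channel reporter intensity to the total
#' summed reporter intensity of the PSM.  Plexes where the entry has no
#' quantified PSM are imputed with the global minimum observed `REF` value,
#' and the overall `REF_i` is the mean over all plexes (after imputation).
#'
#' @param psms filtered, collapsed PSM `data.frame`.
#' @param design the `plex_design`.
#' @param level summarization level (`gene`/`protein` use the entry id,
#'   `peptide` the peptide string).
#' @return list with `REF_ik` (entries x plexes matrix, `NA` where
#'   unobserved), `REF_i` (named vector after imputation and averaging) and
#'   `global_min`.
#' @export
reference_intensity <- function(psms, design, level = "gene") {
  n_channels <- max(table(design$plex_id))
  rep_cols <- psm_reporter_cols(n_channels)
  plexes <- unique(design$plex_id)
  key <- entry_key(psms, level)
  entries <- sort(unique(key))
  if (!length(entries)) pb_stop("domain_error", "no quantified PSMs")
  REF_ik <- matrix(NA_real_, length(entries), length(plexes),
                   dimnames = list(entries, plexes))
  rep_mat <- as.matrix(psms[, rep_cols, drop = FALSE])
  tot <- rowSums(rep_mat, na.rm = TRUE)
  for (plex in plexes) {
    ref_idx <- reference_channel_index(design, plex)
    sel <- which(psms$plex == plex & !is.na(psms$ms1_intensity) & tot > 0)
    if (!length(sel)) next
    w <- psms[[rep_cols[ref_idx]]][sel] / tot[sel]
    contrib <- psms$ms1_intensity[sel] * w
    ms1 <- psms$ms1_intensity[sel]
    for (grp in split(seq_along(sel), key[sel])) {
      top <- grp[order(-ms1[grp])][seq_len(min(3L, length(grp)))]
      REF_ik[key[sel[grp[1]]], plex] <- sum(contrib[top])
    }
  }
  observed <- REF_ik[!is.na(REF_ik)]
  if (!length(observed)) pb_stop("domain_error", "no reference intensities observed")
  global_min <- min(observed)
  imputed <- REF_ik
  imputed[is.na(imputed)] <- global_min
  REF_i <- rowMeans(imputed)
  absent <- rowSums(!is.na(REF_ik)) == 0
  if (any(absent)) {
    pb_warn("%d entries absent from all plexes excluded from REF", sum(absent))
    REF_i <- REF_i[!absent]
  }
  list(REF_ik = REF_ik, REF_i = REF_i, global_min = global_min)
}

#' Assemble the unified log2 abundance matrix
#'
#' Converts normalized ratios back to the absolute intensity scale:
#' `A_ij = RN_ij + log2(REF_i)`.  Missing ratios stay missing; entries with
#' a nonpositive reference intensity are excluded and counted.
#'
#' @param rn normalized-ratio `quant_matrix`.
#' @param ref result of [reference_intensity()] (or a named `REF_i` vector).
#' @return a `quant_matrix` of kind `"abundance"`.
#' @export
assemble_abundance <- function(rn, ref) {
  REF_i <- if (is.list(ref)) ref$REF_i else ref
  common <- intersect(rownames(rn), names(REF_i))
  bad <- common[REF_i[common] <= 0]
  if (length(bad)) {
    pb_warn("%d entries with nonpositive reference intensity excluded", length(bad))
    common <- setdiff(common, bad)
  }
  a <- rn[common, , drop = FALSE] + log2(REF_i[common])
  quant_matrix(unclass(a), level = attr(rn, "level"), kind = "abundance")
}

#' Run the full plex-normalization pipeline
#'
#' Filter, collapse, ratio, summarize, MAD-normalize and assemble: PSM tables
#' from several plexes in, one unified log2 abundance matrix out.
#'
#' @param psms canonical PSM `data.frame` covering all plexes.
#' @param design the `plex_design`.
#' @param level summarization level.
#' @param ... passed to [apply_quality_filters()].
#' @return list with `abundance`, `normalized`, `ratio` matrices, `params`
#'   (normalization parameters), `ref` (reference intensities),
#'   `filter_report` and the kept `psms`.
#' @export
normalize_plexes <- function(psms, design, level = c("gene", "protein", "peptide"),
                             ...) {
  level <- match.arg(level)
  n_channels <- max(table(design$plex_id))
  flt <- apply_quality_filters(psms, design, ...)
  kept <- collapse_redundant(flt$kept, n_channels)
  ratios <- compute_ratios(kept, design)
  rmat <- summarize_entry(ratios, design, level = level)
  norm <- mad_normalize(rmat)
  ref <- reference_intensity(kept, design, level = level)
  abundance <- assemble_abundance(norm$normalized, ref)
  list(abundance = abundance, normalized = norm$normalized, ratio = rmat,
       params = norm$params, ref = ref, filter_report = flt$report,
       psms = kept)
}
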