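# PSM-level quality control before quantification.

summed_reporter <- function(psms, n_channels) {
  rep <- as.matrix(psms[, psm_reporter_cols(n_channels), drop = FALSE])
  rowSums(rep, na.rm = TRUE)
}

reference_channel_index <- function(design, plex) {
  d <- design[design$plex_id == plex, , drop = FALSE]
  which(d$role == "reference")
}

#' Apply PSM quality filters
#'
#' Removes PSMs failing any of the standard reporter-quantification quality
#' rules for an isobaric plex:
#' (a) no TMT label; (b) missing quantification in the reference channel;
#' (c) precursor-ion purity below 50%; (d) summed reporter-ion intensity
#' (across all channels) in the 5th percentile or lower of the plex.
#' PSMs mapping to external contaminant proteins are also excluded.  Both
#' `unique` and `razor` assignments are retained.
#'
#' The intensity percentile for rule (d) is computed per plex, by
#' linear-interpolation sample quantile, over the summed reporter intensity
#' of PSMs surviving rules (a)-(c); the boundary is inclusive (values equal
#' to the 5th-percentile value are removed, honoring "or lower").
#'
#' @param psms canonical PSM `data.frame` (see [read_psm_table()]).
#' @param design the `plex_design`; used to locate the reference channel.
#' @param purity_min minimum purity retained (default 0.5; rule is strict
#'   `purity < purity_min` removal, so exactly 0.5 is kept).
#' @param intensity_percentile percentile bound for rule (d) (default 0.05);
#'   a nonpositive value disables the rule.
#' @param min_probability optional re-application of a PSM-probability cut;
#'   the default 0 assumes the cut was applied upstream.
#' @return list with `kept` (surviving PSMs) and `report` (a filter report:
#'   per-rule removal counts, overall and per plex; `kept + removed` always
#'   reconciles with the input count).
#' @export
apply_quality_filters <- function(psms, design, purity_min = 0.5,
                                  intensity_percentile = 0.05,
                                  min_probability = 0) {
  n_channels <- max(table(design$plex_id))
  rules <- c("no_label", "missing_reference", "low_purity", "low_probability",
             "contaminant", "low_intensity")
  zero <- stats::setNames(integer(length(rules)), rules)
  if (!nrow(psms)) {
    return(list(kept = psms,
                report = list(counts_removed = as.list(zero), counts_kept = 0L,
                              per_plex = list())))
  }
  keep <- rep(TRUE, nrow(psms))
  removed <- zero
  per_plex <- list()
  rep_cols <- psm_reporter_cols(n_channels)

  for (plex in unique(psms$plex)) {
    in_plex <- which(psms$plex == plex)
    ref_idx <- reference_channel_index(design, plex)
    if (!length(ref_idx)) {
      pb_stop("design_error", "plex %s not present in design", plex)
    }
    p <- psms[in_plex, , drop = FALSE]
    alive <- rep(TRUE, nrow(p))
    plex_removed <- zero

    drop_rule <- function(bad, rule) {
      bad <- bad & alive
      plex_removed[rule] <<- plex_removed[rule] + sum(bad)
      alive <<- alive & !bad
    }
    # (a) unlabeled peptides cannot carry reporter signal
    drop_rule(!p$tmt_labeled, "no_label")
    # (b) no reference quantification -> no ratio denominator
    ref_int <- p[[rep_cols[ref_idx]]]
    drop_rule(is.na(ref_int), "missing_reference")
    # (c) co-isolation distorts reporter ratios; strict < cut
    drop_rule(!is.na(p$purity) & p$purity < purity_min, "low_purity")
    if (min_probability > 0) {
      drop_rule(!is.na(p$probability) & p$probability < min_probability,
                "low_probability")
    }
    # contaminant-mapped PSMs are excluded from quantification
    survivors_abc <- alive
    drop_rule(p$contaminant, "contaminant")
    # (d) low summed reporter intensity; threshold from (a)-(c) survivors.
    # A nonpositive percentile disables the rule (the inclusive boundary
    # would otherwise always remove the minimum).
    if (intensity_percentile > 0 && any(survivors_abc)) {
      sums <- summed_reporter(p, n_channels)
      thr <- pb_quantile(sums[survivors_abc], intensity_percentile)
      drop_rule(sums <= thr, "low_intensity")
    }
    keep[in_plex] <- alive
    removed <- removed + plex_removed
    per_plex[[plex]] <- list(counts_removed = as.list(plex_removed),
                             counts_kept = sum(alive),
                             input = length(in_plex))
  }
  list(kept = psms[keep, , drop = FALSE],
       report = list(counts_removed = as.list(removed),
                     counts_kept = sum(keep),
                     input = nrow(psms),
                     per_plex = per_plex))
}

#' Collapse redundant PSMs to one per peptide ion
#'
#' Within each (plex, run, peptide sequence, charge) group -- the same
#' peptide ion observed in the same MS run -- keeps only the PSM with the
#' highest summed reporter intensity.  Ties are broken deterministically by
#' lexicographic `spectrum` id.  Peptide modifications are part of the
#' peptide string, so differently modified forms are distinct peptide ions.
#'
#' @param psms quality-filtered PSM `data.frame`.
#' @param n_channels reporter channel count (default 10).
#' @return PSM `data.frame` with unique (plex, run, peptide, charge) keys.
#' @export
collapse_redundant <- function(psms, n_channels = 10) {
  if (!nrow(psms)) return(psms)
  sums <- summed_reporter(psms, n_channels)
  key <- paste(psms$plex, psms$run, psms$peptide, psms$charge, sep = "\r")
  ord <- order(key, -sums, psms$spectrum)
  keep <- ord[!duplicated(key[ord])]
  psms[sort(keep), , drop = FALSE]
}
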