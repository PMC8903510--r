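#' Canonical PSM-table schema
#'
#' The package reads tab-separated PSM (peptide-spectrum match) tables with
#' one row per PSM.  Different search/quantification pipelines name their
#' columns differently; `psm_schema()` maps the canonical names used
#' throughout this package to the column names found in a particular file
#' dialect.  The default is the identity mapping on the package's own schema.
#'
#' Canonical columns: `plex`, `run`, `spectrum`, `peptide`, `charge`,
#' `entry`, `assignment` (`unique`/`razor`), `contaminant` (0/1),
#' `tmt_labeled` (0/1), `ms1_intensity`, `purity`, `probability`, and
#' `reporter_1` .. `reporter_<n>` for an n-channel plex.
#'
#' @param ... named overrides, e.g. `purity = "precursor_purity"` if the file
#'   stores precursor-ion purity under a different header.
#' @param n_channels number of reporter channels (default 10 for TMT 10-plex).
#' @return named character vector mapping canonical names to file columns.
#' @export
psm_schema <- function(..., n_channels = 10) {
  base <- c("plex", "run", "spectrum", "peptide", "charge", "entry",
            "assignment", "contaminant", "tmt_labeled", "ms1_intensity",
            "purity", "probability",
            paste0("reporter_", seq_len(n_channels)))
  map <- stats::setNames(base, base)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), base)
    if (length(bad)) {
      pb_stop("schema_error", "unknown schema field(s): %s",
              paste(bad, collapse = ", "))
    }
    map[names(dots)] <- unlist(dots)
  }
  map
}

psm_reporter_cols <- function(n_channels) paste0("reporter_", seq_len(n_channels))

#' Construct a plex design table
#'
#' A plex design maps each reporter channel of each plex to a sample, a role,
#' and a phenotype.  Exactly one channel per plex must carry the role
#' `"reference"`: the pooled bridge sample against which all other channels
#' are ratioed.  Pool aliquots that are quantified as ordinary sample columns
#' (e.g. a validation pool re-run in every plex) carry the roles
#' `"validation_pool"` or `"bridge_pool"`; patient samples are `"individual"`.
#'
#' @param plex_id,channel,sample_id,role,phenotype equal-length vectors; one
#'   element per (plex, channel).  `role` is one of `individual`,
#'   `bridge_pool`, `validation_pool`, `reference`; `phenotype` is `CTL`,
#'   `PDR`, or `NA` for pools.
#' @return a `data.frame` of class `plex_design`.
#' @export
plex_design <- function(plex_id, channel, sample_id, role, phenotype) {
  d <- data.frame(plex_id = as.character(plex_id),
                  channel = as.character(channel),
                  sample_id = as.character(sample_id),
                  role = as.character(role),
                  phenotype = as.character(phenotype),
                  stringsAsFactors = FALSE)
  ok_roles <- c("individual", "bridge_pool", "validation_pool", "reference")
  if (!all(d$role %in% ok_roles)) {
    pb_stop("design_error", "invalid role(s): %s",
            paste(setdiff(unique(d$role), ok_roles), collapse = ", "))
  }
  class(d) <- c("plex_design", "data.frame")
  d
}

#' Validate a plex design set
#'
#' Confirms that every plex has exactly one reference channel and that sample
#' identifiers are unique, and returns the set of non-reference sample ids,
#' i.e. the columns of all downstream quantitative matrices.
#'
#' @param design a `plex_design` (possibly covering several plexes).
#' @return list with `samples` (character vector of non-reference sample ids,
#'   in design order), `plexes` (plex ids), and the validated `design`.
#' @export
validate_design <- function(design) {
  if (!nrow(design)) pb_stop("design_error", "design has no channels")
  for (p in unique(design$plex_id)) {
    nref <- sum(design$role[design$plex_id == p] == "reference")
    if (nref != 1L) {
      pb_stop("design_error",
              "plex %s has %d reference channels (exactly 1 required)", p, nref)
    }
  }
  nonref <- design[design$role != "reference", , drop = FALSE]
  dup <- nonref$sample_id[duplicated(nonref$sample_id)]
  if (length(dup)) {
    # duplicate ids are only tolerable for pool aliquots explicitly flagged
    roles <- nonref$role[nonref$sample_id %in% dup]
    if (any(roles == "individual")) {
      pb_stop("design_error", "duplicate sample_id across plexes: %s",
              paste(unique(dup), collapse = ", "))
    }
  }
  list(samples = unique(nonref$sample_id),
       plexes = unique(design$plex_id),
       design = design)
}

#' Read / write a plex design table (TSV)
#'
#' @param path file path; columns `plex`, `channel`, `sample`, `role`,
#'   `phenotype`.
#' @return `read_design`: a `plex_design`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("plex", "channel", "sample", "role", "phenotype")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    pb_stop("schema_error", "design file missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  ph <- d$phenotype
  ph[ph %in% c("", "NA", "n/a")] <- NA_character_
  plex_design(d$plex, d$channel, d$sample, d$role, ph)
}

#' @rdname read_design
#' @param design a `plex_design` to serialize.
#' @export
write_design <- function(design, path) {
  out <- data.frame(plex = design$plex_id, channel = design$channel,
                    sample = design$sample_id, role = design$role,
                    phenotype = ifelse(is.na(design$phenotype), "", design$phenotype))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSM quantification table
#'
#' Reads a tab-separated PSM table (one row per peptide-spectrum match, with
#' ten reporter-ion intensity columns for a 10-plex) into the canonical
#' in-memory representation: a `data.frame` with canonical column names.
#' Empty reporter cells become `NA` (missing), never 0: a zero intensity is a
#' measured value, distinct from dropout.  Columns not named by the schema
#' are carried through untouched.
#'
#' @param path file path.
#' @param design the `plex_design` for the plex(es) in the file; the reporter
#'   column count must match the design's channel count.
#' @param schema a [psm_schema()] mapping for alternative column dialects.
#' @return `data.frame` of PSM records with canonical names.
#' @export
read_psm_table <- function(path, design, schema = psm_schema()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss)) {
    pb_stop("schema_error", "PSM table missing required column(s): %s",
            paste(miss, collapse = ", "))
  }
  # rename dialect columns to canonical names, keep unknown columns as-is
  idx <- match(unname(schema), names(raw))
  names(raw)[idx] <- names(schema)
  n_channels <- sum(grepl("^reporter_", names(schema)))
  n_design_channels <- max(table(design$plex_id))
  if (n_channels != n_design_channels) {
    pb_stop("design_error",
            "schema has %d reporter channels but design has %d per plex",
            n_channels, n_design_channels)
  }
  rep_cols <- psm_reporter_cols(n_channels)
  for (cc in c(rep_cols, "ms1_intensity", "purity", "probability")) {
    raw[[cc]] <- as.numeric(raw[[cc]])
  }
  raw$charge <- as.integer(raw$charge)
  raw$contaminant <- as.integer(raw$contaminant) == 1L
  raw$tmt_labeled <- as.integer(raw$tmt_labeled) == 1L
  for (cc in c("plex", "run", "spectrum", "peptide", "entry", "assignment")) {
    raw[[cc]] <- as.character(raw[[cc]])
  }
  validate_psm_table(raw, n_channels)
  if (!all(raw$plex %in% design$plex_id)) {
    pb_stop("design_error", "PSM table contains plex ids absent from design: %s",
            paste(setdiff(unique(raw$plex), design$plex_id), collapse = ", "))
  }
  raw
}

validate_psm_table <- function(psms, n_channels = 10) {
  pur <- psms$purity[!is.na(psms$purity)]
  if (any(pur < 0 | pur > 1)) pb_stop("schema_error", "purity outside [0,1]")
  ms1 <- psms$ms1_intensity[!is.na(psms$ms1_intensity)]
  if (any(ms1 < 0)) pb_stop("schema_error", "negative ms1_intensity")
  rep <- as.matrix(psms[, psm_reporter_cols(n_channels), drop = FALSE])
  if (any(rep[!is.na(rep)] < 0)) pb_stop("schema_error", "negative reporter intensity")
  invisible(psms)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: missing reporter cells are written as empty
#' fields and numeric values at full (round-trippable) precision.
#'
#' @param psms canonical PSM `data.frame`.
#' @param path output path.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  num <- vapply(out, is.numeric, logical(1))
  for (cc in names(out)[num]) out[[cc]] <- fmt_full(out[[cc]])
  for (cc in names(out)[vapply(out, is.logical, logical(1))]) {
    out[[cc]] <- as.integer(out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# full-precision numeric formatting: 17 significant digits round-trips doubles
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Quantitative matrices (ratios, abundances, z-scores)
#'
#' A `quant_matrix` is a numeric entries-by-samples matrix (with `NA` for
#' missing cells) carrying two attributes: the summarization `level`
#' (`gene`, `protein`, or `peptide`) and the `kind` of quantity stored
#' (`ratio`, `normalized_ratio`, `abundance`, or `zscore`).
#'
#' @param values numeric matrix with entry rownames and sample colnames.
#' @param level summarization level.
#' @param kind quantity kind.
#' @return a `quant_matrix`.
#' @export
quant_matrix <- function(values,
                         level = c("gene", "protein", "peptide"),
                         kind = c("ratio", "normalized_ratio", "abundance", "zscore")) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values)))) {
    pb_stop("matrix_error", "quant_matrix needs entry rownames and sample colnames")
  }
  if (kind == "abundance" && any(is.infinite(values))) {
    pb_stop("matrix_error", "abundance matrix must be finite where nonmissing")
  }
  structure(values, level = level, kind = kind,
            class = c("quant_matrix", class(values)))
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s-level %s]: %d entries x %d samples, %.1f%% missing\n",
              attr(x, "level"), attr(x, "kind"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Write / read a quantitative matrix (TSV)
#'
#' Entries as rows, samples as columns, first column `entry_id`; missing cells
#' are empty.  Values are written at full precision so a write-then-read
#' round trip is bit-identical for finite values.
#'
#' @param m a [quant_matrix()].
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(entry_id = rownames(m) %||% character(0),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_full(m[, j])
  con <- tryCatch(file(path, "w"), error = function(e) {
    pb_stop("io_error", "cannot open '%s' for writing", path)
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @param level,kind metadata restored on read (not stored in the TSV).
#' @export
read_matrix <- function(path, level = "gene", kind = "abundance") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character")
  if (names(df)[1] != "entry_id") {
    pb_stop("schema_error", "matrix file must start with an entry_id column")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$entry_id
  quant_matrix(vals, level = level, kind = kind)
}

#' Read a clinical annotation table (TSV)
#'
#' Expects columns `sample_id`, `phenotype`, `hemoglobin` (g/dL; may be empty
#' for controls) and optionally `bilirubin` (mg/dL).
#'
#' @param path file path.
#' @return `data.frame` of clinical annotations.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "phenotype", "hemoglobin")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    pb_stop("schema_error", "clinical file missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  d$hemoglobin <- as.numeric(d$hemoglobin)
  if (any(d$hemoglobin < 0, na.rm = TRUE)) {
    pb_stop("domain_error", "negative hemoglobin concentration")
  }
  d
}
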