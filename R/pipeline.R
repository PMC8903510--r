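#' Run the full analysis pipeline on PSM tables
#'
#' Convenience wrapper chaining normalization, trimming, differential
#' expression, effect sizes and QC summaries, as a command-line run would.
#'
#' @param psms canonical PSM `data.frame` covering all plexes.
#' @param design the `plex_design`.
#' @param level summarization level (default gene).
#' @param lambda Storey lambda (default 0.5).
#' @param fc_cut,q_cut volcano cuts (defaults 1.5 and 0.05).
#' @return list with `normalization` (see [normalize_plexes()]), `trimmed`,
#'   `de` (volcano-classified DE table and hyperparameters), `effects`,
#'   `dropout`, and `annotation`.
#' @export
run_pipeline <- function(psms, design, level = "gene", lambda = 0.5,
                         fc_cut = 1.5, q_cut = 0.05) {
  norm <- normalize_plexes(psms, design, level = level)
  trimmed <- trim_matrix(norm$abundance, design)
  annotation <- annotate_blood(rownames(norm$abundance))
  de <- run_de(trimmed, lambda = lambda, annotation = annotation)
  de$table <- volcano_table(de$table, fc_cut = fc_cut, q_cut = q_cut)
  effects <- effect_table(trimmed)
  dropout <- dropout_accounting(norm$abundance, design)
  list(normalization = norm, trimmed = trimmed, de = de, effects = effects,
       dropout = dropout, annotation = annotation)
}

#' Write a JSON run manifest
#'
#' Records the parameters and input provenance of a pipeline run.
#'
#' @param path output path.
#' @param command subcommand or function name.
#' @param params named list of parameters.
#' @export
write_manifest <- function(path, command, params) {
  jsonlite::write_json(
    list(tool = "plexbridge", command = command,
         version = as.character(utils::packageVersion("plexbridge")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
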