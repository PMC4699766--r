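# Table and configuration I/O.
#
# Per-nucleus tables are plain UTF-8 text with a mandatory header row; the
# dialect is auto-detected from the extension (.csv comma, anything else
# tab). Counts are integers on disk; energies are written with 6 significant
# digits. Configuration is YAML; reports and manifests are JSON.

nucleus_columns <- c("nucleus_id", "replicate_id", "dose_nominal_Gy",
                     "dose_actual_Gy", "phase_true", "is_cluster",
                     "area_um2", "circularity", "dapi_int", "a488_int",
                     "ki67_int", "rif_count")

table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read / write per-nucleus tables
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated. A header row is mandatory.
#' @return [read_nucleus_table()] returns a tibble;
#'   [write_nucleus_table()] returns `path` invisibly.
#' @export
read_nucleus_table <- function(path) {
  tb <- utils::read.table(path, sep = table_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("rif_count" %in% names(tb)) {
    if (any(tb$rif_count != round(tb$rif_count) | tb$rif_count < 0)) {
      stop_invalid("column 'rif_count' must hold non-negative integers (row %d)",
                   which(tb$rif_count != round(tb$rif_count) | tb$rif_count < 0)[1])
    }
    tb$rif_count <- as.integer(tb$rif_count)
  }
  tibble::as_tibble(tb)
}

#' @rdname read_nucleus_table
#' @param records Data frame of per-nucleus records.
#' @export
write_nucleus_table <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("area_um2", "circularity", "dapi_int", "a488_int", "ki67_int",
                "dose_actual_Gy")) {
    if (col %in% names(out)) out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.table(out, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with optional blocks `population` (arguments of
#' [population_config()]), `model` (`k1`, `k2`, `beam_label` overriding the
#' default calibration), `geometry` (`nucleus`: major/minor/thickness;
#' `dna_cylinder`: diameter/length with unit tags) and `study`
#' (`doses`, `n_per_dose`, `volumes`, `seed`).
#'
#' @param path YAML file path.
#' @return Named list with `population` ([population_config()] or NULL),
#'   `model` ([specific_energy_model()] or NULL), raw `geometry` and
#'   `study` blocks, and `hash` (the [config_hash()] of the raw file
#'   contents).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(population = NULL, model = NULL,
              geometry = raw$geometry, study = raw$study,
              hash = config_hash(raw))
  if (!is.null(raw$population)) {
    out$population <- do.call(population_config, raw$population)
  }
  if (!is.null(raw$model)) {
    out$model <- specific_energy_model(
      k1 = raw$model$k1, k2 = raw$model$k2,
      beam_label = if (is.null(raw$model$beam_label)) "Co-60" else raw$model$beam_label)
  }
  out
}

#' Write a run manifest
#'
#' Records tool version, configuration hash, per-stage seeds, input/output
#' paths and a timestamp next to the outputs of a run.
#'
#' @param path Output JSON path.
#' @param seeds Named list/vector of per-stage seeds.
#' @param config List used for the run (hashed with [config_hash()]).
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seeds, config = list(), inputs = character(),
                           outputs = character()) {
  manifest <- list(
    tool = "rifvar",
    version = as.character(utils::packageVersion("rifvar")),
    config_hash = config_hash(config),
    seeds = as.list(seeds),
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
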