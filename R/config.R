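# Run configuration: one YAML document with a section per pipeline stage.
# Defaults mirror the canonical protocol (M = 64 filters, K = 1024 atoms
# per 10 s, batch 24, up to 250 epochs with patience 10, 70/30 split,
# 10 repetitions, five audiometric frequencies on the 5-dB grid). Unknown
# keys are rejected so that typos cannot silently fall back to defaults.

#' Default run configuration
#'
#' @return Nested list with sections `filterbank`, `encoder`, `raster`,
#'   `synthesis`, `training`, `audiometry`, plus `seed`, `out_dir`,
#'   `verbose`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    verbose = TRUE,
    filterbank = list(M = 64L, fmin = 80, fmax = 7200, sample_rate = 16000),
    encoder = list(K = 1024L, stop_ratio = 1e-12),
    raster = list(bin_ms = 25, transform = "log1p"),
    synthesis = list(n_per_class = 60L, duration = 10),
    training = list(learning_rate = 1e-3, batch_size = 24L,
                    max_epochs = 250L, patience = 10L,
                    train_fraction = 0.70, n_repetitions = 10L),
    audiometry = list(n_listeners = 18L, n_repetitions = 3L,
                      latency_clinical = 0.2, latency_remote = 0.2,
                      sweep_rate = 10)
  )
}

#' Validate and merge a configuration against the defaults
#'
#' @param config Nested list (e.g. from [load_config()]); may be partial.
#' @return The merged configuration.
#' @export
validate_config <- function(config) {
  merge_section <- function(def, got, path) {
    if (is.null(got)) return(def)
    unknown <- setdiff(names(got), names(def))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(got)) {
      def[[nm]] <- if (is.list(def[[nm]]))
        merge_section(def[[nm]], got[[nm]], paste0(path, nm, "."))
      else got[[nm]]
    }
    def
  }
  merge_section(default_config(), config, "")
}

#' Load a YAML run configuration
#'
#' @param path YAML file; keys must be a subset of [default_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write a machine-readable report
#'
#' JSON keeps the full nested structure; CSV is available for tabular
#' reports (data.frames or matrices). Numeric fields round-trip at double
#' precision.
#'
#' @param report List, data.frame or matrix.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                         matrix = "rowmajor", dataframe = "columns")
  } else {
    if (is.matrix(report)) report <- as.data.frame(report)
    if (!is.data.frame(report))
      stop("csv format needs a data.frame or matrix", call. = FALSE)
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [write_report()].
#' @return List with vectors simplified.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a provenance record for an output directory
#'
#' Records the package version, the resolved configuration, its MD5 hash
#' and the seeds in `provenance.json`, so any output directory documents
#' how it was produced.
#'
#' @param dir Output directory.
#' @param config Resolved configuration list.
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  prov <- list(
    package = "hearscene",
    version = as.character(utils::packageVersion("hearscene")),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    config = config
  )
  out <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
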