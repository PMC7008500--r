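## configuration, result writers and run manifests

config_defaults <- list(
  na = 0.22, d_um = 100, musp_per_cm = 10, n_sample = 1.35,
  n_fiber = 1.45, n_external = 1.0, seed = 1, n_photons = 1e6,
  lambda0_nm = 600
)
## optional keys without defaults
config_optional <- c("termination_cm", "constants")

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys, injects
#' defaults (NA 0.22, 100-um fiber, indices 1.35/1.45/1.00, calibrated
#' constants) and validates the probe geometry.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return List of class `sfr_config` with the filled configuration plus
#'   derived `probe` ([probe_config]) and `constants` ([sfr_constants]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c(names(config_defaults), config_optional))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(config_defaults, raw)
  probe <- probe_config(diameter_um = cfg$d_um, na = cfg$na,
                        n_sample = cfg$n_sample, n_fiber = cfg$n_fiber,
                        n_external = cfg$n_external)
  constants <- if (is.null(cfg$constants)) {
    sfr_constants(cfg$na)
  } else {
    do.call(sfr_constants, c(list(na = cfg$na), cfg$constants))
  }
  structure(c(cfg, list(probe = probe, constants = constants)),
            class = "sfr_config")
}

#' Save a configuration
#'
#' @param config An `sfr_config` (or plain list of settings).
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  keep <- intersect(c(names(config_defaults), "termination_cm"),
                    names(config))
  yaml::write_yaml(config[keep], path)
  invisible(path)
}

## CSV writer preserving full double precision (%.17g round-trips exactly)
write_full_precision_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Writes a data frame as CSV (column order preserved, full numeric
#' precision) or JSON (column-oriented, full precision). Both formats
#' round-trip doubles losslessly through [read_results()].
#'
#' @param table Non-empty data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (format == "csv") {
    write_full_precision_csv(table, path)
  } else {
    jsonlite::write_json(as.list(table), path, digits = I(17),
                         auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write a run manifest
#'
#' Drops a small JSON manifest (command, configuration path, seed, package
#' version, timestamp) into an output directory so any result set records
#' how it was produced.
#'
#' @param command Name of the command/experiment.
#' @param output_dir Directory the results are written to.
#' @param config_path Configuration file used (may be `NA`).
#' @param seed Seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(command, output_dir, config_path = NA,
                           seed = NA) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command, config = config_path, seed = seed,
    package = "sfrsub",
    version = as.character(utils::packageVersion("sfrsub")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
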