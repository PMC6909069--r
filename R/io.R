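#' Load a simulation configuration from file
#'
#' Reads a flat YAML or JSON key-value file whose keys are named exactly
#' as the [game_config()] arguments (`payoffs` may be a nested map with
#' keys `reward_cc`, `temptation_dc`, `sucker_cd`, `punish_dd`;
#' `strategy_mix` a preset name or a named weight map).  Missing keys fall
#' back to the baseline defaults; an empty file yields the full baseline
#' configuration.  Unknown keys are an error, named individually.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [game_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("forgiveness: 0.05", f)
#' load_config(f)$forgiveness
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a key-value mapping")
  known <- setdiff(names(formals(game_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$payoffs)) {
    raw$payoffs <- do.call(payoff_matrix, as.list(raw$payoffs))
  }
  if (!is.null(raw$strategy_mix)) {
    sm <- raw$strategy_mix
    raw$strategy_mix <- if (is.character(sm) && length(sm) == 1L) {
      strategy_mix(sm)
    } else {
      unlist(sm)
    }
  }
  do.call(game_config, raw)
}

#' Write simulation outputs and a run manifest
#'
#' Emits the standard output set under `dir`: `summary.csv` (per-category
#' counts and wealth), `series.csv` (per-round time series), `deaths.csv`
#' (death log), `agents.csv` (final per-player state) and `manifest.json`
#' — a snapshot of the configuration, seed, package version, timestamp and
#' output paths from which the run can be reproduced exactly.
#'
#' @param result A [run_simulation()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "farmers_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(summary = file.path(dir, "summary.csv"),
                series = file.path(dir, "series.csv"),
                deaths = file.path(dir, "deaths.csv"),
                agents = file.path(dir, "agents.csv"))
  utils::write.csv(result$summary, paths$summary, row.names = FALSE)
  utils::write.csv(result$series, paths$series, row.names = FALSE)
  utils::write.csv(result$deaths, paths$deaths, row.names = FALSE)
  utils::write.csv(result$agents, paths$agents, row.names = FALSE)
  manifest <- run_manifest(result$config, paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# Manifest snapshot: everything needed to rerun bit-for-bit with the same
# package version.
run_manifest <- function(config, paths = list()) {
  cfg <- unclass(config)
  cfg$payoffs <- unclass(cfg$payoffs)
  cfg$strategy_mix <- as.list(cfg$strategy_mix)
  list(package = "farmersgame",
       version = as.character(utils::packageVersion("farmersgame")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = config$seed,
       config = cfg,
       outputs = paths)
}

#' Round-trip a manifest back into a configuration
#'
#' @param path Path to a `manifest.json` written by [write_result()].
#' @return The validated [game_config()] recorded in the manifest.
#' @export
read_manifest_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  cfg$payoffs <- do.call(payoff_matrix, as.list(cfg$payoffs))
  cfg$strategy_mix <- unlist(cfg$strategy_mix)
  cfg$borderless <- isTRUE(cfg$borderless)
  do.call(game_config, cfg)
}
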