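#' Load and validate a run configuration
#'
#' Resolves a run configuration against the defaults and validates it.  The
#' configuration drives [build_network()] / [run_simulation()]: network
#' state, scale, duration, integration step, out-of-field switch, and
#' arbitrary parameter overrides under `params` (merged recursively over
#' [ca1_defaults()]).  Unknown top-level keys are rejected with a hint at
#' the nearest valid key; all violations are reported together.
#'
#' @param config path to a YAML/JSON file, or a named list, or a
#'   `run_config`.
#' @return object of class `run_config` with all defaults resolved.
#' @export
load_run_config <- function(config = list()) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(state = "theta", scale = 0.05, duration = 60000,
                   dt = 0.1, out_of_field = FALSE, params = list())
  errs <- character(0)
  for (k in names(config)) {
    if (!k %in% names(defaults)) {
      near <- agrep(k, names(defaults), max.distance = 0.4, value = TRUE)
      errs <- c(errs, paste0("unknown key '", k, "'",
                             if (length(near)) paste0(" (did you mean '",
                                                      near[1], "'?)")))
    }
  }
  cfg <- modifyList(defaults, config[names(config) %in% names(defaults)])
  if (!cfg$state %in% c("theta", "non_theta"))
    errs <- c(errs, "state must be 'theta' or 'non_theta'")
  if (!is.numeric(cfg$scale) || cfg$scale <= 0 || cfg$scale > 1)
    errs <- c(errs, "scale must be in (0, 1]")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    errs <- c(errs, "duration must be positive (ms)")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0 || cfg$dt > 0.1)
    errs <- c(errs, "dt must be in (0, 0.1] ms")
  if (length(cfg$params)) {
    pops <- names(ca1_defaults()$populations)
    for (p in names(cfg$params$populations))
      if (!p %in% pops)
        errs <- c(errs, paste0("unknown population '", p, "'"))
    for (b in names(cfg$params$bands)) {
      bb <- cfg$params$bands[[b]]
      if (length(bb) == 2 && bb[[1]] >= bb[[2]])
        errs <- c(errs, paste0("band '", b, "': low >= high"))
    }
  }
  if (length(errs)) stop("invalid run config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg$params <- ca1_defaults(cfg$params)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$state, "state, scale", x$scale, ", duration",
      x$duration, "ms, dt", x$dt, "ms\n")
  invisible(x)
}

recording_fingerprint <- function(recording) {
  cfg <- recording$config
  paste0("state=", cfg$state, ";scale=", cfg$scale, ";duration=",
         recording$duration, ";dt=", recording$dt, ";seed=", recording$seed)
}

#' Write / read a recording
#'
#' Serializes a `ca1_recording` to a single file (RDS container; the logical
#' layout keeps the group naming `spikes/<pop>`, `vm/<pop>`,
#' `currents/pyr/<compartment>`, `lfp/<depth>`, `meta/config` used by the
#' export helpers).  The round trip is exact: spike times and all floating
#' point series are restored bit-identically.
#'
#' @param recording a `ca1_recording`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ca1_recording"))
  recording$meta <- list(fingerprint = recording_fingerprint(recording),
                         seed = recording$seed,
                         written = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read recording '", path, "': ", conditionMessage(e)))
  if (!inherits(rec, "ca1_recording"))
    stop("file '", path, "' does not contain a ca1_recording")
  rec
}

#' Export spikes of a recording as CSV
#' @param recording a `ca1_recording`.
#' @param path output file.
#' @export
export_spikes_csv <- function(recording, path) {
  utils::write.csv(recording$spikes, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an analysis report to JSON
#' @param result a `coupling_result`.
#' @param path output file.
#' @export
write_report_json <- function(result, path) {
  out <- unclass(result)
  out$amplitude_map$map <- unclass(out$amplitude_map$map)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
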