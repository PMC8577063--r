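#' @useDynLib ca1rhythms, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx fft rnorm runif rpois quantile sd setNames
#' @importFrom utils head tail modifyList
NULL

.ca1_env <- new.env(parent = emptyenv())

#' Default model parameters
#'
#' Loads the shipped parameter file (cell templates, receptor classes,
#' population sizes, generator settings, the connection matrix, LFP and band
#' defaults).  The file is plain YAML under `inst/extdata/defaults.yaml`;
#' every value can be overridden through `overrides` or from a run config.
#'
#' @param overrides optional named list merged recursively over the defaults.
#' @return nested list of parameters.
#' @export
ca1_defaults <- function(overrides = NULL) {
  if (is.null(.ca1_env$defaults)) {
    path <- system.file("extdata", "defaults.yaml", package = "ca1rhythms")
    .ca1_env$defaults <- yaml::read_yaml(path)
  }
  out <- .ca1_env$defaults
  if (!is.null(overrides)) out <- merge_params(out, overrides)
  out
}

# recursive list merge; atomic values in `over` replace defaults
merge_params <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_params(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

# deterministic child seeds below 2^31 derived from one user seed
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}
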