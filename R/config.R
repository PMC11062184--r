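#' Read a pipeline configuration from YAML
#'
#' The configuration declares the condition vocabulary (ordered list of
#' labels) and any overrides for simulation and analysis settings, so
#' synthetic and externally derived matrices share one schema. Unknown
#' keys are rejected to catch typos early.
#'
#' @param path path to a YAML file. Recognized keys: `conditions`,
#'   `reference`, any [sim_config()] argument under `simulate:`, and
#'   `decimals` (floating-point serialization width, default 6).
#' @return named list with elements `conditions`, `reference`, `decimals`
#'   and `simulate` (argument list for [sim_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("conditions", "reference", "decimals", "simulate")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  sim <- raw$simulate %||% list()
  bad <- setdiff(names(sim), names(formals(sim_config)))
  if (length(bad))
    stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
  list(conditions = raw$conditions %||% sim$conditions,
       reference = raw$reference %||% "0w",
       decimals = raw$decimals %||% 6L,
       simulate = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
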