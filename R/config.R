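#' @importFrom yaml read_yaml write_yaml
#' @importFrom jsonlite write_json
NULL

config_sections <- c("parameters", "release", "simulation")
release_keys <- c("sigma", "batch", "period", "start")
simulation_keys <- c("model", "horizon", "init", "scenario", "preference",
                     "seed", "replicates", "sigmas", "scenarios",
                     "sigma_grid", "axis1", "axis2", "cap",
                     "wild_males", "females", "larvae", "sterile_males",
                     "females_mated", "command")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Read a structured run configuration
#'
#' Configurations are YAML files with up to three sections:
#' \code{parameters} (all twelve biological parameters, required as a
#' block when present), \code{release} and \code{simulation}. Unknown
#' sections or keys are an error, not a warning, so typos cannot silently
#' fall back to defaults.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements \code{params} (\code{\link{sit_params}} or
#'   NULL), \code{release} (\code{\link{release_policy}}) and
#'   \code{simulation} (named list).
#' @export
read_sit_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, config_sections, "config")
  params <- NULL
  if (!is.null(cfg$parameters)) {
    check_keys(cfg$parameters, param_fields, "parameters")
    missing <- setdiff(param_fields, names(cfg$parameters))
    if (length(missing))
      stop("parameters section missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    params <- do.call(sit_params, cfg$parameters)
  }
  rel <- release_policy(0)
  if (!is.null(cfg$release)) {
    check_keys(cfg$release, release_keys, "release")
    rel <- do.call(release_policy, cfg$release)
  }
  sim <- list()
  if (!is.null(cfg$simulation)) {
    check_keys(cfg$simulation, simulation_keys, "simulation")
    sim <- cfg$simulation
  }
  list(params = params, release = rel, simulation = sim)
}

#' Write a run configuration
#'
#' Round-trips with \code{\link{read_sit_config}}: every parameter field is
#' preserved exactly.
#'
#' @param config A list with optional \code{params}, \code{release} and
#'   \code{simulation} entries (as produced by \code{read_sit_config} or a
#'   preset).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sit_config <- function(config, path) {
  out <- list()
  if (!is.null(config$params))
    out$parameters <- unclass(config$params)
  if (!is.null(config$release))
    out$release <- unclass(config$release)
  if (length(config$simulation))
    out$simulation <- config$simulation
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
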