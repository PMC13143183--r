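json_sidecar <- function(path, meta) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(side)
}

#' Write an ODE trajectory to CSV with a JSON metadata sidecar
#'
#' Columns \code{day,L,M,F_U,F_I,F_F,S}; the \code{F_U} column is blank for
#' reduced-model trajectories. The sidecar (same name, \code{.json})
#' records the parameters, release rate, model tag and integrator settings.
#'
#' @param traj A \code{sit_trajectory} from \code{\link{simulate_sit}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sit_trajectory"))
  out <- as.data.frame(traj)
  if (!"F_U" %in% names(out)) out$F_U <- NA_real_
  out <- out[, c("day", "L", "M", "F_U", "F_I", "F_F", "S")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  json_sidecar(path, list(model = attr(traj, "model"),
                          sigma = attr(traj, "sigma"),
                          parameters = unclass(attr(traj, "params")),
                          integrator = attr(traj, "integrator")))
  invisible(path)
}

#' Write a bifurcation table to long-format CSV
#'
#' @param tab A \code{sit_bifurcation} from \code{\link{bifurcation_diagram}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_bifurcation <- function(tab, path) {
  stopifnot(inherits(tab, "sit_bifurcation"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Write a threshold heatmap to long-format CSV
#'
#' Columns \code{axis1,axis2,sigma_bar} (capped values).
#'
#' @param hm A \code{sit_heatmap} from \code{\link{threshold_heatmap}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  stopifnot(inherits(hm, "sit_heatmap"))
  a1 <- attr(hm, "axis1"); a2 <- attr(hm, "axis2")
  long <- expand.grid(axis1 = a1$grid, axis2 = a2$grid)
  long$sigma_bar <- as.vector(unclass(hm))
  names(long)[1:2] <- c(a1$name, a2$name)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write an ABM time series to CSV with its configuration as JSON sidecar
#'
#' @param series An \code{abm_series} from \code{\link{run_abm}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_abm_series <- function(series, path) {
  stopifnot(inherits(series, "abm_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  cfg <- attr(series, "config")
  json_sidecar(path, list(
    parameters = unclass(cfg$params),
    scenario = unclass(cfg$scenario),
    release = unclass(cfg$release),
    init = cfg[c("wild_males", "females", "larvae", "sterile_males",
                 "females_mated")],
    horizon = cfg$horizon, seed = cfg$seed))
  invisible(path)
}

#' Write a reduction-summary table to CSV
#'
#' @param x A \code{sit_reduction_summary} from \code{\link{replicate_sweep}}.
#' @param path Output CSV path.
#' @param replicates If TRUE, also write the per-replicate long table next
#'   to it (suffix \code{_replicates.csv}).
#' @return \code{path}, invisibly.
#' @export
write_reduction_summary <- function(x, path, replicates = FALSE) {
  stopifnot(inherits(x, "sit_reduction_summary"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  if (replicates)
    utils::write.csv(attr(x, "replicates"),
                     paste0(tools::file_path_sans_ext(path),
                            "_replicates.csv"),
                     row.names = FALSE)
  invisible(path)
}
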