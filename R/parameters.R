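#' Biological parameter set for the SIT models
#'
#' Constructs and validates the full set of biological rates and constants
#' used by both the compartmental ODE models and the agent-based simulator.
#' All rates are per day; the time unit is the day throughout the package.
#'
#' @param omega Egg-laying rate of fertilized females (eggs female^-1 day^-1).
#' @param nu Larval hatching (maturation to adult) rate, day^-1.
#' @param p Sex ratio: proportion of males among emerging adults, in [0, 1].
#' @param mu_L,mu_M,mu_F,mu_S Stage-specific mortality rates for larvae, wild
#'   males, females and sterilized males, day^-1.
#' @param chi Mating rate of available females, day^-1.
#' @param eta Sterilized-male competitiveness relative to wild males, in
#'   [0, 1]: matings go to sterilized males in proportion eta*S/(M + eta*S).
#' @param K Larval carrying capacity (maximum juveniles the fruit resource
#'   supports); enters oviposition through the logistic factor (1 - L/K).
#' @param tau_F,tau_I Refractory rates (inverse of the mean time before a
#'   mated female becomes available again), day^-1, after mating with a wild
#'   (tau_F) or sterilized (tau_I) male.
#'
#' @return An object of class \code{sit_params}: a named list of the twelve
#'   parameters. The object is treated as immutable; derive variants with
#'   \code{\link{update_params}}.
#' @seealso \code{\link{suzukii_params}} for the Drosophila suzukii preset.
#' @export
sit_params <- function(omega, nu, p, mu_L, mu_M, mu_F, mu_S,
                       chi, eta, K, tau_F, tau_I) {
  x <- list(omega = omega, nu = nu, p = p,
            mu_L = mu_L, mu_M = mu_M, mu_F = mu_F, mu_S = mu_S,
            chi = chi, eta = eta, K = K, tau_F = tau_F, tau_I = tau_I)
  validate_sit_params(x)
  structure(x, class = "sit_params")
}

#' @export
print.sit_params <- function(x, ...) {
  cat("SIT model parameters (per-day rates):\n")
  for (nm in names(x)) cat(sprintf("  %-6s = %g\n", nm, x[[nm]]))
  invisible(x)
}

param_fields <- c("omega", "nu", "p", "mu_L", "mu_M", "mu_F", "mu_S",
                  "chi", "eta", "K", "tau_F", "tau_I")

validate_sit_params <- function(x) {
  for (nm in param_fields) {
    v <- x[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in setdiff(param_fields, c("p", "eta", "K"))) {
    if (x[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("p", "eta")) {
    if (x[[nm]] < 0 || x[[nm]] > 1)
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (x$K <= 0) stop("parameter 'K' must be strictly positive", call. = FALSE)
  invisible(x)
}

#' Default parameter preset calibrated for Drosophila suzukii
#'
#' Returns the parameter set estimated for the spotted-wing drosophila in a
#' ~500 m^2 strawberry tunnel: high fecundity (6 eggs per female per day),
#' fast mating (chi = 10 day^-1, essentially immediate), moderate
#' sterilized-male competitiveness (eta = 0.6) and refractory rates giving
#' mean re-mating delays of ~8 days (after a wild mate) and ~7 days (after a
#' sterilized mate).
#'
#' @return A \code{\link{sit_params}} object.
#' @examples
#' pr <- suzukii_params()
#' basic_reproduction_number(pr)
#' @export
suzukii_params <- function() {
  sit_params(omega = 6, nu = 0.08, p = 0.50,
             mu_L = 0.037, mu_M = 0.013, mu_F = 0.012, mu_S = 0.054,
             chi = 10, eta = 0.60, K = 36000,
             tau_F = 0.12, tau_I = 0.14)
}

#' Derive a parameter variant by overriding selected fields
#'
#' Parameter objects are immutable; sweeps and scenario variants are built by
#' copying with overrides so shared state is never mutated.
#'
#' @param object A \code{\link{sit_params}} object. (Named \code{object}
#'   so partial matching cannot confuse it with the parameter \code{p}.)
#' @param ... Named scalar overrides, e.g. \code{tau_F = 0, tau_I = 0}.
#' @return A new validated \code{sit_params} object.
#' @export
update_params <- function(object, ...) {
  stopifnot(inherits(object, "sit_params"))
  ov <- list(...)
  bad <- setdiff(names(ov), param_fields)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x <- unclass(object)
  x[names(ov)] <- ov
  do.call(sit_params, x)
}

#' Basic reproduction number
#'
#' Average number of viable female offspring produced by a single pest female
#' over her lifetime: R0 = omega * (1 - p) * nu / (mu_F * (mu_L + nu)).
#' The pest persists without control only when R0 > 1.
#'
#' @param params A \code{\link{sit_params}} object.
#' @return Dimensionless scalar.
#' @export
basic_reproduction_number <- function(params) {
  stopifnot(inherits(params, "sit_params"))
  if (params$mu_F == 0 || params$mu_L + params$nu == 0)
    stop("R0 undefined: mu_F and mu_L + nu must be positive", call. = FALSE)
  params$omega * (1 - params$p) * params$nu /
    (params$mu_F * (params$mu_L + params$nu))
}

#' Male-production factor gamma = nu * p / mu_M
#'
#' Ratio converting larval density to the equilibrium wild-male density it
#' sustains (M* = gamma * L*).
#'
#' @param params A \code{\link{sit_params}} object.
#' @return Dimensionless scalar.
#' @export
gamma_factor <- function(params) {
  stopifnot(inherits(params, "sit_params"))
  if (params$mu_M == 0)
    stop("gamma undefined: mu_M must be positive", call. = FALSE)
  params$nu * params$p / params$mu_M
}

#' Derived quantities of a parameter set
#'
#' @param params A \code{\link{sit_params}} object.
#' @return A list with \code{gamma}, \code{R0} and \code{sigma_bar} (the
#'   eradication threshold, see \code{\link{eradication_threshold}}).
#' @export
derived_quantities <- function(params) {
  list(gamma = gamma_factor(params),
       R0 = basic_reproduction_number(params),
       sigma_bar = eradication_threshold(params))
}

#' Sterilized-male release policy
#'
#' For the ODE models only \code{sigma} (a constant release rate,
#' individuals day^-1) is used. The agent-based model releases a batch of
#' \code{batch} males every \code{period} days starting on \code{start}
#' (day 1 is the first simulated day); the default daily batch of
#' \code{sigma} males matches the ODE's constant rate.
#'
#' @param sigma Release rate, individuals per day (>= 0).
#' @param batch Batch size per release event (integer >= 0); defaults to
#'   \code{sigma}.
#' @param period Days between release events (integer >= 1).
#' @param start First release day (integer >= 0).
#' @return An object of class \code{sit_release}.
#' @export
release_policy <- function(sigma = 0, batch = sigma, period = 1, start = 1) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  batch <- as.integer(round(batch))
  if (batch < 0) stop("'batch' must be >= 0", call. = FALSE)
  if (period < 1) stop("'period' must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, batch = batch,
                 period = as.integer(period), start = as.integer(start)),
            class = "sit_release")
}
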