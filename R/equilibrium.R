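#' Release-rate equivalent of an infestation equilibrium
#'
#' The infestation equilibria of the reduced model are the roots in L* of
#' zeta(L*) = sigma, where
#' zeta(L*) = gamma * mu_S * (mu_F + tau_I) / (eta * (mu_F + tau_F)) *
#'            (-(R0/K) L*^2 + (R0 - 1) L*)
#' is a downward parabola in larval density with roots at 0 and
#' K (1 - 1/R0). Its summit is the eradication threshold.
#'
#' @param L_star Larval density at equilibrium (>= 0); vectorized.
#' @param params A \code{\link{sit_params}} object with eta > 0.
#' @return zeta evaluated at \code{L_star} (release-rate units,
#'   individuals day^-1).
#' @export
zeta <- function(L_star, params) {
  stopifnot(inherits(params, "sit_params"))
  if (params$eta == 0)
    stop("zeta undefined when eta = 0 (sterilized males never mate)",
         call. = FALSE)
  R0 <- basic_reproduction_number(params)
  A <- gamma_factor(params) * params$mu_S * (params$mu_F + params$tau_I) /
    (params$eta * (params$mu_F + params$tau_F))
  A * (-(R0 / params$K) * L_star^2 + (R0 - 1) * L_star)
}

#' Eradication threshold (critical release rate)
#'
#' The summit of the zeta parabola:
#' sigma_bar = K * gamma * mu_S * (R0 - 1)^2 * (mu_F + tau_I) /
#'             (4 * eta * R0 * (mu_F + tau_F)).
#' Releasing sterilized males at any constant rate above sigma_bar leaves
#' the pest-free equilibrium as the only stable state (a saddle-node
#' bifurcation: the stable and unstable infestation equilibria collide and
#' vanish at sigma_bar). When R0 <= 1 the pest dies out on its own and the
#' threshold is 0. Note sigma_bar depends on the refractory rates only
#' through the ratio (mu_F + tau_I)/(mu_F + tau_F): equal re-mating rates
#' (tau_F = tau_I) leave the threshold identical to the no-re-mating case.
#'
#' @param params A \code{\link{sit_params}} object.
#' @return Release rate, individuals day^-1.
#' @export
eradication_threshold <- function(params) {
  stopifnot(inherits(params, "sit_params"))
  R0 <- basic_reproduction_number(params)
  if (R0 <= 1) return(0)
  if (params$eta == 0)
    stop("eradication threshold is infinite when eta = 0 and R0 > 1",
         call. = FALSE)
  params$K * gamma_factor(params) * params$mu_S * (R0 - 1)^2 *
    (params$mu_F + params$tau_I) /
    (4 * params$eta * R0 * (params$mu_F + params$tau_F))
}

# Complete an infestation root L* of zeta(L*) = sigma to a full reduced-model
# state by back-substitution: M* = nu*p*L*/mu_M, S* = sigma/mu_S, F_F* from
# the L-equation, F_I* from the F_I-equation.
complete_equilibrium <- function(L_star, params, sigma) {
  with(unclass(params), {
    M <- nu * p * L_star / mu_M
    S <- if (mu_S > 0) sigma / mu_S else 0
    F_F <- (mu_L + nu) * L_star / (omega * (1 - L_star / K))
    tot <- M + eta * S
    fs <- if (tot > 0) eta * S / tot else 0
    fw <- if (tot > 0) M / tot else 0
    F_I <- (nu * (1 - p) * fs * L_star + tau_F * fs * F_F) /
      (mu_F + tau_I * fw)
    c(L = L_star, M = M, F_I = F_I, F_F = F_F, S = S)
  })
}

new_equilibrium <- function(state, kind, stability = NA_character_) {
  structure(list(state = state, kind = kind, stability = stability,
                 L_star = unname(state[["L"]])),
            class = "sit_equilibrium")
}

#' @export
print.sit_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (%s): L* = %.4g\n", x$kind,
              ifelse(is.na(x$stability), "unclassified", x$stability),
              x$L_star))
  print(round(x$state, 4))
  invisible(x)
}

#' Equilibria of the reduced model at a given release rate
#'
#' The pest-free equilibrium (all pest compartments 0, S = sigma/mu_S)
#' always exists. Infestation equilibria are the real roots in (0, K) of
#' the quadratic zeta(L*) = sigma, solved in closed form and completed by
#' back-substitution; the root below the parabola vertex K/2 (1 - 1/R0) is
#' labelled \code{infestation-low} (E1*), the one above
#' \code{infestation-high} (E2*). At sigma = sigma_bar exactly (double
#' root) a single infestation equilibrium labelled \code{marginal} is
#' returned.
#'
#' @param params A \code{\link{sit_params}} object.
#' @param sigma Release rate (>= 0).
#' @param classify If TRUE (default) attach Jacobian-based stability labels
#'   via \code{\link{classify_stability}}.
#' @return List of \code{sit_equilibrium} objects (pest-free first).
#' @export
find_equilibria <- function(params, sigma, classify = TRUE) {
  stopifnot(inherits(params, "sit_params"), sigma >= 0)
  S_star <- if (params$mu_S > 0) sigma / params$mu_S else 0
  eqs <- list(new_equilibrium(
    c(L = 0, M = 0, F_I = 0, F_F = 0, S = S_star), "pest-free"))
  R0 <- basic_reproduction_number(params)
  if (R0 > 1 && params$eta > 0) {
    # A*(R0/K) L^2 - A*(R0-1) L + sigma = 0
    A <- gamma_factor(params) * params$mu_S *
      (params$mu_F + params$tau_I) /
      (params$eta * (params$mu_F + params$tau_F))
    a <- A * R0 / params$K
    b <- -A * (R0 - 1)
    disc <- b^2 - 4 * a * sigma
    vertex <- params$K / 2 * (1 - 1 / R0)
    if (abs(disc) <= 1e-12 * b^2) {
      eqs <- c(eqs, list(new_equilibrium(
        complete_equilibrium(vertex, params, sigma), "marginal")))
    } else if (disc > 0) {
      roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
      roots <- roots[roots > 0 & roots < params$K]
      kinds <- ifelse(roots < vertex, "infestation-low", "infestation-high")
      for (i in seq_along(roots))
        eqs <- c(eqs, list(new_equilibrium(
          complete_equilibrium(roots[i], params, sigma), kinds[i])))
    }
  }
  if (classify)
    eqs <- lapply(eqs, function(e) {
      e$stability <- classify_stability(e, params, sigma)
      e
    })
  eqs
}

# Jacobian of the reduced RHS by central finite differences; relative step
# 1e-6 per component with an absolute floor for components at zero.
reduced_jacobian <- function(state, params, sigma) {
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(names(state), names(state)))
  for (j in seq_len(n)) {
    h <- 1e-6 * max(abs(state[j]), 1)
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (reduced_rhs(up, params, sigma) -
                 reduced_rhs(dn, params, sigma)) / (2 * h)
  }
  J
}

#' Stability of an equilibrium from Jacobian eigenvalues
#'
#' Classifies local stability numerically: \code{stable} when the largest
#' real part of the reduced-model Jacobian eigenvalues is below -tol,
#' \code{unstable} when above +tol, and \code{marginal} in between (never
#' silently binned).
#'
#' @param eq A \code{sit_equilibrium} (or named reduced-model state vector).
#' @param params A \code{\link{sit_params}} object.
#' @param sigma Release rate used for the equilibrium.
#' @param tol Absolute tolerance on max Re(lambda), day^-1.
#' @return One of `"stable"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(eq, params, sigma, tol = 1e-9) {
  state <- if (inherits(eq, "sit_equilibrium")) eq$state else eq
  J <- reduced_jacobian(state, params, sigma)
  mre <- max(Re(eigen(J, only.values = TRUE)$values))
  if (mre < -tol) "stable" else if (mre > tol) "unstable" else "marginal"
}

#' Bifurcation diagram of larval equilibrium density versus release rate
#'
#' For each sigma on the grid, lists every equilibrium with its stability
#' label. Below sigma_bar (with R0 > 1) there are three equilibria: the
#' stable pest-free state, the unstable low-infestation branch E1* and the
#' stable high-infestation branch E2*; the two infestation branches meet and
#' disappear at sigma_bar (saddle-node bifurcation).
#'
#' @param params A \code{\link{sit_params}} object.
#' @param sigma_grid Non-empty vector of release rates (>= 0).
#' @return A \code{sit_bifurcation} data.frame with columns
#'   \code{sigma}, \code{L_star}, \code{kind}, \code{stability}.
#' @export
bifurcation_diagram <- function(params, sigma_grid) {
  stopifnot(length(sigma_grid) > 0, all(sigma_grid >= 0))
  rows <- lapply(sigma_grid, function(s) {
    eqs <- find_equilibria(params, s)
    data.frame(sigma = s,
               L_star = vapply(eqs, function(e) e$L_star, numeric(1)),
               kind = vapply(eqs, function(e) e$kind, character(1)),
               stability = vapply(eqs, function(e) e$stability, character(1)))
  })
  structure(do.call(rbind, rows),
            class = c("sit_bifurcation", "data.frame"),
            sigma_bar = eradication_threshold(params))
}

#' Eradication-threshold heatmap over two parameter axes
#'
#' Evaluates sigma_bar on a 2-D grid over two of the parameters
#' \code{tau_F}, \code{tau_I}, \code{eta}, holding the rest at their values
#' in \code{params}. Values above \code{cap} are replaced by \code{cap}
#' (raw values are kept in the \code{raw} attribute).
#'
#' @param params Base \code{\link{sit_params}}.
#' @param axis1,axis2 Named lists \code{list(name =, grid =)} with distinct
#'   names among \code{"tau_F"}, \code{"tau_I"}, \code{"eta"}.
#' @param cap Ceiling applied to the reported threshold (default 1e6).
#' @return A matrix (axis1 on rows, axis2 on columns) of capped sigma_bar
#'   values, with axis metadata and raw values as attributes.
#' @export
threshold_heatmap <- function(params,
                              axis1 = list(name = "tau_F",
                                           grid = seq(0, 0.5, length.out = 100)),
                              axis2 = list(name = "tau_I",
                                           grid = seq(0, 0.5, length.out = 100)),
                              cap = 1e6) {
  allowed <- c("tau_F", "tau_I", "eta")
  for (ax in list(axis1, axis2))
    if (!ax$name %in% allowed)
      stop("heatmap axis must be one of ", paste(allowed, collapse = ", "),
           call. = FALSE)
  if (axis1$name == axis2$name) stop("axes must differ", call. = FALSE)
  raw <- outer(seq_along(axis1$grid), seq_along(axis2$grid),
               Vectorize(function(i, j) {
                 ov <- stats::setNames(list(axis1$grid[i], axis2$grid[j]),
                                       c(axis1$name, axis2$name))
                 eradication_threshold(do.call(update_params,
                                               c(list(params), ov)))
               }))
  dimnames(raw) <- list(signif(axis1$grid, 8), signif(axis2$grid, 8))
  structure(pmin(raw, cap), raw = raw, cap = cap,
            axis1 = axis1, axis2 = axis2, class = c("sit_heatmap", "matrix"))
}

#' Transient advantage of re-mating: First vs Last larval reduction
#'
#' For each release rate, simulates the reduced model under the First
#' scenario (tau_F = tau_I = 0, no effective re-mating), the Last scenario
#' (refractory rates as in \code{params}) and the no-release baseline WR
#' (sigma = 0), all from a high-infestation initial state, and returns
#' (L_First - L_Last) / L_WR on the shared daily grid. Positive entries
#' mean the Last scenario has reduced larvae further at that time; negative
#' entries mean the First scenario is ahead. Cells where the baseline has
#' collapsed (L_WR < 1) are NA (undefined).
#'
#' @param params A \code{\link{sit_params}} object (its tau values define
#'   the Last scenario).
#' @param sigma_grid Release rates to scan.
#' @param horizon Days to simulate (default 3000).
#' @param init Initial reduced-model state; default high infestation
#'   L = 30000, M = 100000, F_I = 0, F_F = 100000 (S is set to sigma/mu_S
#'   per run so releases start at their equilibrium standing density).
#' @return Matrix with one row per sigma and one column per day, with the
#'   grids attached as attributes.
#' @export
transient_comparison <- function(params, sigma_grid, horizon = 3000,
                                 init = c(L = 30000, M = 100000,
                                          F_I = 0, F_F = 100000)) {
  first_p <- update_params(params, tau_F = 0, tau_I = 0)
  base_init <- c(init[c("L", "M", "F_I", "F_F")], S = 0)
  wr <- simulate_sit("reduced", base_init, params, 0, horizon)
  out <- t(vapply(sigma_grid, function(s) {
    ini <- base_init
    ini[["S"]] <- if (params$mu_S > 0) s / params$mu_S else 0
    lf <- simulate_sit("reduced", ini, first_p, s, horizon)$L
    ll <- simulate_sit("reduced", ini, params, s, horizon)$L
    d <- (lf - ll) / wr$L
    d[wr$L < 1] <- NA_real_
    d
  }, numeric(horizon + 1)))
  structure(out, sigma = sigma_grid, day = 0:horizon,
            class = c("sit_transient", "matrix"))
}
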