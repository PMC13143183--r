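# Shared fixtures built in code.

# Random valid parameter set with R0 > 1, for property-style tests.
random_params <- function() {
  repeat {
    pr <- try(sit_params(
      omega = runif(1, 1, 12),
      nu = runif(1, 0.02, 0.2),
      p = runif(1, 0.2, 0.8),
      mu_L = runif(1, 0.005, 0.1),
      mu_M = runif(1, 0.005, 0.1),
      mu_F = runif(1, 0.005, 0.1),
      mu_S = runif(1, 0.01, 0.2),
      chi = runif(1, 1, 20),
      eta = runif(1, 0.1, 1),
      K = runif(1, 1e3, 1e5),
      tau_F = runif(1, 0, 0.5),
      tau_I = runif(1, 0, 0.5)), silent = TRUE)
    if (!inherits(pr, "try-error") && basic_reproduction_number(pr) > 1.05)
      return(pr)
  }
}

# Scenario presets used throughout: Table-2 parameters are the Last
# scenario; zeroing both refractory rates gives the First scenario.
first_params <- function() update_params(suzukii_params(), tau_F = 0, tau_I = 0)

high_infestation_init <- function(sigma, params = suzukii_params()) {
  c(L = 30000, M = 100000, F_I = 0, F_F = 100000, S = sigma / params$mu_S)
}

low_infestation_init <- function(sigma, params = suzukii_params()) {
  c(L = 100, M = 300, F_I = 0, F_F = 300, S = sigma / params$mu_S)
}

trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2)
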