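#' Sperm-use scenario
#'
#' Rule deciding which stored mate's sperm fertilizes each egg of a
#' polyandrous female:
#' \describe{
#'   \item{first}{exclusive use of the first mate's sperm (equivalent to no
#'     multiple mating as far as offspring are concerned);}
#'   \item{last}{exclusive use of the most recent mate's sperm;}
#'   \item{mixed}{fertile sperm used in proportion to the fraction of
#'     fertile matings stored;}
#'   \item{preference_w}{complete preference for fertile (wild-male) sperm
#'     whenever any is stored;}
#'   \item{preference_i}{relative preference for fertile sperm: when both
#'     kinds are stored, fertile sperm is used with probability
#'     \code{preference} (default 0.8);}
#'   \item{preference_s}{complete preference for sterilized sperm whenever
#'     any is stored (the most favourable case for SIT).}
#' }
#'
#' @param name Scenario name (see above).
#' @param preference Preference weight in [0, 1] for fertile sperm, used by
#'   \code{preference_i} only.
#' @return An object of class \code{sperm_scenario}.
#' @export
sperm_scenario <- function(name = c("first", "last", "mixed", "preference_w",
                                    "preference_i", "preference_s"),
                           preference = 0.8) {
  name <- match.arg(name)
  if (length(preference) != 1L || preference < 0 || preference > 1)
    stop("'preference' must be a single value in [0, 1]", call. = FALSE)
  structure(list(name = name, preference = preference),
            class = "sperm_scenario")
}

#' Per-female sperm store
#'
#' Ordered record of a female's matings; the order is the mating order and
#' is never rearranged. A female with an empty store lays no viable eggs.
#'
#' @param origins Character vector in mating order, entries \code{"fertile"}
#'   (wild mate) or \code{"sterile"}.
#' @param days Optional mating days (same length).
#' @return An object of class \code{sperm_store}.
#' @export
sperm_store <- function(origins = character(),
                        days = rep(NA_real_, length(origins))) {
  if (!all(origins %in% c("fertile", "sterile")))
    stop("store origins must be 'fertile' or 'sterile'", call. = FALSE)
  if (length(days) != length(origins))
    stop("'days' must match 'origins' in length", call. = FALSE)
  structure(list(origins = origins, days = days), class = "sperm_store")
}

# Probability that an egg is fertilized by fertile sperm, vectorized over
# females summarized by (# fertile records, # sterile records, first origin,
# last origin) with origin codes 1 = fertile, 2 = sterile. These four
# statistics are sufficient for all six scenarios.
fertile_use_prob <- function(scenario, nf, ns, first, last) {
  switch(scenario$name,
         first = as.numeric(first == 1L),
         last = as.numeric(last == 1L),
         mixed = nf / pmax(nf + ns, 1L),
         preference_w = as.numeric(nf > 0L),
         preference_i = ifelse(nf > 0L & ns > 0L,
                               scenario$preference, as.numeric(nf > 0L)),
         preference_s = as.numeric(ns == 0L))
}

#' Draw the sperm origin used for one egg
#'
#' Applies the scenario rule to a non-empty store. \code{first}, \code{last},
#' \code{preference_w} and \code{preference_s} are deterministic given the
#' store; \code{mixed} and \code{preference_i} are random draws.
#'
#' @param scenario A \code{\link{sperm_scenario}}.
#' @param store A non-empty \code{\link{sperm_store}}.
#' @return \code{"fertile"} or \code{"sterile"}.
#' @export
sperm_selection <- function(scenario, store) {
  stopifnot(inherits(scenario, "sperm_scenario"), inherits(store, "sperm_store"))
  n <- length(store$origins)
  if (n == 0L)
    stop("sperm_selection requires a non-empty store", call. = FALSE)
  nf <- sum(store$origins == "fertile")
  p <- fertile_use_prob(scenario, nf, n - nf,
                        ifelse(store$origins[1] == "fertile", 1L, 2L),
                        ifelse(store$origins[n] == "fertile", 1L, 2L))
  if (stats::runif(1) < p) "fertile" else "sterile"
}

#' Female agent
#'
#' @param refractory Days remaining before the female can mate again
#'   (0 = available; may be \code{Inf} when the refractory rate is 0).
#' @param store A \code{\link{sperm_store}}.
#' @param age Age in days.
#' @return An object of class \code{female_agent}.
#' @export
female_agent <- function(refractory = 0, store = sperm_store(), age = 0) {
  if (refractory < 0) stop("'refractory' must be >= 0", call. = FALSE)
  structure(list(alive = TRUE, refractory = refractory,
                 store = store, age = age),
            class = "female_agent")
}

# Daily refractory duration after mating: the ODE's exponential refractory
# sojourn (rate tau) is discretized as a geometric number of full days with
# daily end-probability 1 - exp(-tau); tau = 0 means the female never
# re-mates (infinite refractory).
draw_refractory <- function(n, tau) {
  q <- 1 - exp(-tau)
  if (q <= 0) rep(Inf, n) else stats::rgeom(n, q)
}

#' One mating opportunity for an available female
#'
#' With wild and sterilized males present, the female mates with daily
#' probability 1 - exp(-chi) (~1 at chi = 10); the mate is sterilized with
#' probability eta*S/(M + eta*S) and wild otherwise. A record is appended to
#' her store and a refractory duration is drawn geometrically with daily
#' end-probability 1 - exp(-tau_F) (wild mate) or 1 - exp(-tau_I)
#' (sterilized mate). When no effective mates exist (M + eta*S = 0) nothing
#' happens.
#'
#' @param female A \code{\link{female_agent}} with \code{refractory == 0}.
#' @param wild_count,sterile_count Current male counts.
#' @param params A \code{\link{sit_params}} object.
#' @param day Mating day recorded in the store (optional).
#' @return The updated \code{female_agent}.
#' @export
mate_event <- function(female, wild_count, sterile_count, params,
                       day = NA_real_) {
  stopifnot(inherits(female, "female_agent"), female$refractory == 0)
  total <- wild_count + params$eta * sterile_count
  if (total <= 0) return(female)
  if (stats::runif(1) >= 1 - exp(-params$chi)) return(female)
  sterile <- stats::runif(1) < params$eta * sterile_count / total
  origin <- if (sterile) "sterile" else "fertile"
  female$store$origins <- c(female$store$origins, origin)
  female$store$days <- c(female$store$days, day)
  female$refractory <- draw_refractory(1, if (sterile) params$tau_I
                                       else params$tau_F)
  female
}

# --- internal vectorized female pool -------------------------------------
# Parallel vectors: refr (days remaining, Inf allowed), nf/ns (counts of
# fertile/sterile records), first/last (origin codes, 0 = empty store).
empty_females <- function() {
  list(refr = numeric(0), nf = integer(0), ns = integer(0),
       first = integer(0), last = integer(0))
}

append_females <- function(fem, n, refr = 0, nf = 0L, first = 0L) {
  if (n == 0L) return(fem)
  list(refr = c(fem$refr, rep(refr, length.out = n)),
       nf = c(fem$nf, rep(as.integer(nf), n)),
       ns = c(fem$ns, rep(0L, n)),
       first = c(fem$first, rep(as.integer(first), n)),
       last = c(fem$last, rep(as.integer(first), n)))
}

subset_females <- function(fem, keep) lapply(fem, `[`, keep)

# Sequential-equivalent egg admission against the carrying capacity: eggs
# are thinned with probability (1 - L/K) recomputed over 16 chunks so the
# larval pool can never exceed K, approximating per-egg updating of L.
admit_eggs <- function(total, L, K) {
  total <- as.integer(total)
  if (total <= 0L || L >= K) return(0L)
  admitted <- 0L
  chunk <- max(1L, ceiling(total / 16))
  remaining <- total
  while (remaining > 0L) {
    size <- min(chunk, remaining)
    pk <- max(0, 1 - (L + admitted) / K)
    a <- stats::rbinom(1, size, pk)
    a <- min(a, as.integer(K) - as.integer(L) - admitted)
    admitted <- admitted + a
    remaining <- remaining - size
    if (L + admitted >= K) break
  }
  admitted
}

#' Advance the agent-based model by one day
#'
#' Executes, in order: (1) sterilized-male release per policy; (2)
#' sterilized-male survival (daily death probability 1 - exp(-mu_S)); (3)
#' wild-male survival; (4) larval survival then maturation (daily
#' probability 1 - exp(-nu)), matured larvae becoming wild males with
#' probability p or available females with empty stores; (5) the female
#' step: survival, refractory countdown, a mating opportunity for available
#' females, then oviposition — every female with a non-empty store lays a
#' Poisson(omega) clutch, each egg is viable only if the scenario's sperm
#' selection returns fertile, and viable eggs are admitted as larvae with
#' probability (1 - L/K); (6) count collection. All rate-to-probability
#' conversions use q = 1 - exp(-rate * 1 day) so sojourn times match the
#' ODE's exponential durations.
#'
#' @param state ABM state as returned by \code{\link{abm_init}} or a
#'   previous \code{daily_step} call.
#' @param params A \code{\link{sit_params}} object.
#' @param scenario A \code{\link{sperm_scenario}}.
#' @param release A \code{\link{release_policy}}.
#' @return A list with the updated \code{state}, the day's \code{counts}
#'   (named vector matching \code{\link{run_abm}} columns) and a
#'   \code{ledger} of flow tallies (births, deaths, releases).
#' @export
daily_step <- function(state, params, scenario, release) {
  day <- state$day + 1L
  L <- state$L; M <- state$M; S <- state$S; fem <- state$fem
  ledger <- c(released = 0, sterile_deaths = 0, male_deaths = 0,
              female_deaths = 0, larval_deaths = 0,
              emerged_males = 0, emerged_females = 0,
              eggs_laid = 0, eggs_viable = 0, eggs_admitted = 0)

  # (1) release
  if (release$batch > 0L && day >= release$start &&
      (day - release$start) %% release$period == 0L) {
    S <- S + release$batch
    ledger[["released"]] <- release$batch
  }
  # (2) sterilized-male survival
  S_new <- stats::rbinom(1, S, exp(-params$mu_S))
  ledger[["sterile_deaths"]] <- S - S_new; S <- S_new
  # (3) wild-male survival
  M_new <- stats::rbinom(1, M, exp(-params$mu_M))
  ledger[["male_deaths"]] <- M - M_new; M <- M_new
  # (4) larvae: survival then maturation
  L_surv <- stats::rbinom(1, L, exp(-params$mu_L))
  ledger[["larval_deaths"]] <- L - L_surv
  matured <- stats::rbinom(1, L_surv, 1 - exp(-params$nu))
  L <- L_surv - matured
  new_males <- stats::rbinom(1, matured, params$p)
  new_females <- matured - new_males
  M <- M + new_males
  fem <- append_females(fem, new_females)
  ledger[["emerged_males"]] <- new_males
  ledger[["emerged_females"]] <- new_females
  # (5) females
  n <- length(fem$refr)
  if (n > 0L) {
    keep <- stats::runif(n) < exp(-params$mu_F)
    ledger[["female_deaths"]] <- sum(!keep)
    fem <- subset_females(fem, keep)
    n <- length(fem$refr)
  }
  if (n > 0L) {
    fem$refr <- pmax(fem$refr - 1, 0)
    total <- M + params$eta * S
    if (total > 0) {
      avail <- fem$refr == 0
      mates <- avail & (stats::runif(n) < 1 - exp(-params$chi))
      nm <- sum(mates)
      if (nm > 0L) {
        idx <- which(mates)
        sterile <- stats::runif(nm) < params$eta * S / total
        origin <- ifelse(sterile, 2L, 1L)
        fem$nf[idx] <- fem$nf[idx] + as.integer(!sterile)
        fem$ns[idx] <- fem$ns[idx] + as.integer(sterile)
        newly <- fem$first[idx] == 0L
        fem$first[idx[newly]] <- origin[newly]
        fem$last[idx] <- origin
        refr_new <- numeric(nm)
        refr_new[sterile] <- draw_refractory(sum(sterile), params$tau_I)
        refr_new[!sterile] <- draw_refractory(sum(!sterile), params$tau_F)
        fem$refr[mates] <- refr_new
      }
    }
    layers <- fem$nf + fem$ns > 0L
    nl <- sum(layers)
    if (nl > 0L) {
      eggs <- stats::rpois(nl, params$omega)
      pf <- fertile_use_prob(scenario, fem$nf[layers], fem$ns[layers],
                             fem$first[layers], fem$last[layers])
      viable <- stats::rbinom(nl, eggs, pf)
      admitted <- admit_eggs(sum(viable), L, params$K)
      L <- L + admitted
      ledger[["eggs_laid"]] <- sum(eggs)
      ledger[["eggs_viable"]] <- sum(viable)
      ledger[["eggs_admitted"]] <- admitted
    }
  }
  state <- list(day = day, L = L, M = M, S = S, fem = fem)
  list(state = state, counts = abm_counts(state), ledger = ledger)
}

abm_counts <- function(state) {
  fem <- state$fem
  refr <- fem$refr > 0
  c(day = state$day, larvae = state$L, wild_males = state$M,
    sterile_males = state$S,
    females_available = sum(!refr),
    females_fertile_refractory = sum(refr & fem$last == 1L),
    females_infertile_refractory = sum(refr & fem$last == 2L))
}

#' Configuration for an agent-based simulation
#'
#' @param params A \code{\link{sit_params}} object.
#' @param scenario A \code{\link{sperm_scenario}}.
#' @param release A \code{\link{release_policy}}.
#' @param wild_males,females,larvae,sterile_males Initial integer counts
#'   (default: the low-infestation tunnel setting of 1000 wild males, 1000
#'   females, no larvae, no sterilized males).
#' @param horizon Days to simulate (>= 0).
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical output.
#' @param females_mated If TRUE, initial females carry one fertile mating
#'   record (a fertilized-female start, used for high-infestation settings)
#'   and begin with a refractory countdown drawn at rate tau_F; if FALSE
#'   (default) they start available with empty stores.
#' @return An object of class \code{abm_config}.
#' @export
abm_config <- function(params = suzukii_params(),
                       scenario = sperm_scenario("last"),
                       release = release_policy(0),
                       wild_males = 1000, females = 1000,
                       larvae = 0, sterile_males = 0,
                       horizon = 100, seed = 1, females_mated = FALSE) {
  counts <- c(wild_males, females, larvae, sterile_males)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("initial counts must be non-negative integers", call. = FALSE)
  if (horizon < 0) stop("'horizon' must be >= 0", call. = FALSE)
  structure(list(params = params, scenario = scenario, release = release,
                 wild_males = as.integer(wild_males),
                 females = as.integer(females),
                 larvae = as.integer(larvae),
                 sterile_males = as.integer(sterile_males),
                 horizon = as.integer(horizon), seed = as.integer(seed),
                 females_mated = isTRUE(females_mated)),
            class = "abm_config")
}

#' Initial ABM state from a configuration
#'
#' @param config An \code{\link{abm_config}}. Uses the current RNG stream
#'   (for the initial refractory draws of pre-mated females).
#' @return An ABM state list (day 0).
#' @export
abm_init <- function(config) {
  fem <- empty_females()
  if (config$females > 0L) {
    if (config$females_mated) {
      fem <- append_females(fem, config$females, refr = 0, nf = 1L,
                            first = 1L)
      fem$refr <- draw_refractory(config$females, config$params$tau_F)
    } else {
      fem <- append_females(fem, config$females)
    }
  }
  list(day = 0L, L = config$larvae, M = config$wild_males,
       S = config$sterile_males, fem = fem)
}

#' Run the agent-based SIT simulation
#'
#' Daily-step, well-mixed stochastic simulation of the pest population
#' under sterilized-male releases with explicit polyandrous females. Wild
#' and sterilized males carry no individual state beyond survival and are
#' held as counts with binomial daily survival; larvae likewise (all larval
#' hazards are age-independent); females are individual records because
#' their sperm stores and refractory states drive the dynamics.
#'
#' @param config An \code{\link{abm_config}}.
#' @param detail If TRUE, append the per-day flow ledger columns (releases,
#'   deaths, emergences, egg tallies) to the output.
#' @return An \code{abm_series} data.frame with one row per day (day 0 is
#'   the initial configuration) and columns \code{day}, \code{larvae},
#'   \code{wild_males}, \code{sterile_males}, \code{females_available},
#'   \code{females_fertile_refractory}, \code{females_infertile_refractory};
#'   the configuration is attached as an attribute.
#' @export
run_abm <- function(config, detail = FALSE) {
  stopifnot(inherits(config, "abm_config"))
  set.seed(config$seed)
  state <- abm_init(config)
  nrows <- config$horizon + 1L
  counts <- matrix(NA_real_, nrows, 7,
                   dimnames = list(NULL, names(abm_counts(state))))
  counts[1, ] <- abm_counts(state)
  ledgers <- NULL
  for (d in seq_len(config$horizon)) {
    step <- daily_step(state, config$params, config$scenario, config$release)
    state <- step$state
    counts[d + 1L, ] <- step$counts
    if (detail) {
      if (is.null(ledgers))
        ledgers <- matrix(0, nrows, length(step$ledger),
                          dimnames = list(NULL, names(step$ledger)))
      ledgers[d + 1L, ] <- step$ledger
    }
  }
  out <- as.data.frame(counts)
  if (detail && !is.null(ledgers)) out <- cbind(out, as.data.frame(ledgers))
  structure(out, class = c("abm_series", "data.frame"), config = config)
}
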