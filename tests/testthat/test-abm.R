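test_that("sperm selection follows each scenario's rule on ordered stores", {
  st_sf <- sperm_store(c("sterile", "fertile"))
  st_fs <- sperm_store(c("fertile", "sterile"))
  expect_equal(sperm_selection(sperm_scenario("preference_w"), st_sf),
               "fertile")
  expect_equal(sperm_selection(sperm_scenario("preference_s"), st_fs),
               "sterile")
  expect_equal(sperm_selection(sperm_scenario("first"), st_sf), "sterile")
  expect_equal(sperm_selection(sperm_scenario("first"), st_fs), "fertile")
  expect_equal(sperm_selection(sperm_scenario("last"), st_fs), "sterile")
  expect_equal(sperm_selection(sperm_scenario("last"), st_sf), "fertile")
  expect_error(sperm_selection(sperm_scenario("last"), sperm_store()),
               "non-empty")
})

test_that("mixed sperm use is proportional to the stored composition", {
  set.seed(5)
  st <- sperm_store(c("sterile", "sterile", "sterile", "fertile"))
  sc <- sperm_scenario("mixed")
  draws <- replicate(2e4, sperm_selection(sc, st))
  expect_equal(mean(draws == "fertile"), 0.25, tolerance = 0.012)
  # intermediate preference uses the weight only when both kinds are stored
  set.seed(6)
  sci <- sperm_scenario("preference_i", preference = 0.8)
  draws2 <- replicate(2e4, sperm_selection(sci, st))
  expect_equal(mean(draws2 == "fertile"), 0.8, tolerance = 0.012)
  only_st <- sperm_store(c("sterile", "sterile"))
  expect_equal(sperm_selection(sci, only_st), "sterile")
})

test_that("mate outcomes follow the competitiveness-weighted male fractions", {
  pr <- suzukii_params()
  set.seed(7)
  f <- mate_event(female_agent(), wild_count = 0, sterile_count = 500, pr)
  expect_equal(f$store$origins, "sterile")
  expect_gt(f$refractory, -1)
  f2 <- mate_event(female_agent(), wild_count = 1e5, sterile_count = 0, pr)
  expect_equal(f2$store$origins, "fertile")
  # eta = 0.6, equal counts: sterile share 0.6/1.6 = 0.375
  set.seed(8)
  hits <- vapply(1:3e4, function(i) {
    identical(mate_event(female_agent(), 1000, 1000, pr)$store$origins,
              "sterile")
  }, logical(1))
  expect_equal(mean(hits), 0.375, tolerance = 0.012)
  # with no effective mates (eta = 0, no wild males) nothing happens
  f3 <- mate_event(female_agent(), 0, 1000, update_params(pr, eta = 0))
  expect_length(f3$store$origins, 0)
})

test_that("a population without females never produces larvae", {
  cfg <- abm_config(females = 0, wild_males = 500, larvae = 0,
                    release = release_policy(1000), horizon = 30, seed = 3)
  out <- run_abm(cfg)
  expect_true(all(out$larvae == 0))
})

test_that("complete sterile-sperm preference blocks all post-release output", {
  # sterile-only stores lay nothing under preference_s
  set.seed(9)
  state <- abm_init(abm_config(females = 200, wild_males = 0, larvae = 0,
                               sterile_males = 5000, horizon = 1))
  state$fem$ns[] <- 1L; state$fem$first[] <- 2L; state$fem$last[] <- 2L
  step <- daily_step(state, suzukii_params(), sperm_scenario("preference_s"),
                     release_policy(0))
  expect_equal(step$counts[["larvae"]], 0)
  expect_gt(step$ledger[["eggs_laid"]], 0)
  expect_equal(step$ledger[["eggs_viable"]], 0)
})

test_that("identical configurations and seeds give bit-identical series", {
  cfg <- abm_config(scenario = sperm_scenario("mixed"),
                    release = release_policy(5000), horizon = 40, seed = 123)
  a <- run_abm(cfg)
  b <- run_abm(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a zero-day horizon returns only the initial configuration", {
  cfg <- abm_config(horizon = 0, seed = 1, larvae = 7, sterile_males = 2)
  out <- run_abm(cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$larvae, 7)
  expect_equal(out$sterile_males, 2)
  expect_equal(out$females_available, 1000)
})

test_that("an uncontrolled population grows into the thousands but never past K", {
  cfg <- abm_config(horizon = 100, seed = 21)
  out <- run_abm(cfg)
  expect_gt(max(out$larvae), 10000)
  expect_lte(max(out$larvae), 36000)
})

test_that("the daily ledger balances every adult pool exactly", {
  cfg <- abm_config(release = release_policy(3000, period = 3),
                    horizon = 50, seed = 31, larvae = 500)
  out <- run_abm(cfg, detail = TRUE)
  n <- nrow(out)
  expect_equal(out$wild_males[-1],
               out$wild_males[-n] - out$male_deaths[-1] +
                 out$emerged_males[-1])
  expect_equal(out$sterile_males[-1],
               out$sterile_males[-n] + out$released[-1] -
                 out$sterile_deaths[-1])
  fem_tot <- out$females_available + out$females_fertile_refractory +
    out$females_infertile_refractory
  expect_equal(fem_tot[-1],
               fem_tot[-n] - out$female_deaths[-1] +
                 out$emerged_females[-1])
  expect_equal(out$larvae[-1],
               out$larvae[-n] - out$larval_deaths[-1] -
                 (out$emerged_males[-1] + out$emerged_females[-1]) +
                 out$eggs_admitted[-1])
})

test_that("replicate-mean larvae track the reduced ODE without releases", {
  # pre-mated females, standing larvae, no releases: the ABM's First
  # scenario is dynamically equivalent to the reduced model at sigma = 0
  pr <- suzukii_params()
  n_rep <- 30
  cfg <- abm_config(scenario = sperm_scenario("first"),
                    wild_males = 10000, females = 10000, larvae = 3000,
                    horizon = 100, females_mated = TRUE)
  seeds <- replicate_seeds(515, n_rep)
  acc <- 0
  for (r in seq_len(n_rep)) {
    cfg$seed <- seeds[r]
    acc <- acc + run_abm(cfg)$larvae
  }
  abm_mean <- acc / n_rep
  ode <- simulate_sit("reduced", c(L = 3000, M = 10000, F_I = 0,
                                   F_F = 10000, S = 0), pr, 0, horizon = 100)
  rel_err <- abs(abm_mean - ode$L) / pmax(ode$L, 1)
  expect_lt(max(rel_err), 0.15)
})

test_that("scenario suppression ranks sterile-preference above last above wild-preference", {
  cfg <- abm_config(horizon = 100)
  sw <- replicate_sweep(list("preference_s", "last", "preference_w"),
                        10000, cfg, n_replicates = 8, master_seed = 77)
  m <- setNames(sw$mean_reduction, sw$scenario)
  expect_gt(m[["preference_s"]], m[["last"]])
  expect_gt(m[["last"]], m[["preference_w"]])
  expect_gt(m[["preference_s"]], 90)
})

test_that("ABM output and sidecar round-trip through the writer", {
  cfg <- abm_config(horizon = 5, seed = 4, release = release_policy(100))
  out <- run_abm(cfg)
  path <- tempfile(fileext = ".csv")
  write_abm_series(out, path)
  got <- utils::read.csv(path)
  expect_identical(names(got)[1:4],
                   c("day", "larvae", "wild_males", "sterile_males"))
  meta <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(meta$seed, 4)
  expect_equal(meta$release$sigma, 100)
})
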