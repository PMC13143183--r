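test_that("zeta vanishes at its parabola roots and peaks at the threshold", {
  pr <- suzukii_params()
  R0 <- basic_reproduction_number(pr)
  expect_equal(zeta(0, pr), 0)
  expect_lt(abs(zeta(pr$K * (1 - 1 / R0), pr)), 1e-6)
  vertex <- pr$K / 2 * (1 - 1 / R0)
  expect_equal(zeta(vertex, pr), eradication_threshold(pr),
               tolerance = 1e-12)
  expect_error(zeta(100, update_params(pr, eta = 0)), "eta")
})

test_that("the zeta summit equals the closed-form threshold on random parameter sets", {
  set.seed(202)
  for (i in 1:100) {
    pr <- random_params()
    R0 <- basic_reproduction_number(pr)
    vertex <- pr$K / 2 * (1 - 1 / R0)
    expect_equal(zeta(vertex, pr), eradication_threshold(pr),
                 tolerance = 1e-12)
  }
})

test_that("eradication thresholds reproduce the calibrated First/Last values", {
  first <- eradication_threshold(first_params())
  last <- eradication_threshold(suzukii_params())
  expect_equal(round(first / 1e4) * 1e4, 420000)
  expect_equal(round(last / 1e4) * 1e4, 480000)
  expect_gt(last, first)
})

test_that("equal refractory rates leave the threshold at its no-re-mating value", {
  base <- eradication_threshold(first_params())
  for (cc in c(0.05, 0.12, 0.3))
    expect_equal(eradication_threshold(
      update_params(suzukii_params(), tau_F = cc, tau_I = cc)), base,
      tolerance = 1e-12)
})

test_that("threshold ordering follows the refractory-rate asymmetry", {
  pr <- suzukii_params()
  eq <- eradication_threshold(update_params(pr, tau_F = 0.1, tau_I = 0.1))
  up <- eradication_threshold(update_params(pr, tau_F = 0.1, tau_I = 0.2))
  dn <- eradication_threshold(update_params(pr, tau_F = 0.2, tau_I = 0.1))
  expect_gt(up, eq)
  expect_lt(dn, eq)
})

test_that("the threshold is linear in K and in mu_S and zero when R0 <= 1", {
  pr <- suzukii_params()
  s0 <- eradication_threshold(pr)
  expect_equal(eradication_threshold(update_params(pr, K = 2 * pr$K)),
               2 * s0, tolerance = 1e-12)
  expect_equal(eradication_threshold(update_params(pr, mu_S = 3 * pr$mu_S)),
               3 * s0, tolerance = 1e-12)
  expect_equal(eradication_threshold(update_params(pr, omega = 0.01)), 0)
})

test_that("equilibrium counts and labels match the bistability structure", {
  pr <- suzukii_params()
  # above the threshold: pest-free only
  eqs <- find_equilibria(pr, 6e5, classify = FALSE)
  expect_length(eqs, 1)
  expect_equal(eqs[[1]]$kind, "pest-free")
  expect_equal(eqs[[1]]$state[["S"]], 6e5 / pr$mu_S)
  # no releases: one infestation root at K(1 - 1/R0)
  eqs0 <- find_equilibria(pr, 0, classify = FALSE)
  R0 <- basic_reproduction_number(pr)
  linf <- vapply(eqs0, function(e) e$L_star, numeric(1))
  expect_equal(max(linf), pr$K * (1 - 1 / R0), tolerance = 1e-9)
  # below the threshold: two infestation roots straddling the vertex
  eqs45 <- find_equilibria(pr, 450000, classify = FALSE)
  expect_length(eqs45, 3)
  kinds <- vapply(eqs45, function(e) e$kind, character(1))
  expect_setequal(kinds, c("pest-free", "infestation-low",
                           "infestation-high"))
  vertex <- pr$K / 2 * (1 - 1 / R0)
  lo <- eqs45[[which(kinds == "infestation-low")]]$L_star
  hi <- eqs45[[which(kinds == "infestation-high")]]$L_star
  expect_lt(lo, vertex); expect_gt(hi, vertex)
})

test_that("stability classification matches the summary-box structure", {
  pr <- suzukii_params()
  eqs <- find_equilibria(pr, 450000)
  lab <- vapply(eqs, function(e) e$stability, character(1))
  kinds <- vapply(eqs, function(e) e$kind, character(1))
  expect_equal(lab[kinds == "pest-free"], "stable")
  expect_equal(lab[kinds == "infestation-low"], "unstable")
  expect_equal(lab[kinds == "infestation-high"], "stable")
})

test_that("at the exact threshold a single marginal infestation equilibrium remains", {
  pr <- suzukii_params()
  eqs <- find_equilibria(pr, eradication_threshold(pr), classify = FALSE)
  kinds <- vapply(eqs, function(e) e$kind, character(1))
  expect_equal(sort(kinds), c("marginal", "pest-free"))
})

test_that("trajectories respect the basin boundary set by E1*", {
  pr <- suzukii_params()
  sigma <- 450000
  eqs <- find_equilibria(pr, sigma, classify = FALSE)
  kinds <- vapply(eqs, function(e) e$kind, character(1))
  e1 <- eqs[[which(kinds == "infestation-low")]]
  e2 <- eqs[[which(kinds == "infestation-high")]]
  # small perturbation of E2* returns to E2*
  tr <- simulate_sit("reduced", e2$state * 1.05, pr, sigma, horizon = 4000)
  expect_equal(tail(tr$L, 1), e2$L_star, tolerance = 1e-3)
  # scaled below E1* the pest collapses; scaled above it rises toward E2*
  dn <- simulate_sit("reduced", e1$state * 0.8, pr, sigma, horizon = 8000)
  expect_lt(tail(dn$L, 1), 1)
  up <- simulate_sit("reduced", e1$state * 1.2, pr, sigma, horizon = 8000)
  expect_equal(tail(up$L, 1), e2$L_star, tolerance = 1e-3)
})

test_that("the bifurcation branch count collapses from three to one at the threshold", {
  prf <- first_params()
  sb <- eradication_threshold(prf)
  tab <- bifurcation_diagram(prf, c(1000, sb - 2000, sb + 2000, 6e5))
  counts <- table(tab$sigma)
  expect_equal(unname(counts[as.character(c(1000, sb - 2000))]), c(3L, 3L),
               ignore_attr = TRUE)
  expect_equal(unname(counts[as.character(c(sb + 2000, 6e5))]), c(1L, 1L),
               ignore_attr = TRUE)
  # R0 <= 1: a single pest-free branch everywhere
  tame <- update_params(suzukii_params(), omega = 0.01)
  tab2 <- bifurcation_diagram(tame, c(0, 1e5, 6e5))
  expect_true(all(tab2$kind == "pest-free"))
})

test_that("threshold heatmaps are constant on the diagonal, capped, and monotone", {
  pr <- suzukii_params()
  g <- seq(0, 0.5, length.out = 21)
  hm <- threshold_heatmap(pr, list(name = "tau_F", grid = g),
                          list(name = "tau_I", grid = g), cap = 1e6)
  diagv <- unname(diag(unclass(hm)))
  expect_equal(diagv, rep(diagv[1], length(diagv)), tolerance = 1e-12)
  raw <- attr(hm, "raw")
  expect_true(any(raw > 1e6))
  expect_equal(max(hm), 1e6)
  hm2 <- threshold_heatmap(pr,
                           list(name = "eta", grid = seq(0.2, 1, length.out = 15)),
                           list(name = "tau_I", grid = seq(0, 0.4, length.out = 15)),
                           cap = Inf)
  m2 <- attr(hm2, "raw")
  expect_true(all(diff(t(m2)) > 0))   # increasing in tau_I (columns)
  expect_true(all(apply(m2, 2, diff) < 0))  # decreasing in eta (rows)
  expect_error(threshold_heatmap(pr, list(name = "omega", grid = 1:2),
                                 list(name = "tau_I", grid = 1:2)),
               "axis")
})

test_that("the transient comparison shows the early-Last/late-First sign structure", {
  pr <- suzukii_params()
  tc <- transient_comparison(pr, c(0, 300000, 450000), horizon = 3000)
  # no releases: the scenarios coincide
  expect_true(all(abs(tc[1, ]) < 1e-8, na.rm = TRUE))
  # moderate sigma, early times: Last reduces faster (positive values)
  expect_gt(mean(tc[2, 30:200]), 0)
  expect_gt(mean(tc[3, 30:200]), 0)
  # intermediate band (between the two thresholds), late times: First wins
  expect_lt(tc[3, 3001], 0)
})
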