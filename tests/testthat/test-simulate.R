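test_that("the simplex matrix obeys the product rule exactly", {
  R <- simplex_corr(c(0.6, 0.5, 0.7))
  expect_equal(R[1, 3], 0.6 * 0.5)
  expect_equal(R[1, 4], 0.6 * 0.5 * 0.7)
  # simplex closure: corr(i,k) = corr(i,j) * corr(j,k) for i < j < k
  for (i in 1:2) for (j in (i + 1):3) for (k in (j + 1):4)
    expect_equal(R[i, k], R[i, j] * R[j, k])
  expect_true(isSymmetric(R))
  expect_error(simplex_corr(c(0.5, 1)), "lag-1")
})

test_that("latent draws match the configured correlation structure", {
  cfg <- synthetic_config(20000, c("a", "b", "c"), lag1 = c(0.6, 0.5),
                          seed = 301)
  lat <- generate_latent(cfg)
  emp <- cor(lat)
  expect_equal(emp[1, 2], 0.6, tolerance = 0.02)
  expect_equal(emp[1, 3], 0.30, tolerance = 0.02)
  # independence when all lag-1 vanish
  cfg0 <- synthetic_config(10000, c("a", "b"), lag1 = 0, seed = 302)
  expect_lt(abs(cor(generate_latent(cfg0))[1, 2]), 3 / sqrt(10000))
  # same seed, same matrix
  expect_identical(generate_latent(cfg), generate_latent(cfg))
  expect_error(synthetic_config(100, c("a", "b"), corr =
                                  matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("selection truncates as the truncated-normal formulas predict", {
  cfg <- synthetic_config(
    50000, c("a", "b"), lag1 = 0.6, seed = 303,
    selection = list(stage = "a", fraction = 0.4, type = "truncation"))
  lat <- generate_latent(cfg)
  sel <- apply_selection(lat, cfg)
  ent <- sel$entrants
  expect_equal(nrow(ent), 20000)
  # E[X | X > qnorm(0.6)] = dnorm(qnorm(0.6)) / 0.4
  expect_equal(mean(ent[, "a"]), dnorm(qnorm(0.6)) / 0.4, tolerance = 0.02)
  expect_lt(sd(ent[, "a"]), 1)
  # fraction 1 is the identity
  cfg1 <- cfg; cfg1$selection$fraction <- 1
  expect_equal(nrow(apply_selection(lat, cfg1)$entrants), nrow(lat))
  expect_error(synthetic_config(100, c("a", "b"), lag1 = 0.5,
                                selection = list(stage = "a", fraction = 0)),
               "fraction")
})

test_that("restriction of range attenuates entrant correlations", {
  deltas <- vapply(1:10, function(i) {
    cfg <- synthetic_config(
      4000, c("a", "b"), lag1 = 0.6, seed = 310 + i,
      selection = list(stage = "a", fraction = 0.3, type = "truncation"))
    lat <- generate_latent(cfg)
    ent <- apply_selection(lat, cfg)$entrants
    cor(lat[, 1], lat[, 2]) - cor(ent[, 1], ent[, 2])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("observation modes reproduce their target masses", {
  set.seed(320)
  z <- rnorm(1e5)
  cc <- observe_stage(z, list(mode = "ceiling", ceiling_q = 0.375), "al")
  expect_equal(mean(cc$observed == cc$spec$ceiling), 0.625, tolerance = 0.005)
  expect_equal(cc$spec$kind, "censored_continuous")
  props <- c(0.117, 0.533, 0.283, 0.067)
  oo <- observe_stage(z, list(mode = "ordinal", proportions = props), "bms")
  expect_equal(as.numeric(table(oo$observed) / 1e5), props, tolerance = 0.005)
  bb <- observe_stage(z, list(mode = "binary", prevalence = 0.554), "reg")
  expect_equal(mean(bb$observed), 0.554, tolerance = 0.005)
  # zero-noise continuous observation is the identity
  ident <- observe_stage(z[1:100], list(mode = "continuous"), "x")
  expect_identical(ident$observed, z[1:100])
  # reliability < 1 keeps unit variance but mixes in noise
  noisy <- observe_stage(z, list(mode = "continuous", reliability = 0.8), "x")
  expect_equal(sd(noisy$observed), 1, tolerance = 0.02)
  expect_equal(cor(noisy$observed, z), sqrt(0.8), tolerance = 0.01)
  expect_error(observe_stage(z, list(mode = "ordinal",
                                     proportions = c(0.5, 0.4)), "x"),
               "sum to 1")
})

test_that("exam uptake depends on prior performance as configured", {
  cfg <- synthetic_config(
    20000, c("a", "b"), lag1 = 0.6, seed = 330,
    uptake = list(list(stage = "b", on = "a", slope = 1.5, rate = 0.346)))
  sim <- generate_cohort(cfg)
  tab <- sim$table
  expect_equal(mean(tab$attempted_b), 0.346, tolerance = 0.01)
  expect_true(all(is.na(tab$b[!tab$attempted_b])))
  # attempters outperform non-attempters on the prior stage
  expect_gt(mean(tab$a[tab$attempted_b]), mean(tab$a[!tab$attempted_b]))
  # slope 0: uptake independent of performance
  cfg0 <- synthetic_config(
    20000, c("a", "b"), lag1 = 0.6, seed = 331,
    uptake = list(list(stage = "b", on = "a", slope = 0, rate = 0.5)))
  tab0 <- generate_cohort(cfg0)$table
  expect_equal(mean(tab0$attempted_b), 0.5, tolerance = 0.015)
  expect_lt(abs(mean(tab0$a[tab0$attempted_b]) -
                  mean(tab0$a[!tab0$attempted_b])), 0.05)
})

test_that("the full generator is deterministic and keeps its truth record", {
  cfg <- cohort_preset("uclms", seed = 340)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  expect_equal(s1$truth$n_entrants, 729)
  expect_equal(names(s1$specs), cfg$stages)
  expect_equal(s1$specs$alevel$kind, "censored_continuous")
  # truth suffices to recover population parameters
  expect_equal(s1$truth$corr, simplex_corr(c(0.7, 0.55, 0.65, 0.7)))
  expect_true(is.finite(s1$truth$uptake$mrcp1$intercept))
  # degenerate one-stage config still yields a table
  lone <- generate_cohort(synthetic_config(50, "only", lag1 = numeric(0),
                                           corr = matrix(1, 1, 1), seed = 3))
  expect_equal(ncol(lone$table), 1L)
})

test_that("generated censored pairs are recovered by the latent estimator", {
  cfg <- synthetic_config(
    1200, c("a", "b"), lag1 = 0.6, seed = 350,
    observe = list(a = list(mode = "ceiling", ceiling_q = 0.4)))
  sim <- generate_cohort(cfg)
  fit <- latent_cor(sim$table$a, sim$table$b,
                    list(sim$specs$a, sim$specs$b), quick_mcmc(351))
  expect_lt(abs(fit$estimate - 0.6), 0.1)
  naive <- cor(sim$table$a, sim$table$b)
  expect_gt(fit$estimate, naive)
})
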