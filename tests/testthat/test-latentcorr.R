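test_that("variable specs enforce their measurement invariants", {
  expect_error(var_spec("x", "censored_continuous"), "ceiling")
  expect_error(var_spec("x", "ordinal", n_categories = 2), ">= 3")
  expect_equal(var_spec("x", "binary")$n_categories, 2L)
  expect_error(mcmc_config(chain_length = 1000, estimate_window = 1000),
               "smaller")
})

test_that("observations map to the correct points and latent intervals", {
  sp_c <- var_spec("x", "continuous")
  expect_equal(to_interval(27.1, sp_c),
               data.frame(lo = 27.1, hi = 27.1, point = TRUE))
  sp_cc <- var_spec("a", "censored_continuous", ceiling = 30)
  iv <- to_interval(c(28, 30), sp_cc)
  expect_equal(iv$lo, c(28, 30))
  expect_equal(iv$hi, c(28, Inf))
  expect_equal(iv$point, c(TRUE, FALSE))
  expect_error(to_interval(31, sp_cc), "ceiling")
  sp_b <- var_spec("b", "binary")
  ivb <- to_interval(c(0, 1), sp_b, tau = 0.3)
  expect_equal(ivb$lo, c(-Inf, 0.3))
  expect_equal(ivb$hi, c(0.3, Inf))
  sp_o <- var_spec("o", "ordinal", n_categories = 4)
  tau <- c(-1, 0, 1.5)
  ivo <- to_interval(1:4, sp_o, tau = tau)
  # cells tile the real line
  expect_equal(ivo$lo, c(-Inf, tau))
  expect_equal(ivo$hi, c(tau, Inf))
  expect_error(to_interval(5, sp_o, tau = tau), "out of range")
  expect_error(to_interval(2, sp_o, tau = c(0, -1, 1)), "increasing")
})

test_that("pair log-likelihood factorizes at rho = 0 and normalizes over cells", {
  set.seed(31)
  x <- rnorm(40, 2, 1.5); y <- rnorm(40, -1, 0.7)
  specs <- list(var_spec("x", "continuous"), var_spec("y", "continuous"))
  par0 <- list(mu = c(2, -1), sigma = c(1.5, 0.7), rho = 0,
               tau = list(NULL, NULL))
  ll <- pair_loglik(x, y, specs, par0)
  expect_equal(ll, sum(dnorm(x, 2, 1.5, log = TRUE)) +
                 sum(dnorm(y, -1, 0.7, log = TRUE)), tolerance = 1e-10)
  # cell probabilities of a 2x2 table normalize: summing exp(loglik) of one
  # pair over all four cells gives 1
  bspecs <- list(var_spec("x", "binary"), var_spec("y", "binary"))
  parb <- list(mu = c(0, 0), sigma = c(1, 1), rho = 0.4,
               tau = list(0.2, -0.5))
  tot <- sum(vapply(0:1, function(i) sum(vapply(0:1, function(j)
    exp(pair_loglik(i, j, bspecs, parb)), numeric(1))), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("censored-pair likelihood matches a numerical-integration oracle", {
  set.seed(32)
  n <- 20
  mu <- c(1, 0.5); sig <- c(2, 1); rho <- 0.55
  z <- make_bvn(n, rho, seed = 33)
  x <- mu[1] + sig[1] * z[, 1]; y <- mu[2] + sig[2] * z[, 2]
  cx <- quantile(x, 0.6); x <- pmin(x, cx)
  specs <- list(var_spec("x", "censored_continuous", ceiling = unname(cx)),
                var_spec("y", "continuous"))
  par <- list(mu = mu, sigma = sig, rho = rho, tau = list(NULL, NULL))
  joint <- function(u, v) {
    zu <- (u - mu[1]) / sig[1]; zv <- (v - mu[2]) / sig[2]
    om <- 1 - rho^2
    exp(-(zu^2 - 2 * rho * zu * zv + zv^2) / (2 * om)) /
      (2 * pi * sqrt(om) * sig[1] * sig[2])
  }
  oracle <- sum(vapply(seq_len(n), function(i) {
    if (x[i] < cx) log(joint(x[i], y[i])) else
      log(integrate(function(u) joint(u, y[i]), cx, Inf,
                    rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_equal(pair_loglik(x, y, specs, par), oracle, tolerance = 1e-6)
  # degenerate parameters give -Inf, not an exception
  bad <- par; bad$sigma <- c(1e-12, 1)
  expect_true(is.infinite(pair_loglik(x, y, specs, bad)))
})

test_that("the adaptive chain samples a known target and is reproducible", {
  m <- c(1, -2); s <- c(0.5, 2)
  logpost <- function(th) -0.5 * sum(((th - m) / s)^2)
  cfg <- mcmc_config(chain_length = 4000, estimate_window = 2000, seed = 17)
  ch <- run_chain(logpost, c(0, 0), cfg)
  win <- ch[2001:4000, ]
  expect_equal(colMeans(win), m, tolerance = 0.2)
  expect_equal(apply(win, 2, sd), s, tolerance = 0.35)
  ch2 <- run_chain(logpost, c(0, 0), cfg)
  expect_identical(unclass(ch)[, ], unclass(ch2)[, ])
  expect_error(run_chain(function(th) -Inf, c(0, 0), cfg), "re-initialize")
})

test_that("chain summaries use the final window with percentile intervals", {
  cfg <- mcmc_config(chain_length = 5000, estimate_window = 2000, seed = 1)
  const <- rep(0.42, 5000)
  s <- summarize_chain(const, cfg)
  expect_equal(s$estimate, 0.42)
  expect_equal(s$se, 0)
  expect_equal(unname(s$ci), c(0.42, 0.42))
  set.seed(51)
  draws <- c(rnorm(3000, 5, 1), rnorm(2000, 0.5, 0.03))
  s2 <- summarize_chain(draws, cfg)
  expect_equal(s2$estimate, 0.5, tolerance = 0.01)
  expect_equal(s2$se, 0.03, tolerance = 0.05)
  expect_equal(unname(s2$ci), qnorm(c(0.025, 0.975), 0.5, 0.03),
               tolerance = 0.01)
  expect_error(summarize_chain(rnorm(100), cfg), "window")
  # report cell style
  est <- list(estimate = 0.561, se = 0.032, ci = c(0.501, 0.621))
  expect_equal(format_estimate(est), "0.561 ± 0.032 (0.501 to 0.621)")
})

test_that("stability diagnostic passes i.i.d. draws and flags drift", {
  cfg <- mcmc_config(chain_length = 4000, estimate_window = 2000, seed = 1)
  set.seed(61)
  fails <- 0
  for (i in 1:20)
    fails <- fails + !stability_check(rnorm(4000), cfg)$pass
  expect_lte(fails, 2)
  drift <- seq(0, 1, length.out = 4000)
  expect_false(stability_check(drift, cfg)$pass)
  const <- stability_check(rep(1, 4000), cfg)
  expect_equal(const$z, 0)
  expect_true(const$pass)
})

test_that("uncensored continuous fits agree with the Pearson correlation", {
  z <- make_bvn(2000, 0.5, seed = 71)
  specs <- list(var_spec("x", "continuous"), var_spec("y", "continuous"))
  fit <- latent_cor(z[, 1], z[, 2], specs, mcmc_config(seed = 72))
  r <- cor(z[, 1], z[, 2])
  expect_lt(abs(fit$estimate - r), 0.05)
  expect_true(fit$ci[1] <= fit$estimate && fit$estimate <= fit$ci[2])
  expect_gt(fit$se, 0)
  expect_equal(fit$n_pairs, 2000L)
})

test_that("fits are symmetric in the two margins up to Monte-Carlo error", {
  z <- make_bvn(800, 0.6, seed = 81)
  cp <- quantile(z[, 1], 0.5)
  x <- pmin(z[, 1], cp)
  sx <- var_spec("x", "censored_continuous", ceiling = unname(cp))
  sy <- var_spec("y", "continuous")
  f1 <- latent_cor(x, z[, 2], list(sx, sy), quick_mcmc(82))
  f2 <- latent_cor(z[, 2], x, list(sy, sx), quick_mcmc(83))
  expect_lt(abs(f1$estimate - f2$estimate), 3 * sqrt(f1$se^2 + f2$se^2) + 0.02)
})

test_that("pairwise deletion counts pairs and degenerate inputs error", {
  z <- make_bvn(200, 0.4, seed = 91)
  x <- z[, 1]; y <- z[, 2]
  x[1:50] <- NA; y[41:60] <- NA
  specs <- list(var_spec("x", "continuous"), var_spec("y", "continuous"))
  fit <- latent_cor(x, y, specs, quick_mcmc(92))
  expect_equal(fit$n_pairs, sum(!is.na(x) & !is.na(y)))
  expect_error(latent_cor(rep(NA_real_, length(y)), y, specs), "missing")
  expect_error(latent_cor(z[1:12, 1], rep(1, 12),
                          list(specs[[1]], var_spec("y", "binary"))),
               "single observed value")
  expect_error(latent_cor(z[1:5, 1], z[1:5, 2], specs), "at least 10")
})

test_that("one-step and two-step threshold handling agree for binary data", {
  z <- make_bvn(1500, 0.6, seed = 101)
  xb <- as.integer(z[, 1] > 0.3)
  yb <- as.integer(z[, 2] > -0.2)
  specs <- list(var_spec("x", "binary"), var_spec("y", "binary"))
  f1 <- latent_cor(xb, yb, specs, quick_mcmc(102))
  f2 <- latent_cor(xb, yb, specs, quick_mcmc(103), fixed_thresholds = TRUE)
  expect_lt(abs(f1$estimate - f2$estimate), 0.05)
  expect_equal(f1$method, "tetrachoric")
  # two-step mode holds thresholds at the marginal quantiles
  expect_equal(f2$nuisance$tau[[1]], qnorm(mean(xb == 0)), tolerance = 1e-9)
})

test_that("dichotomization attenuates Pearson r but not the latent estimate", {
  diffs <- numeric(12)
  for (i in seq_along(diffs)) {
    z <- make_bvn(400, 0.5, seed = 110 + i)
    xb <- as.integer(z[, 1] > 0); yb <- as.integer(z[, 2] > 0)
    naive <- cor(xb, yb)
    fit <- latent_cor(xb, yb,
                      list(var_spec("x", "binary"), var_spec("y", "binary")),
                      quick_mcmc(210 + i))
    diffs[i] <- fit$estimate - naive
  }
  # corrected exceeds naive on average (phi coefficient of a median split
  # of rho = 0.5 data is ~0.33)
  expect_gt(mean(diffs), 0.05)
})
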