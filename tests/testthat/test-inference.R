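p <- model_parameters()

test_that("likelihood contract: shape, mode at the mean, mismatch penalty", {
  obs <- generate_model_observations(p, cv = 0.05, seed = 1, n_roots = 3)
  ll <- log_likelihood(p, "B", obs)
  expect_length(ll$pointwise, nrow(obs))
  expect_equal(ll$total, sum(ll$pointwise))
  # doubling every observation with unchanged predictions penalizes fit
  obs2 <- obs
  obs2$value <- pmin(obs2$value * 2,
                     ifelse(obs2$measurement == "relative_auxin", 1, Inf))
  expect_lt(log_likelihood(p, "B", obs2)$total, ll$total)
  # exact observations attain a higher density than perturbed parameters
  obs0 <- generate_model_observations(p, cv = 0, seed = 1, n_roots = 1)
  perturbed <- model_parameters(l_n = 0.4, tr_n = 0.3)
  expect_gt(log_likelihood(p, "B", obs0)$total,
            log_likelihood(perturbed, "B", obs0)$total)
  # lengths are not part of the fitted likelihood
  len <- generate_length_profiles(condition = "ammonium", n_roots = 2, seed = 1)
  expect_error(log_likelihood(p, "B", len), "length")
})

test_that("adaptive Metropolis reproduces a conjugate Gaussian posterior", {
  set.seed(42)
  y <- rnorm(12, 2, 1)
  tau2 <- 4
  post_var <- 1 / (1 / tau2 + length(y))
  post_mean <- post_var * sum(y)
  lt <- function(th) dnorm(th[["mu"]], 0, sqrt(tau2), log = TRUE) +
    sum(dnorm(y, th[["mu"]], 1, log = TRUE))
  fit <- mh_sample(lt, c(mu = 0), n_draws = 1500, n_chains = 4,
                   warmup = 500, seed = 7)
  mcse <- stats::sd(fit$draws[, "mu"]) / sqrt(fit$diagnostics$ess[1])
  expect_lt(abs(mean(fit$draws[, "mu"]) - post_mean), 2 * mcse + 0.01)
  expect_equal(stats::sd(fit$draws[, "mu"]), sqrt(post_var), tolerance = 0.15)
  expect_lt(fit$diagnostics$rhat[1], 1.05)
  expect_gt(fit$diagnostics$ess[1], 100)
  # identical seeds give identical draws
  fit2 <- mh_sample(lt, c(mu = 0), n_draws = 1500, n_chains = 4,
                    warmup = 500, seed = 7)
  expect_identical(fit$draws, fit2$draws)
})

test_that("prior-only sampling reproduces the prior distribution", {
  empty <- data.frame(condition = character(0), tissue = character(0),
                      position = integer(0), replicate = character(0),
                      measurement = character(0), value = numeric(0))
  fit <- suppressWarnings(
    sample_posterior(empty, "B", free = c("l_n", "s1"), free_sources = FALSE,
                     n_draws = 1500, n_chains = 4, warmup = 500, seed = 3))
  ln <- fit$draws[, "l_n"]
  expect_true(all(ln >= 0 & ln <= 1))
  expect_equal(unname(stats::quantile(ln, c(0.25, 0.5, 0.75))),
               c(0.25, 0.5, 0.75), tolerance = 0.08)
  # half-normal with scale 3 * 8.36: median = scale * qnorm(0.75)
  s1 <- fit$draws[, "s1"]
  expect_true(all(s1 >= 0))
  expect_equal(stats::median(s1), 3 * 8.36 * stats::qnorm(0.75),
               tolerance = 0.1)
})

test_that("the posterior over a source parameter contracts with more roots", {
  sd_of <- function(n_roots) {
    obs <- generate_model_observations(p, cv = 0.05, seed = 11,
                                       n_roots = n_roots,
                                       measurements = "relative_auxin",
                                       conditions = "ammonium")
    fit <- suppressWarnings(
      sample_posterior(obs, "B", free = "s2", free_sources = FALSE,
                       n_draws = 400, n_chains = 2, warmup = 500, seed = 5))
    stats::sd(fit$draws[, "s2"])
  }
  expect_lt(sd_of(50), sd_of(5))
})

test_that("single-parameter profile recovery", {
  obs0 <- generate_model_observations(p, cv = 0, seed = 1, n_roots = 2)
  expect_equal(recover_parameter("l_n", obs0, p, bounds = c(0, 1)), 0.6,
               tolerance = 1e-3)
  expect_equal(recover_parameter("tr_wn", obs0, p, bounds = c(0.02, 0.5)),
               0.13, tolerance = 1e-3)
  # parameters with no effect on steady-state observables are flagged
  expect_error(recover_parameter("k_v0", obs0, p, bounds = c(0.1, 5)),
               "insensitive")
  # recovery error shrinks as observation noise vanishes
  err <- vapply(c(0.15, 0.02), function(cv) {
    mean(vapply(1:6, function(s) {
      obs <- generate_model_observations(p, cv = cv, seed = s, n_roots = 3)
      abs(recover_parameter("l_n", obs, p, bounds = c(0, 1)) - 0.6)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("OLS slope statistic", {
  df <- data.frame(position = rep(10:20, 2),
                   value = rep(2.5 * (10:20) + 1, 2))
  expect_equal(slope_between(df)$slope, 2.5)
  expect_equal(slope_between(data.frame(position = 10:20, value = 7))$slope, 0)
  expect_error(slope_between(data.frame(position = rep(12, 5), value = 1:5)),
               "distinct positions")
  noisy <- data.frame(position = rep(10:20, 40),
                      value = 3 * rep(10:20, 40) + rnorm(440))
  got <- slope_between(noisy)
  expect_gt(got$se, 0)
  expect_equal(got$slope, 3, tolerance = 0.1)
})
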