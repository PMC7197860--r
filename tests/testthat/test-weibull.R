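test_that("closed-form survival quantities are exact for a known Weibull", {
  expect_equal(weib_survival(wm_fix, 0), 1)
  expect_equal(weib_survival(wm_fix, 12.89), exp(-1))
  expect_equal(weib_survival(wm_fix, 10), exp(-(10 / 12.89)^3.75))
  expect_equal(weib_chf(wm_fix, 10), (10 / 12.89)^3.75)
  expect_equal(weib_chf(wm_fix, 12.89), 1)
  expect_equal(weib_median(wm_fix), 12.89 * log(2)^(1 / 3.75))
  expect_equal(weib_median(weibull_model(1, 1)), log(2))
  expect_equal(weib_median(weibull_model(10, 2)), 10 * sqrt(log(2)))
  # CHF at the fitted median is -log(0.5) whatever the shape
  for (fit in list(wm_fix, weibull_model(5, 0.8), weibull_model(20, 6)))
    expect_equal(weib_chf(fit, weib_median(fit)), log(2), tolerance = 1e-12)
  expect_error(weib_survival(wm_fix, -1), "non-negative")
  expect_error(weib_chf(wm_fix, -0.5), "non-negative")
})

test_that("survival and cumulative hazard satisfy the conservation identity", {
  tt <- seq(0, 40, length.out = 101)
  expect_equal(weib_survival(wm_fix, tt) * exp(weib_chf(wm_fix, tt)),
               rep(1, length(tt)), tolerance = 1e-12)
  expect_lt(abs(weib_survival(wm_fix, weib_median(wm_fix)) - 0.5), 1e-10)
  # strictly monotone
  expect_true(all(diff(weib_survival(wm_fix, tt)) < 0))
  expect_true(all(diff(weib_chf(wm_fix, tt)) > 0))
})

test_that("conditional predicted median behaves like a median past censoring", {
  # closed form: S(t_pred) = S(t_cens) / 2
  for (tc in c(0, 2, 10, 25)) {
    tp <- predicted_median(wm_fix, tc)
    expect_equal(weib_survival(wm_fix, tp), weib_survival(wm_fix, tc) / 2,
                 tolerance = 1e-12)
  }
  expect_equal(predicted_median(wm_fix, 0), weib_median(wm_fix))
  tc <- seq(0.5, 30, by = 0.25)
  tp <- predicted_median(wm_fix, tc)
  expect_true(all(diff(tp) > 0))                       # strictly increasing
  expect_true(all(tp > pmax(tc, weib_median(wm_fix)))) # beyond both bounds
  # generic bisection fallback agrees with the closed form
  sf <- function(t) weib_survival(wm_fix, t)
  expect_equal(conditional_median(sf, 10), predicted_median(wm_fix, 10),
               tolerance = 1e-7)
  expect_error(predicted_median(wm_fix, -3), "non-negative")
})

test_that("censored Weibull MLE recovers generating parameters and matches survreg", {
  set.seed(71)
  n <- 5000
  t_e <- rweibull(n, shape = 3.75, scale = 12.89)
  t_o <- simulate_observation_age(n, r = 10, p = 0.4)
  d <- assemble_dataset(t_e, t_o, rep(0:2, length.out = n), rep(1, n))
  fit <- fit_weibull(d$time, d$status)
  expect_s3_class(fit, "weibull_cfit")
  expect_lt(fit$gradient_norm, 1e-8)

  # independent oracle: survreg's Weibull AFT parameterisation
  sr <- survival::survreg(survival::Surv(time, status) ~ 1, data = d,
                          dist = "weibull")
  expect_equal(fit$scale, unname(exp(coef(sr))), tolerance = 1e-6)
  expect_equal(fit$shape, 1 / sr$scale, tolerance = 1e-6)
  expect_equal(fit$loglik, sr$loglik[1], tolerance = 1e-8)

  # within 3 standard errors of truth (asymptotic SEs from survreg)
  se_scale <- unname(exp(coef(sr))) * sqrt(vcov(sr)[1, 1])
  expect_lt(abs(fit$scale - 12.89), 3 * se_scale)
  se_shape <- (1 / sr$scale) * sqrt(vcov(sr)[2, 2]) # delta method on log scale
  expect_lt(abs(fit$shape - 3.75), 3 * se_shape)

  # reported loglik equals the censored objective at the optimum
  ll <- sum(dweibull(d$time[d$status == 1], fit$shape, fit$scale, log = TRUE)) +
    sum(pweibull(d$time[d$status == 0], fit$shape, fit$scale,
                 lower.tail = FALSE, log.p = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
})

test_that("parameter recovery is unbiased across seeded replicates", {
  set.seed(2024)
  est <- t(vapply(1:50, function(i) {
    n <- 5000
    t_e <- rweibull(n, shape = 3.75, scale = 12.89)
    t_o <- simulate_observation_age(n, r = 10, p = 0.4)
    coef(fit_weibull(pmin(t_e, t_o), as.integer(t_e < t_o)))
  }, numeric(2)))
  expect_lt(abs(mean(est[, "scale"]) / 12.89 - 1), 0.01)
  expect_lt(abs(mean(est[, "shape"]) / 3.75 - 1), 0.01)
})

test_that("degenerate and unidentifiable inputs are rejected with diagnostics", {
  expect_error(fit_weibull(c(1, 2, 3), c(0, 0, 0)), "no uncensored")
  expect_error(fit_weibull(rep(4.2, 20), rep(1, 20)), "degenerate")
  expect_error(fit_weibull(5, 1), "at least 2")
  expect_error(fit_weibull(c(-1, 2), c(1, 1)), "strictly positive")
  expect_error(fit_weibull(c(1, 2), c(1, 2)), "status")
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # censoring at t = 1: risk set at 2 is {2, 3}
  km2 <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$survival[km2$time == 2], 0.5)
  expect_equal(km2$survival[km2$time == 3], 0)
  # survival starts at <= 1, non-increasing, in [0, 1]
  d <- sim_small(n = 300, seed = 9)
  km3 <- km_estimate(d$time, d$status)
  expect_true(all(diff(km3$survival) <= 0))
  expect_true(all(km3$survival >= 0 & km3$survival <= 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "one event|positive")
})

test_that("simulated event times are well approximated by the fitted Weibull", {
  d <- simulate_study(1, n = 10000, seed = 77, levels = 1)
  fit <- fit_weibull(d$time, d$status)
  km <- km_estimate(d$time, d$status)
  gap <- max(abs(km$survival - weib_survival(fit, km$time)))
  expect_lt(gap, 0.02)
})
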