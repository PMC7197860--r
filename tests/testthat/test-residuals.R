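# Frozen oracle values below were computed by direct evaluation of the
# residual definitions under the Weibull(12.89, 3.75) curve; the worked-example
# chain (median 11.69, predicted median 13.15) reproduces them exactly.

test_that("Martingale residual is observed minus expected events", {
  expect_equal(res_martingale(1, 1), 0)
  chf10 <- weib_chf(wm_fix, 10)
  expect_equal(res_martingale(0, chf10), -0.3859682, tolerance = 1e-6)
  # censored vs uncensored at equal time and level differ by exactly 1
  tt <- seq(0.5, 30, by = 0.5)
  chf <- weib_chf(wm_fix, tt)
  expect_equal(res_martingale(rep(1, length(tt)), chf) -
               res_martingale(rep(0, length(tt)), chf),
               rep(1, length(tt)))
  expect_true(all(res_martingale(rep(1, length(tt)), chf) <= 1))
  expect_error(res_martingale(1, -0.1), "non-negative")
})

test_that("deviance residual transforms MR as a signed square root", {
  # uncensored at t = lambda: CHF = 1, MR = 0, DR = 0
  expect_equal(res_deviance(0, 1), 0)
  expect_equal(res_deviance(-0.3859682, 0), -sqrt(2 * 0.3859682),
               tolerance = 1e-7)
  expect_equal(res_deviance(0.5, 1), sqrt(-2 * (0.5 + log(0.5))),
               tolerance = 1e-12)
  # rank order of MR is preserved within each censoring stratum
  mr_c <- seq(-3, 0, by = 0.05)
  expect_true(all(diff(res_deviance(mr_c, rep(0, length(mr_c)))) > 0))
  mr_u <- seq(-3, 0.99, by = 0.01)
  expect_true(all(diff(res_deviance(mr_u, rep(1, length(mr_u)))) > 0))
  expect_error(res_deviance(0.2, 0), "censored")
  expect_error(res_deviance(1, 1), "positive")
})

test_that("deviance residual equals its g-function form at delta = 1", {
  # with b = 1 the b*log(b) term vanishes: DR = sign(1-x) sqrt(-2 g(x))
  g <- function(x, b) b - x - b * log(b) + b * log(x)
  x <- seq(0.05, 5, by = 0.05)
  dr_direct <- res_deviance(res_martingale(rep(1, length(x)), x),
                            rep(1, length(x)))
  dr_g <- sign(1 - x) * sqrt(-2 * g(x, 1))
  expect_equal(dr_direct, dr_g, tolerance = 1e-12)
})

test_that("g-function is non-positive with maximum 0 at its parameter", {
  g <- function(x, b) b - x - b * log(b) + b * log(x)
  b <- log(2)
  x <- seq(1e-4, 6, length.out = 2000)
  expect_true(all(g(x, b) <= 1e-14))
  expect_equal(g(b, b), 0)
  expect_lt(max(g(x[abs(x - b) > 1e-3], b)), 0)
})

test_that("OTE residual is zero exactly at the median and decreasing in CHF", {
  expect_equal(res_ote(0), 0)
  expect_equal(res_mmr(log(2)), 0)
  expect_equal(res_mmr(0), log(2))
  # evaluation at the predicted median for censoring at 10
  tstar <- predicted_median(wm_fix, 10)
  mmr <- res_mmr(weib_chf(wm_fix, tstar))
  expect_equal(mmr, -0.3859682, tolerance = 1e-6)
  expect_equal(res_ote(mmr), -0.3978529, tolerance = 1e-6)
  # strictly decreasing in CHF(t*), sign given by t* vs median
  chf <- seq(0.01, 5, by = 0.01)
  ote <- res_ote(res_mmr(chf))
  expect_true(all(diff(ote) < 0))
  expect_true(all(ote[chf < log(2)] > 0))
  expect_true(all(ote[chf > log(2)] < 0))
  expect_error(res_ote(log(2)), "undefined")
})

test_that("naive linear residual is expected minus observed time", {
  tm <- weib_median(wm_fix)
  expect_equal(res_olrr(tm, tm), 0)
  expect_equal(res_olrr(11.69, 13.15), -1.46)
  expect_equal(res_olrr(11.69, 10), 1.69)
  expect_error(res_olrr(11.69, 0), "positive")
})

test_that("the three-individual worked example reproduces end to end", {
  # individual 1 censored at 10; individual 3 uncensored at the corresponding
  # predicted median; individual 2 uncensored with DR equal to individual 1's
  tm <- weib_median(wm_fix)
  expect_equal(tm, 11.69, tolerance = 5e-4)
  t3 <- predicted_median(wm_fix, 10)
  expect_equal(t3, 13.15, tolerance = 5e-4)
  dr1 <- res_deviance(res_martingale(0, weib_chf(wm_fix, 10)), 0)
  t2 <- uniroot(function(t)
    res_deviance(res_martingale(1, weib_chf(wm_fix, t)), 1) - dr1,
    c(tm, 40), tol = 1e-10)$root
  expect_equal(t2, 15.80, tolerance = 0.005 * 15.80)

  d <- data.frame(time = c(10, t2, t3), status = c(0, 1, 1),
                  covariate = rep(1, 3))
  res <- compute_residuals(d, list(`1` = wm_fix))
  # OTE treats individuals 1 and 3 identically (same evaluation time)...
  expect_equal(res$ote[1], res$ote[3], tolerance = 1e-12)
  expect_equal(res$t_star[1], res$t_star[3], tolerance = 1e-12)
  # ...while individual 2 (latest evaluation time) is the most extreme
  expect_lt(res$ote[2], res$ote[1])
  # DR instead ties individuals 1 and 2 and separates 1 from 3
  expect_equal(res$dr[1], res$dr[2], tolerance = 1e-9)
  expect_gt(res$dr[3], res$dr[1])
})

test_that("censored individuals never receive positive MR, DR or OTE", {
  d <- sim_small(n = 600, seed = 42)
  fits <- fit_levels(d)
  res <- compute_residuals(d, fits)
  cens <- res$status == 0
  expect_true(any(cens))
  expect_true(all(res$mr[cens] <= 0))
  expect_true(all(res$dr[cens] <= 0))
  expect_true(all(res$ote[cens] <= 0))
  # censored near 0 has OTE near 0 (predicted median near the median)
  d0 <- data.frame(time = c(1e-6, 5), status = c(0, 1), covariate = c(1, 1))
  r0 <- compute_residuals(d0, list(`1` = wm_fix))
  expect_lt(abs(r0$ote[1]), 1e-6)
})

test_that("OTE, OLRR and evaluation time are rank-order equivalent", {
  set.seed(5)
  tt <- sort(runif(1000, 0.2, 30))
  status <- rbinom(1000, 1, 0.6)
  d <- data.frame(time = tt, status = status, covariate = 1)
  res <- compute_residuals(d, list(`1` = wm_fix))
  ord <- order(res$t_star)
  expect_equal(order(res$ote, decreasing = TRUE), ord)
  expect_equal(order(res$olrr, decreasing = TRUE), ord)
  # MR and DR orderings agree with each other within each censoring stratum
  for (s in 0:1) {
    i <- res$status == s
    expect_equal(order(res$dr[i]), order(res$mr[i]))
  }
})

test_that("standardization centres and scales within each covariate level", {
  d <- sim_small(model = 2, n = 500, seed = 31)
  fits <- fit_levels(d)
  res <- standardize_residuals(compute_residuals(d, fits))
  for (l in unique(d$covariate)) {
    i <- res$covariate == l
    for (k in c("mr_std", "dr_std", "ote_std", "olrr_std")) {
      expect_lt(abs(mean(res[[k]][i])), 1e-10)
      expect_lt(abs(sd(res[[k]][i]) - 1), 1e-10)
    }
    # affine map: within-level rank order unchanged
    expect_equal(order(res$ote_std[i]), order(res$ote[i]))
  }
  bad <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 1, 1),
                    covariate = c(1, 1, 2, 2),
                    ote = c(0.5, 0.5, 1, 2))
  expect_error(standardize_residuals(bad, "ote"), "level 1")
})

test_that("raw OTE stays centred on zero on large simulated samples", {
  d <- simulate_study(1, n = 10000, seed = 55, levels = 1)
  fit <- fit_weibull(d$time, d$status)
  res <- compute_residuals(d, list(`1` = fit), kinds = c("ote", "dr"))
  expect_lt(abs(mean(res$ote)), 0.05)
  # the median sits slightly below zero at ~40% censoring (no censored
  # individual can have positive OTE) but stays small; the contrast with
  # DR's censoring-driven drift is tested across regimes in the sweep
  expect_lt(abs(median(res$ote)), 0.1)
})

test_that("compute_residuals validates its configuration", {
  d <- data.frame(time = 1:3, status = c(1, 1, 1), covariate = c(1, 2, 1))
  expect_error(compute_residuals(d, list(`1` = wm_fix)), "level")
})
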