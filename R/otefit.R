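#' Fit stratified Weibull survival models for residual construction
#'
#' The main entry point of the package. Fits one right-censored Weibull model
#' per covariate level — the estimation backend for ordinary time-to-event
#' (OTE) residuals — via a formula interface with a [survival::Surv()]
#' response:
#'
#' ```
#' ote_fit(Surv(time, status) ~ covariate, data = d)
#' ```
#'
#' The right-hand side must be a single categorical covariate (or `1` for no
#' stratification). Residuals of all supported kinds are then available
#' through [residuals.ote_fit()], survival quantities through
#' [predict.ote_fit()], and diagnostics through [plot.ote_fit()].
#'
#' @param formula a formula whose response is `survival::Surv(time, status)`
#'   and whose right-hand side names one categorical covariate, or is `1`.
#' @param data data frame holding the variables of `formula`.
#' @param fit_subset optional logical vector: rows used for survival-curve
#'   estimation (e.g. unrelated individuals only). Residuals are still
#'   computed for every row.
#' @return An object of class `"ote_fit"`: list with `fits` (named list of
#'   [fit_weibull()] results per level), `data` (time/status/covariate frame),
#'   `formula` and `call`.
#' @examples
#' d <- simulate_study(model = 2, n = 400, seed = 11)
#' fit <- ote_fit(survival::Surv(time, status) ~ covariate, data = d)
#' fit
#' head(residuals(fit, type = "ote"))
#' @export
ote_fit <- function(formula, data, fit_subset = NULL) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv(time, status) object")
  if (ncol(y) != 2L || attr(y, "type") != "right")
    stop("only right-censored Surv(time, status) responses are supported")
  time <- as.numeric(y[, 1L])
  status <- as.numeric(y[, 2L])
  labs <- attr(stats::terms(mf), "term.labels")
  if (length(labs) > 1L)
    stop("the right-hand side must be a single categorical covariate (or 1)")
  covariate <- if (length(labs) == 0L) rep("1", length(time))
               else as.character(mf[[labs]])
  validate_records(time, status)
  if (is.null(fit_subset)) fit_subset <- rep(TRUE, length(time))
  stopifnot(is.logical(fit_subset), length(fit_subset) == length(time))

  levels <- sort(unique(covariate))
  fits <- lapply(levels, function(l) {
    i <- covariate == l & fit_subset
    fit_weibull(time[i], status[i], level = l)
  })
  names(fits) <- levels
  structure(list(fits = fits,
                 data = data.frame(time = time, status = status,
                                   covariate = covariate,
                                   stringsAsFactors = FALSE),
                 formula = formula, fit_subset = fit_subset, call = cl),
            class = "ote_fit")
}

#' @export
print.ote_fit <- function(x, ...) {
  cat("Stratified right-censored Weibull fit\n")
  cat("  call:", deparse(x$call), "\n")
  print(summary_table(x), digits = 5)
  invisible(x)
}

summary_table <- function(object) {
  do.call(rbind, lapply(object$fits, function(f)
    data.frame(level = f$level, scale = f$scale, shape = f$shape,
               median = weib_median(f), n = f$n_total, events = f$n_events,
               pct_censored = 100 * (1 - f$n_events / f$n_total),
               loglik = f$loglik, row.names = NULL)))
}

#' Summary of a stratified Weibull fit
#'
#' @param object an `"ote_fit"` object.
#' @param ... unused.
#' @return An object of class `"summary.ote_fit"`: the per-level parameter
#'   table plus residual summary statistics.
#' @export
summary.ote_fit <- function(object, ...) {
  res <- stats::residuals(object, type = "all", standardize = FALSE)
  structure(list(table = summary_table(object),
                 residual_summary = vapply(
                   res[intersect(RESIDUAL_KINDS, names(res))],
                   function(z) c(mean = mean(z), median = stats::median(z),
                                 sd = stats::sd(z)),
                   numeric(3))),
            class = "summary.ote_fit")
}

#' @export
print.summary.ote_fit <- function(x, ...) {
  cat("Per-level Weibull parameters:\n")
  print(x$table, digits = 5)
  cat("\nRaw residual summaries (all individuals):\n")
  print(t(x$residual_summary), digits = 4)
  invisible(x)
}

#' @export
coef.ote_fit <- function(object, ...) {
  m <- t(vapply(object$fits, function(f) c(f$scale, f$shape), numeric(2)))
  colnames(m) <- c("scale", "shape")
  m
}

#' Residuals from a stratified Weibull survival fit
#'
#' @param object an `"ote_fit"` object.
#' @param type `"all"` or a subset of `c("mr", "dr", "mmr", "ote", "olrr")`.
#' @param standardize standardize within covariate levels (appends `_std`
#'   columns)? Default `TRUE`.
#' @param ... unused.
#' @return A data frame: the model data plus `t_star` and the requested
#'   residual columns.
#' @export
residuals.ote_fit <- function(object, type = "all", standardize = TRUE, ...) {
  kinds <- if (identical(type, "all")) RESIDUAL_KINDS
           else match.arg(type, RESIDUAL_KINDS, several.ok = TRUE)
  tab <- compute_residuals(object$data, object$fits, kinds)
  if (standardize) tab <- standardize_residuals(tab, kinds)
  tab
}

#' Predictions from a stratified Weibull survival fit
#'
#' @param object an `"ote_fit"` object.
#' @param newdata data frame with `time`, `status` and `covariate` columns;
#'   defaults to the fitting data.
#' @param type one of `"tstar"` (evaluation time: observed failure time if
#'   uncensored, conditional median if censored), `"median"` (level median
#'   survival time), `"conditional_median"`, `"survival"` or `"chf"` (each
#'   evaluated at `newdata$time`).
#' @param ... unused.
#' @return A numeric vector, one value per row of `newdata`.
#' @export
predict.ote_fit <- function(object, newdata = NULL,
                            type = c("tstar", "median", "conditional_median",
                                     "survival", "chf"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  lev <- as.character(newdata$covariate)
  missing_fit <- setdiff(unique(lev), names(object$fits))
  if (length(missing_fit))
    stop("no fitted model for level(s): ", paste(missing_fit, collapse = ", "))
  out <- numeric(nrow(newdata))
  for (l in unique(lev)) {
    i <- lev == l
    f <- object$fits[[l]]
    out[i] <- switch(type,
      tstar = ifelse(newdata$status[i] == 1, newdata$time[i],
                     predicted_median(f, newdata$time[i])),
      median = weib_median(f),
      conditional_median = predicted_median(f, newdata$time[i]),
      survival = weib_survival(f, newdata$time[i]),
      chf = weib_chf(f, newdata$time[i]))
  }
  out
}

#' Diagnostic plots for a stratified Weibull survival fit
#'
#' `which = "km"` overlays the fitted Weibull survival curves on the
#' Kaplan-Meier estimates, one panel message per level; `which = "residuals"`
#' draws OTE, DR (uncensored and censored branches) and scaled OLRR as
#' functions of the evaluation time for the first (or given) level.
#'
#' @param x an `"ote_fit"` object.
#' @param which `"km"` or `"residuals"`.
#' @param level covariate level to plot for `which = "residuals"`.
#' @param ... passed to the underlying plot calls.
#' @return Invisibly `x`.
#' @export
plot.ote_fit <- function(x, which = c("km", "residuals"),
                         level = names(x$fits)[1L], ...) {
  which <- match.arg(which)
  if (which == "km") {
    op <- graphics::par(mfrow = c(1, length(x$fits)))
    on.exit(graphics::par(op))
    for (l in names(x$fits)) {
      i <- x$data$covariate == l
      km <- km_estimate(x$data$time[i], x$data$status[i])
      graphics::plot(km$time, km$survival, type = "s", ylim = c(0, 1),
                     xlab = "time (years)", ylab = "S(t)",
                     main = paste("level", l), ...)
      tt <- seq(0, max(x$data$time[i]), length.out = 200)
      graphics::lines(tt, weib_survival(x$fits[[l]], tt), col = 2, lwd = 2)
      graphics::legend("topright", c("Kaplan-Meier", "Weibull fit"),
                       col = c(1, 2), lty = 1, bty = "n")
    }
  } else {
    f <- x$fits[[as.character(level)]]
    tm <- weib_median(f)
    tt <- seq(0.05 * tm, 2.2 * tm, length.out = 300)
    chf <- weib_chf(f, tt)
    ote <- res_ote(res_mmr(chf))
    dr1 <- res_deviance(res_martingale(rep(1, length(tt)), chf), rep(1, length(tt)))
    graphics::plot(tt, ote, type = "l", lwd = 2,
                   xlab = "evaluation time (years)", ylab = "residual",
                   main = paste("residuals vs time, level", level), ...)
    graphics::lines(tt, dr1, col = 2)
    graphics::lines(tt, res_olrr(tm, tt) / tm, col = 4, lty = 2)
    graphics::abline(h = 0, v = tm, col = "grey")
    graphics::legend("bottomleft",
                     c("OTE", "DR (uncensored)", "OLRR / median"),
                     col = c(1, 2, 4), lty = c(1, 1, 2), bty = "n")
  }
  invisible(x)
}
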