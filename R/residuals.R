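#' Martingale residual
#'
#' \eqn{MR = \delta - \mathrm{CHF}(t_{surv})}: observed minus expected number
#' of events over the individual's follow-up. Range \eqn{(-\infty, 1]}; two
#' individuals at the same time and covariate level, one censored and one not,
#' differ in MR by exactly 1.
#'
#' @param delta event indicators (0 censored, 1 uncensored).
#' @param chf cumulative hazard evaluated at the individual's survival time.
#' @return Martingale residuals.
#' @export
res_martingale <- function(delta, chf) {
  if (any(chf < 0)) stop("cumulative hazard must be non-negative")
  if (!all(delta %in% c(0, 1))) stop("delta must be 0 or 1")
  delta - chf
}

#' Deviance residual
#'
#' Signed square-root transform of the Martingale residual,
#' \eqn{DR = \mathrm{sign}(MR)\sqrt{-2\{MR + \delta \log(\delta - MR)\}}},
#' which symmetrises MR while preserving its sign and rank order within each
#' censoring stratum. Square-root arguments in `(-1e-12, 0)` are clipped to 0.
#'
#' @param mr Martingale residuals.
#' @param delta event indicators matching `mr`.
#' @return Deviance residuals.
#' @export
res_deviance <- function(mr, delta) {
  if (!all(delta %in% c(0, 1))) stop("delta must be 0 or 1")
  if (any(delta == 1 & mr >= 1)) stop("delta - mr must be positive when delta = 1")
  if (any(delta == 0 & mr > 0)) stop("mr must be <= 0 for censored individuals")
  arg <- -2 * (mr + ifelse(delta == 1, log(1 - mr), 0))
  arg <- clip_negatives(arg)
  sign(mr) * sqrt(arg)
}

#' Modified Martingale residual
#'
#' \eqn{MMR = -\log(0.5) - \mathrm{CHF}(t^{*})}, evaluated at the individual's
#' observed (uncensored) or predicted (censored) event time \eqn{t^{*}}. Zero
#' exactly when \eqn{t^{*}} is the fitted median survival time, since
#' \eqn{\mathrm{CHF}(\tilde t) = -\log(0.5)} for any survival curve.
#'
#' @param chf cumulative hazard at \eqn{t^{*}}.
#' @return Modified Martingale residuals, at most \eqn{\log 2}.
#' @export
res_mmr <- function(chf) {
  if (any(chf < 0)) stop("cumulative hazard must be non-negative")
  log(2) - chf
}

#' Ordinary time-to-event (OTE) residual
#'
#' Deviance-style transform of the modified Martingale residual with the event
#' indicator replaced by the constant \eqn{\delta = b = -\log(0.5)} for
#' everyone:
#' \deqn{OTE = \mathrm{sign}(MMR)\sqrt{-2\{MMR - b\log b + b\log(b - MMR)\}}.}
#' Equivalently \eqn{OTE = \mathrm{sign}(b - x)\sqrt{-2 g(x)}} with
#' \eqn{x = \mathrm{CHF}(t^{*})} and \eqn{g(x) = b - x - b\log b + b\log x},
#' which is non-positive with maximum 0 at \eqn{x = b}. OTE is zero if and
#' only if \eqn{t^{*}} equals the median survival time, positive for earlier
#' times, negative for later ones, and strictly decreasing in
#' \eqn{\mathrm{CHF}(t^{*})}.
#'
#' @param mmr modified Martingale residuals (see [res_mmr()]); must be strictly
#'   below \eqn{\log 2} — `mmr == log(2)` corresponds to \eqn{t^{*} = 0},
#'   where the transform diverges.
#' @return OTE residuals.
#' @export
res_ote <- function(mmr) {
  b <- log(2)
  if (any(mmr >= b))
    stop("OTE is undefined at CHF(t*) = 0 (t* = 0): mmr must be < log(2)")
  arg <- -2 * (mmr - b * log(b) + b * log(b - mmr))
  arg <- clip_negatives(arg)
  sign(mmr) * sqrt(arg)
}

#' Naive linear (ordinary-linear-regression-like) residual
#'
#' \eqn{OLRR = \tilde t - t^{*}}: median survival time minus the observed or
#' predicted event time, on the raw time scale, ignoring the hazard function.
#' Positive for early events, negative for late ones ("expected minus
#' observed", for sign comparability with OTE).
#'
#' @param median median survival time(s), years.
#' @param t_star observed or predicted event times, years (> 0).
#' @return Residuals in years.
#' @export
res_olrr <- function(median, t_star) {
  if (any(t_star <= 0)) stop("t_star must be strictly positive")
  median - t_star
}

RESIDUAL_KINDS <- c("mr", "dr", "mmr", "ote", "olrr")

#' Compute survival residuals per individual
#'
#' Evaluates the requested residuals for each record under the fitted Weibull
#' model of its covariate level. MR and DR use the record's own time and its
#' own event indicator; MMR, OTE and OLRR use the evaluation time
#' \eqn{t^{*}} — the observed failure time for uncensored individuals and the
#' conditional median [predicted_median()] for censored ones — with the
#' constant \eqn{\delta = -\log(0.5)} for everyone. All level-specific
#' quantities (median, predicted median, CHF) come from that level's fit.
#'
#' @param data data frame with columns `time`, `status` and `covariate`
#'   (plus any others, carried through).
#' @param fits named list of `"weibull_cfit"` objects, one per covariate level
#'   appearing in `data`.
#' @param kinds residual kinds to compute, a subset of
#'   `c("mr", "dr", "mmr", "ote", "olrr")`.
#' @return The input data frame augmented with a `t_star` column and one
#'   column per requested residual kind.
#' @export
compute_residuals <- function(data, fits, kinds = RESIDUAL_KINDS) {
  kinds <- match.arg(kinds, RESIDUAL_KINDS, several.ok = TRUE)
  stopifnot(is.data.frame(data),
            all(c("time", "status", "covariate") %in% names(data)))
  validate_records(data$time, data$status)
  lev <- as.character(data$covariate)
  missing_fit <- setdiff(unique(lev), names(fits))
  if (length(missing_fit))
    stop("no fitted survival model for covariate level(s): ",
         paste(missing_fit, collapse = ", "))

  n <- nrow(data)
  chf_own <- t_star <- med <- numeric(n)
  for (l in unique(lev)) {
    i <- lev == l
    f <- fits[[l]]
    chf_own[i] <- weib_chf(f, data$time[i])
    t_star[i] <- ifelse(data$status[i] == 1, data$time[i],
                        predicted_median(f, data$time[i]))
    med[i] <- weib_median(f)
  }
  chf_star <- chf_own
  cens <- data$status == 0
  for (l in unique(lev)) {
    i <- lev == l & cens
    if (any(i)) chf_star[i] <- weib_chf(fits[[l]], t_star[i])
  }

  out <- data
  out$t_star <- t_star
  if ("mr" %in% kinds || "dr" %in% kinds)
    mr <- res_martingale(data$status, chf_own)
  if ("mr" %in% kinds) out$mr <- mr
  if ("dr" %in% kinds) out$dr <- res_deviance(mr, data$status)
  if ("mmr" %in% kinds || "ote" %in% kinds)
    mmr <- res_mmr(chf_star)
  if ("mmr" %in% kinds) out$mmr <- mmr
  if ("ote" %in% kinds) out$ote <- res_ote(mmr)
  if ("olrr" %in% kinds) out$olrr <- res_olrr(med, t_star)
  attr(out, "residual_kinds") <- kinds
  out
}

#' Standardize residuals within covariate levels
#'
#' Centres and scales each residual column separately within each covariate
#' level, \eqn{(RES - \overline{RES}_y) / \mathrm{s.d.}(RES_y)} with the
#' sample (n-1) standard deviation, so that residuals from different levels
#' mix on a common scale with the covariate effect removed. Appends `_std`
#' columns.
#'
#' @param table output of [compute_residuals()].
#' @param kinds residual columns to standardize (defaults to those present).
#' @return `table` with `<kind>_std` columns appended.
#' @export
standardize_residuals <- function(table, kinds = NULL) {
  if (is.null(kinds))
    kinds <- intersect(RESIDUAL_KINDS, names(table))
  stopifnot(length(kinds) > 0, all(kinds %in% names(table)))
  lev <- as.character(table$covariate)
  for (k in kinds) {
    z <- numeric(nrow(table))
    for (l in unique(lev)) {
      i <- lev == l
      if (sum(i) < 2L)
        stop("cannot standardize level ", l, ": fewer than 2 individuals")
      s <- stats::sd(table[[k]][i])
      if (s == 0)
        stop("cannot standardize level ", l, ": zero within-level variance in ", k)
      z[i] <- (table[[k]][i] - mean(table[[k]][i])) / s
    }
    table[[paste0(k, "_std")]] <- z
  }
  table
}

clip_negatives <- function(x, tol = 1e-12) {
  bad <- x < 0
  if (any(x[bad] < -tol))
    stop("negative square-root argument beyond numerical tolerance: min ",
         format(min(x)))
  x[bad] <- 0
  x
}
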