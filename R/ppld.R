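#' Halton low-discrepancy sequence
#'
#' Deterministic quasi-random points in the unit hypercube (van der Corput
#' radical-inverse sequences in the first `dim` primes, with a burn-in skip).
#' Used as the integration node set for [bayes_ratio()].
#'
#' @param n number of points.
#' @param dim dimension (at most 6).
#' @param skip number of initial points to discard.
#' @return An `n` x `dim` matrix with entries in (0, 1).
#' @export
halton_sequence <- function(n, dim, skip = 20L) {
  primes <- c(2L, 3L, 5L, 7L, 11L, 13L)
  stopifnot(n >= 1, dim >= 1, dim <= length(primes))
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    ii <- seq_len(n) + skip
    x <- numeric(n)
    f <- 1
    while (any(ii > 0)) {
      f <- f / b
      x <- x + f * (ii %% b)
      ii <- ii %/% b
    }
    out[, d] <- x
  }
  out
}

#' Prior specification for the trait-model parameters
#'
#' The simplified association score integrates a genotype-specific trait model
#' with parameter vector \eqn{\gamma = (\mu_{11}, \mu_{12}, \mu_{22},
#' \sigma_{11}, \sigma_{12}, \sigma_{22})} — location and scale of three
#' t-distributions, one per genotype — against independent uniform priors in a
#' box adapted to the sample: means uniform on
#' `[m - mean_halfwidth*s, m + mean_halfwidth*s]` and standard deviations
#' uniform on `[sd_range[1]*s, sd_range[2]*s]`, where `m` and `s` are the
#' sample mean and s.d. of the trait. The default half-width of one pooled
#' s.d. is a unit-information choice: the prior carries about as much
#' information on each location as a single observation.
#'
#' @param mean_halfwidth half-width of the uniform prior on each genotype
#'   mean, in units of the pooled trait s.d.
#' @param sd_range lower and upper bound of the uniform prior on each
#'   genotype s.d., in units of the pooled trait s.d.
#' @return An object of class `"ppld_prior"`.
#' @export
ppld_prior <- function(mean_halfwidth = 1, sd_range = c(0.5, 2)) {
  stopifnot(mean_halfwidth > 0, length(sd_range) == 2L,
            sd_range[1] > 0, sd_range[2] > sd_range[1])
  structure(list(mean_halfwidth = mean_halfwidth, sd_range = sd_range),
            class = "ppld_prior")
}

#' Bayes ratio for trait-genotype association
#'
#' Integrated likelihood ratio contrasting "association" — each genotype class
#' has its own location-scale t-distribution for the trait — against "no
#' association" — a single t-distribution with pooled sample location and
#' scale:
#' \deqn{BR = \int LR(\gamma)\, f(\gamma)\, d\gamma,}
#' with \eqn{f(\gamma)} the [ppld_prior()] box. Nuisance structure is fixed by
#' construction (direct genotypic effect of the scored marker: recombination
#' fraction 0, complete disequilibrium, no admixture), so the three genotype
#' classes act directly as mixture components.
#'
#' The 6-dimensional integral is evaluated by quasi-Monte-Carlo importance
#' sampling: Halton nodes are pushed through t(3) proposals moment-matched to
#' each genotype class (location at the class mean with scale
#' `inflation * s_g / sqrt(n_g)`; log-scale at the class s.d. with scale
#' `inflation / sqrt(2 n_g)`), and prior-over-proposal weights make the
#' estimate unbiased for the boxed prior. The integrand peak at realistic
#' sample sizes is far too narrow for raw nodes in the prior box to resolve,
#' which is why importance sampling is used. The returned object carries the
#' effective sample size and relative Monte-Carlo error of the weighted mean.
#'
#' @param trait numeric trait values (typically standardized residuals).
#' @param genotypes genotype codes 0/1/2, same length as `trait`.
#' @param prior a [ppld_prior()] object.
#' @param dof degrees of freedom of the t kernels (> 2, default 10).
#' @param nodes number of integration nodes (default `2^13`).
#' @param inflation proposal-width inflation factor.
#' @return An object of class `"bayes_ratio"`: list with `br`, `log_br`,
#'   `ess` (effective sample size), `rel_se` (relative MC standard error),
#'   `nodes`, `dof`, `prior`.
#' @export
bayes_ratio <- function(trait, genotypes, prior = ppld_prior(), dof = 10,
                        nodes = 2^13, inflation = 2) {
  stopifnot(length(trait) == length(genotypes), all(is.finite(trait)),
            dof > 2, nodes >= 16)
  if (!all(genotypes %in% 0:2)) stop("genotypes must be coded 0, 1, 2")
  classes <- sort(unique(genotypes))
  if (length(classes) < 2L)
    stop("association is undefined for a monomorphic marker ",
         "(single genotype class observed)")
  small <- vapply(classes, function(k) sum(genotypes == k) < 2L, logical(1))
  if (any(small))
    warning("genotype class(es) with fewer than 2 individuals: ",
            "integration may be unstable")
  m <- mean(trait)
  s <- stats::sd(trait)
  if (s == 0) stop("trait has zero variance")

  H <- halton_sequence(nodes, 6L)
  ll <- numeric(nodes)   # numerator log-likelihood at each node
  lq <- numeric(nodes)   # log proposal density
  lf <- numeric(nodes)   # log prior density
  a <- prior$mean_halfwidth * s
  slo <- prior$sd_range[1] * s
  shi <- prior$sd_range[2] * s
  lf_const <- -log(2 * a) - log(shi - slo)

  for (k in 0:2) {
    xg <- trait[genotypes == k]
    ng <- length(xg)
    if (ng >= 2L && stats::sd(xg) > 0) {
      est <- t_mle(xg, dof)        # proposal centre at the class t MLE
      mg <- est[1L]
      sg0 <- est[2L]
    } else {
      mg <- m
      sg0 <- s
    }
    npseudo <- max(ng, 2L)
    smu <- inflation * sg0 / sqrt(npseudo)
    ssg <- inflation / sqrt(2 * npseudo)
    zmu <- stats::qt(H[, k + 1L], 3)
    zsg <- stats::qt(H[, k + 4L], 3)
    mu <- mg + smu * zmu
    lsig <- log(sg0) + ssg * zsg
    sig <- exp(lsig)
    lq <- lq + stats::dt(zmu, 3, log = TRUE) - log(smu) +
               stats::dt(zsg, 3, log = TRUE) - log(ssg) - lsig
    inbox <- mu >= m - a & mu <= m + a & sig >= slo & sig <= shi
    lf <- lf + ifelse(inbox, lf_const, -Inf)
    if (ng > 0L) {
      z <- (matrix(xg, nodes, ng, byrow = TRUE) - mu) / sig
      ll <- ll + rowSums(stats::dt(z, dof, log = TRUE)) - ng * lsig
    }
  }
  ll0 <- pooled_t_loglik(trait, dof, m, s)

  w <- ll + lf - lq - ll0
  fin <- is.finite(w)
  if (!any(fin))
    stop("Bayes-ratio integration failed: no node carries prior mass ",
         "(consider widening the prior or the proposal inflation)")
  wm <- max(w[fin])
  ew <- ifelse(fin, exp(w - wm), 0)
  br <- mean(ew) * exp(wm)
  ess <- sum(ew)^2 / sum(ew^2)
  rel_se <- stats::sd(ew) / (sqrt(nodes) * mean(ew))
  structure(list(br = br, log_br = log(br), ess = ess, rel_se = rel_se,
                 nodes = nodes, dof = dof, prior = prior),
            class = "bayes_ratio")
}

# "No association" log-likelihood: a single location-scale t fitted to the
# pooled trait by maximum likelihood. Plugging in the sample moments instead
# would under-fit skewed residual distributions (the t MLE downweights long
# tails) and let the genotype-specific numerator win on shape alone, inflating
# BR for markers with no effect.
pooled_t_loglik <- function(x, dof, m, s) {
  -t_nll_opt(x, dof, m, s)$value
}

# location-scale t maximum likelihood (Nelder-Mead on (mu, log sigma))
t_nll_opt <- function(x, dof, m0, s0) {
  nll <- function(p) {
    -sum(stats::dt((x - p[1L]) / exp(p[2L]), dof, log = TRUE)) +
      length(x) * p[2L]
  }
  stats::optim(c(m0, log(s0)), nll, control = list(reltol = 1e-12))
}

t_mle <- function(x, dof) {
  opt <- t_nll_opt(x, dof, mean(x), stats::sd(x))
  c(opt$par[1L], exp(opt$par[2L]))
}

#' @export
print.bayes_ratio <- function(x, ...) {
  cat(sprintf("Bayes ratio: %.6g  (log BR %.3f)\n", x$br, x$log_br))
  cat(sprintf("  %d QMC nodes, ESS %.0f, relative MC se %.3f\n",
              x$nodes, x$ess, x$rel_se))
  invisible(x)
}

#' Posterior probability of trait-marker association (PPLD)
#'
#' \eqn{\mathrm{PPLD} = \pi BR / \{\pi BR + (1 - \pi)\}}, with prior
#' probability \eqn{\pi = 0.0004} that a random SNP is in detectable LD with a
#' trait locus. Strictly increasing in BR; equals the prior at BR = 1.
#'
#' @param br a Bayes ratio (number or [bayes_ratio()] object).
#' @param pi prior probability of association, in (0, 1).
#' @return Posterior probability in (0, 1).
#' @examples
#' ppld(1)        # = prior
#' ppld(2500)     # about 0.5
#' @export
ppld <- function(br, pi = 0.0004) {
  if (inherits(br, "bayes_ratio")) br <- br$br
  stopifnot(all(br >= 0), pi > 0, pi < 1)
  pi * br / (pi * br + 1 - pi)
}

#' Replicated PPLD scoring experiment for one generating model
#'
#' Runs the full evaluation pipeline `reps` times: simulate a study dataset,
#' fit the per-level Weibull models, compute and standardize the residuals,
#' and score each requested residual kind against the genotypes with
#' [bayes_ratio()] and [ppld()]. Per-replicate seeds are drawn once from
#' `seed`, so the whole experiment is reproducible.
#'
#' @param model generating model id 1-8, or a [generating_model()] object.
#' @param kinds residual kinds to score (standardized versions are used).
#' @param reps number of replicates.
#' @param n individuals per replicate.
#' @param seed integer seed for the experiment.
#' @param drop_censored drop censored individuals before fitting and scoring?
#'   (Used to quantify their contribution.)
#' @param pi prior probability of association.
#' @param ... passed to [bayes_ratio()] (prior, dof, nodes, inflation).
#' @return An object of class `"ppld_experiment"`: list with `ppld` (reps x
#'   kinds matrix), `br` (matrix of Bayes ratios), `mean`, `sd`,
#'   `correlations` (between PPLD columns), `model`, `n`, `reps`.
#' @export
ppld_experiment <- function(model, kinds = c("mr", "dr", "ote", "olrr"),
                            reps = 50, n = 500, seed = 1,
                            drop_censored = FALSE, pi = 0.0004, ...) {
  kinds <- match.arg(kinds, RESIDUAL_KINDS, several.ok = TRUE)
  stopifnot(reps >= 1)
  gm <- if (inherits(model, "generating_model")) model else generating_model(model)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  pp <- br <- matrix(NA_real_, reps, length(kinds),
                     dimnames = list(NULL, kinds))
  for (i in seq_len(reps)) {
    d <- simulate_study(gm, n = n, seed = rep_seeds[i])
    if (drop_censored) d <- d[d$status == 1, , drop = FALSE]
    fits <- lapply(split(d, d$covariate),
                   function(dd) fit_weibull(dd$time, dd$status,
                                            level = dd$covariate[1]))
    res <- standardize_residuals(compute_residuals(d, fits, kinds), kinds)
    for (k in kinds) {
      b <- bayes_ratio(res[[paste0(k, "_std")]], d$genotype, ...)
      br[i, k] <- b$br
      pp[i, k] <- ppld(b, pi = pi)
    }
  }
  structure(list(ppld = pp, br = br,
                 mean = colMeans(pp), sd = apply(pp, 2, stats::sd),
                 correlations = if (length(kinds) > 1L) stats::cor(pp) else NULL,
                 model = gm$model, n = n, reps = reps,
                 drop_censored = drop_censored),
            class = "ppld_experiment")
}

#' @export
print.ppld_experiment <- function(x, ...) {
  cat(sprintf("PPLD experiment: model %d, %d replicates of n = %d%s\n",
              x$model, x$reps, x$n,
              if (x$drop_censored) " (censored individuals dropped)" else ""))
  cat("  mean PPLD: ",
      paste(sprintf("%s %.4g", names(x$mean), x$mean), collapse = ", "), "\n")
  invisible(x)
}

#' PPLD experiments across several generating models
#'
#' Convenience grid over [ppld_experiment()]: one experiment per model,
#' summarised as a mean/s.d. table per residual kind plus the pairwise
#' correlation matrices of the per-replicate PPLDs.
#'
#' @param models generating model ids.
#' @inheritParams ppld_experiment
#' @return An object of class `"ppld_grid"`: list with `experiments` (one
#'   [ppld_experiment()] per model), `mean` and `sd` (models x kinds
#'   matrices).
#' @export
ppld_grid <- function(models = 2:8, kinds = c("mr", "dr", "ote", "olrr"),
                      reps = 50, n = 500, seed = 1, ...) {
  ex <- lapply(models, function(m)
    ppld_experiment(m, kinds = kinds, reps = reps, n = n,
                    seed = seed + m, ...))
  names(ex) <- paste0("model", models)
  structure(list(experiments = ex,
                 mean = t(vapply(ex, `[[`, numeric(length(kinds)), "mean")),
                 sd = t(vapply(ex, `[[`, numeric(length(kinds)), "sd"))),
            class = "ppld_grid")
}

#' @export
print.ppld_grid <- function(x, ...) {
  cat("Mean PPLD by model and residual kind:\n")
  print(x$mean, digits = 4)
  invisible(x)
}
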