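#' Aggregate trials into per-level response counts
#'
#' Tallies FTV responses per distinct signed FOV level. Practice trials
#' (rows with `is_practice == TRUE`) are excluded.
#'
#' @param trials data.frame of trial records with at least `signed_fov` and
#'   `response` (`"FTV"`/`"FA"`) columns.
#' @return A `level_counts` data.frame with columns `signed_fov`, `n`, `k`
#'   (FTV count), sorted by level.
#' @export
aggregate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!is.null(trials$is_practice)) trials <- trials[!trials$is_practice, ]
  if (nrow(trials) == 0L) stop("no analysable trials", call. = FALSE)
  if (!all(trials$response %in% c("FTV", "FA"))) {
    stop("`response` must be 'FTV' or 'FA'", call. = FALSE)
  }
  lev <- sort(unique(trials$signed_fov))
  n <- as.integer(table(factor(trials$signed_fov, levels = lev)))
  k <- as.integer(tapply(trials$response == "FTV",
                         factor(trials$signed_fov, levels = lev), sum))
  level_counts(lev, n, k)
}

#' Construct a level-counts table
#'
#' @param signed_fov stimulus levels, degrees; duplicated rows for the
#'   same level are merged by summing counts.
#' @param n trials per level.
#' @param k FTV responses per level (`0 <= k <= n`). Non-integer values
#'   are allowed (weighted pooling produces them).
#' @return A `level_counts` data.frame with distinct, sorted levels.
#' @export
level_counts <- function(signed_fov, n, k) {
  if (any(k < 0) || any(k > n) || any(n < 0)) {
    stop("need 0 <= k <= n at every level", call. = FALSE)
  }
  if (anyDuplicated(signed_fov)) {
    lev <- sort(unique(signed_fov))
    f <- factor(signed_fov, levels = lev)
    n <- as.vector(tapply(n, f, sum))
    k <- as.vector(tapply(k, f, sum))
    signed_fov <- lev
  }
  out <- data.frame(signed_fov = signed_fov, n = n, k = k)
  out <- out[order(out$signed_fov), ]
  rownames(out) <- NULL
  class(out) <- c("level_counts", "data.frame")
  out
}

# psychometric curve used by the fitter; direction +1 = canonical
# decreasing curve, -1 = mirrored (increasing) curve
psy_curve <- function(x, psa, spread, lapse, guess, direction = 1) {
  guess + (1 - guess - lapse) *
    stats::pnorm(direction * (psa - x) / spread)
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `p(x) = guess + (1 - guess - lapse) * pnorm((psa - x)/spread)` to
#' binomial counts by maximizing the binomial log-likelihood, with lapse
#' and guess constrained to `[0, 0.06]` by default (set both bounds to
#' `c(0, 0)` to fix them). Optimization is multistart L-BFGS-B over a
#' deterministic grid of (psa, spread) initial values so the returned
#' optimum is stable across runs; ties broken by first found.
#'
#' @param counts a `level_counts` table (>= 3 informative levels
#'   recommended; >= 2 required with lapse/guess fixed).
#' @param lapse_bounds,guess_bounds length-2 bounds; `c(0, 0)` fixes the
#'   rate at zero.
#' @param n_starts number of multistart initial values (default 9).
#' @param direction `"auto"` (default) fits both the canonical decreasing
#'   curve and its mirrored increasing variant and keeps the better
#'   likelihood (inverse observers exist); `"decreasing"`/`"increasing"`
#'   fix the orientation.
#' @return A `psychometric_fit`: `psa`, `spread`, `lapse`, `guess`,
#'   `slope_at_psa` (proportion/degree, signed), `log_lik`, `deviance`,
#'   `converged`, `extreme_psa` (|psa| beyond the stimulated range),
#'   `counts`, and (after [mc_goodness_of_fit()]) `mc_p_value`, `n_mc`.
#' @export
fit_psychometric <- function(counts, lapse_bounds = c(0, 0.06),
                             guess_bounds = c(0, 0.06), n_starts = 9L,
                             direction = c("auto", "decreasing",
                                           "increasing")) {
  direction <- match.arg(direction)
  counts <- validate_counts(counts)
  used <- counts[counts$n > 0, ]
  fix_l <- lapse_bounds[1] == lapse_bounds[2]
  fix_g <- guess_bounds[1] == guess_bounds[2]
  if (nrow(used) < 2L + !fix_l + !fix_g) {
    stop("too few informative levels for the requested parameterization",
         call. = FALSE)
  }
  x <- used$signed_fov; n <- used$n; k <- used$k
  rng <- diff(range(x))
  if (rng == 0) stop("need at least two distinct levels", call. = FALSE)

  make_nll <- function(dir) function(par) {
    psa <- par[1]; spread <- exp(par[2])
    lapse <- if (fix_l) lapse_bounds[1] else par[3]
    guess <- if (fix_g) guess_bounds[1] else par[[length(par)]]
    p <- psy_curve(x, psa, spread, lapse, guess, dir)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }

  # deterministic start grid: empirical 50% crossing plus range quantiles,
  # crossed with three spread scales
  prop <- k / n
  cross <- empirical_crossing(x, prop)
  psa0 <- unique(c(cross, stats::quantile(x, c(0.25, 0.5, 0.75),
                                          names = FALSE)))
  spread0 <- rng * c(0.3, 1, 3)
  starts <- expand.grid(psa = psa0, spread = spread0)
  starts <- starts[seq_len(min(nrow(starts), max(1L, n_starts))), ,
                   drop = FALSE]

  lower <- c(min(x) - 20 * rng, log(rng * 1e-3))
  upper <- c(max(x) + 20 * rng, log(rng * 1e3))
  if (!fix_l) { lower <- c(lower, lapse_bounds[1]); upper <- c(upper, lapse_bounds[2]) }
  if (!fix_g) { lower <- c(lower, guess_bounds[1]); upper <- c(upper, guess_bounds[2]) }

  dirs <- switch(direction, auto = c(1, -1), decreasing = 1, increasing = -1)
  best <- NULL; best_dir <- 1; any_conv <- FALSE
  for (dir in dirs) {
    nll <- make_nll(dir)
    for (i in seq_len(nrow(starts))) {
      par0 <- c(starts$psa[i], log(starts$spread[i]))
      if (!fix_l) par0 <- c(par0, min(0.02, lapse_bounds[2]))
      if (!fix_g) par0 <- c(par0, min(0.02, guess_bounds[2]))
      fit <- tryCatch(
        stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 200L, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (fit$convergence == 0L) any_conv <- TRUE
      if (is.null(best) || fit$value < best$value - 1e-10) {
        best <- fit; best_dir <- dir
      }
    }
  }
  if (is.null(best)) stop("psychometric fit failed at every start",
                          call. = FALSE)

  psa <- best$par[1]; spread <- exp(best$par[2])
  lapse <- if (fix_l) lapse_bounds[1] else best$par[3]
  guess <- if (fix_g) guess_bounds[1] else best$par[[length(best$par)]]
  p_hat <- psy_curve(counts$signed_fov, psa, spread, lapse, guess, best_dir)
  structure(
    list(psa = psa, spread = spread, lapse = lapse, guess = guess,
         direction = best_dir,
         slope_at_psa = best_dir * slope_at_psa(spread, lapse, guess),
         log_lik = -best$value,
         deviance = psy_deviance(counts, p_hat),
         converged = any_conv,
         extreme_psa = abs(psa) > max(abs(counts$signed_fov)),
         mc_p_value = NA_real_, n_mc = 0L,
         lapse_bounds = lapse_bounds, guess_bounds = guess_bounds,
         counts = counts),
    class = "psychometric_fit"
  )
}

validate_counts <- function(counts) {
  if (!is.data.frame(counts) ||
      !all(c("signed_fov", "n", "k") %in% names(counts))) {
    stop("`counts` must have columns signed_fov, n, k", call. = FALSE)
  }
  level_counts(counts$signed_fov, counts$n, counts$k)
}

# linear interpolation of the first 0.5 crossing of the empirical curve;
# falls back to the level closest to proportion 0.5
empirical_crossing <- function(x, prop) {
  for (i in seq_len(length(x) - 1L)) {
    p1 <- prop[i]; p2 <- prop[i + 1L]
    if ((p1 - 0.5) * (p2 - 0.5) <= 0 && p1 != p2) {
      return(x[i] + (0.5 - p1) * (x[i + 1L] - x[i]) / (p2 - p1))
    }
  }
  x[which.min(abs(prop - 0.5))]
}

#' Predicted FTV probabilities of a fit
#' @param fit a `psychometric_fit`.
#' @param signed_fov levels at which to predict (defaults to the fitted
#'   levels).
#' @return Numeric vector of probabilities.
#' @export
predict_p_ftv <- function(fit, signed_fov = fit$counts$signed_fov) {
  stopifnot(inherits(fit, "psychometric_fit"))
  psy_curve(signed_fov, fit$psa, fit$spread, fit$lapse, fit$guess,
            fit$direction)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSA %.2f deg%s, spread %.2f deg, slope %.5f /deg\n",
    x$psa, if (x$extreme_psa) " (extreme)" else "", x$spread,
    x$slope_at_psa))
  cat(sprintf("  lapse %.4f, guess %.4f, deviance %.3f%s\n",
              x$lapse, x$guess, x$deviance,
              if (is.na(x$mc_p_value)) ""
              else sprintf(", MC p = %.3f (n = %d)", x$mc_p_value, x$n_mc)))
  invisible(x)
}

#' Binomial deviance of counts against fitted probabilities
#'
#' `2 * sum_l [ k*ln(k/(n*p)) + (n-k)*ln((n-k)/(n*(1-p))) ]` with the
#' convention `0 * ln(0/x) = 0`; equal to twice the log-likelihood gap
#' between the saturated and the fitted model. A fitted probability of
#' exactly 0 or 1 that disagrees with the counts gives `Inf`.
#'
#' @param counts a `level_counts` table.
#' @param p_hat fitted probabilities per level (same order), or a
#'   `psychometric_fit` whose predictions to use.
#' @return Non-negative deviance (possibly `Inf`).
#' @export
psy_deviance <- function(counts, p_hat) {
  if (inherits(p_hat, "psychometric_fit")) p_hat <- predict_p_ftv(p_hat, counts$signed_fov)
  n <- counts$n; k <- counts$k
  stopifnot(length(p_hat) == length(n))
  term <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  dev <- 2 * sum(term(k, n * p_hat) + term(n - k, n * (1 - p_hat)))
  if (is.nan(dev)) Inf else dev
}

#' Monte-Carlo deviance goodness-of-fit
#'
#' Parametric-bootstrap test of the cumulative-Gaussian fit: simulates
#' `n_sim` binomial datasets from the fitted probabilities at the observed
#' levels and trial numbers, refits each, and reports the fraction of
#' simulated deviances at least as large as the observed one. Refits reuse
#' the fit's lapse/guess configuration with a reduced multistart budget and
#' are seeded per simulation.
#'
#' @param fit a converged `psychometric_fit`.
#' @param n_sim number of simulations (>= 100; classic studies use 10,000).
#' @param seed integer seed.
#' @param refit_starts multistart budget per refit (default 3).
#' @return The input fit with `mc_p_value`, `n_mc`, `mc_failed` (count of
#'   failed refits) filled in; warns if more than 5% of refits failed.
#' @export
mc_goodness_of_fit <- function(fit, n_sim = 10000L, seed = 1L,
                               refit_starts = 3L) {
  stopifnot(inherits(fit, "psychometric_fit"))
  check_scalar(n_sim, "n_sim"); check_scalar(seed, "seed")
  n_sim <- as.integer(n_sim)
  if (n_sim < 100L) stop("`n_sim` must be >= 100", call. = FALSE)
  if (!fit$converged) stop("refusing to test an unconverged fit",
                           call. = FALSE)
  counts <- fit$counts
  p_hat <- predict_p_ftv(fit)
  sim_dev <- rep(NA_real_, n_sim)
  for (s in seq_len(n_sim)) {
    k_s <- with_seed(derive_seed(seed, "mc_gof", s),
                     stats::rbinom(nrow(counts), counts$n, p_hat))
    sim_counts <- level_counts(counts$signed_fov, counts$n, k_s)
    refit <- tryCatch(
      fit_psychometric(sim_counts, lapse_bounds = fit$lapse_bounds,
                       guess_bounds = fit$guess_bounds,
                       n_starts = refit_starts,
                       direction = if (fit$direction > 0) "decreasing"
                                   else "increasing"),
      error = function(e) NULL)
    if (!is.null(refit)) sim_dev[s] <- refit$deviance
  }
  failed <- sum(is.na(sim_dev))
  if (failed > 0.05 * n_sim) {
    warning(sprintf("%d of %d Monte-Carlo refits failed", failed, n_sim))
  }
  # the 1e-9 guard keeps near-zero deviances from being ranked by float noise
  fit$mc_p_value <- mean(sim_dev[!is.na(sim_dev)] >= fit$deviance - 1e-9)
  fit$n_mc <- n_sim
  fit$mc_failed <- failed
  fit
}

#' Pooled (reliability-weighted) psychometric fit across observers
#'
#' Pools observers by likelihood: each observer's per-level counts enter
#' the joint binomial likelihood weighted by `weights` (default 1, i.e.
#' levels contribute in proportion to their trial counts). Equivalent to
#' fitting the weighted sums of `n` and `k` per level.
#'
#' @param counts_list list of `level_counts` tables, one per observer.
#' @param weights optional per-observer non-negative weights.
#' @param ... passed to [fit_psychometric()].
#' @return A `psychometric_fit` of the pooled counts.
#' @export
pooled_fit <- function(counts_list, weights = NULL, ...) {
  if (inherits(counts_list, "level_counts")) counts_list <- list(counts_list)
  if (length(counts_list) < 1L) stop("need at least one observer",
                                     call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(counts_list))
  if (length(weights) != length(counts_list) || any(weights < 0)) {
    stop("`weights` must be non-negative, one per observer", call. = FALSE)
  }
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  weights <- weights / mean(weights)  # overall scale does not alter the MLE
  lev <- sort(unique(unlist(lapply(counts_list, `[[`, "signed_fov"))))
  n <- k <- rep(0, length(lev))
  for (i in seq_along(counts_list)) {
    ci <- validate_counts(counts_list[[i]])
    j <- match(ci$signed_fov, lev)
    n[j] <- n[j] + weights[i] * ci$n
    k[j] <- k[j] + weights[i] * ci$k
  }
  fit_psychometric(level_counts(lev, n, k), ...)
}

#' Parametric-bootstrap confidence interval for the slope at the PSA
#'
#' Resamples binomial data from the fitted model, refits, and returns the
#' percentile interval of the refitted slopes.
#'
#' @param fit a converged `psychometric_fit`.
#' @param n_boot bootstrap draws (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param refit_starts multistart budget per refit (default 3).
#' @return List with `lo`, `hi`, `level`, `slopes` (the bootstrap draws),
#'   `n_failed`.
#' @export
bootstrap_slope_ci <- function(fit, n_boot = 2000L, level = 0.95, seed = 1L,
                               refit_starts = 3L) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("refusing to bootstrap an unconverged fit",
                           call. = FALSE)
  n_boot <- as.integer(n_boot)
  counts <- fit$counts
  p_hat <- predict_p_ftv(fit)
  slopes <- rep(NA_real_, n_boot)
  for (s in seq_len(n_boot)) {
    k_s <- with_seed(derive_seed(seed, "boot_slope", s),
                     stats::rbinom(nrow(counts), counts$n, p_hat))
    refit <- tryCatch(
      fit_psychometric(level_counts(counts$signed_fov, counts$n, k_s),
                       lapse_bounds = fit$lapse_bounds,
                       guess_bounds = fit$guess_bounds,
                       n_starts = refit_starts,
                       direction = if (fit$direction > 0) "decreasing"
                                   else "increasing"),
      error = function(e) NULL)
    if (!is.null(refit)) slopes[s] <- refit$slope_at_psa
  }
  failed <- sum(is.na(slopes))
  if (failed > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", failed, n_boot))
  }
  qs <- stats::quantile(slopes[!is.na(slopes)],
                        c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lo = qs[1], hi = qs[2], level = level, slopes = slopes,
       n_failed = failed)
}
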