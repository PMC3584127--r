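#' Define a synthetic observer
#'
#' An observer is a cumulative-Gaussian psychometric function (probability
#' of a "facing the viewer" response as a function of signed FOV angle)
#' plus a reaction-time model: a second-order polynomial trend in FOV minus
#' a certainty coupling proportional to the |probit| of the response
#' probability, with multiplicative lognormal noise.
#'
#' @param observer_id character id.
#' @param sex_group `"female"` or `"male"`.
#' @param psa point of subjective ambiguity, degrees (mean of the
#'   psychometric Gaussian).
#' @param spread Gaussian spread sigma, degrees (> 0).
#' @param lapse,guess lapse and guess rates in `[0, 0.06]`.
#' @param rt_constant RT polynomial constant, ms (> 0).
#' @param rt_slope RT polynomial slope, ms/degree.
#' @param rt_curvature RT polynomial curvature, ms/degree^2.
#' @param certainty_coupling RT reduction per unit |z| of certainty, ms
#'   (>= 0).
#' @param rt_noise_sigma SD of the lognormal multiplicative RT noise on the
#'   log scale.
#' @param z_clip |z| ceiling for the certainty term (default 3), keeping
#'   certainty finite at saturated levels.
#' @param inverse if `TRUE`, the psychometric curve is mirrored (FTV
#'   probability increases with FOV) — the rare stable "inverse observer"
#'   phenotype.
#' @param seed integer seed for this observer's response stream.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(observer_id, sex_group = c("female", "male"),
                           psa, spread, lapse = 0, guess = 0,
                           rt_constant = 1800, rt_slope = 0,
                           rt_curvature = 0, certainty_coupling = 0,
                           rt_noise_sigma = 0, z_clip = 3, inverse = FALSE,
                           seed = 1L) {
  check_flag(inverse, "inverse")
  sex_group <- match.arg(sex_group)
  for (nm in c("psa", "spread", "lapse", "guess", "rt_constant", "rt_slope",
               "rt_curvature", "certainty_coupling", "rt_noise_sigma",
               "z_clip", "seed")) {
    check_scalar(get(nm), nm)
  }
  if (spread <= 0) stop("`spread` must be > 0", call. = FALSE)
  if (lapse < 0 || lapse > 0.06 || guess < 0 || guess > 0.06) {
    stop("`lapse` and `guess` must lie in [0, 0.06]", call. = FALSE)
  }
  if (rt_constant <= 0) stop("`rt_constant` must be > 0", call. = FALSE)
  if (certainty_coupling < 0) {
    stop("`certainty_coupling` must be >= 0", call. = FALSE)
  }
  if (rt_noise_sigma < 0) stop("`rt_noise_sigma` must be >= 0", call. = FALSE)
  structure(
    list(observer_id = as.character(observer_id), sex_group = sex_group,
         psa = psa, spread = spread, lapse = lapse, guess = guess,
         rt_constant = rt_constant, rt_slope = rt_slope,
         rt_curvature = rt_curvature,
         certainty_coupling = certainty_coupling,
         rt_noise_sigma = rt_noise_sigma, z_clip = z_clip,
         inverse = inverse, seed = as.integer(seed)),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "<observer_model> %s (%s): PSA %.2f deg, spread %.2f deg, slope %.5f /deg\n",
    x$observer_id, x$sex_group, x$psa, x$spread,
    (if (isTRUE(x$inverse)) -1 else 1) *
      slope_at_psa(x$spread, x$lapse, x$guess)))
  invisible(x)
}

#' Probability of a facing-the-viewer response
#'
#' `p = guess + (1 - guess - lapse) * pnorm((psa - fov) / spread)`:
#' strictly decreasing in the signed FOV angle, so negative FOV angles
#' (facing-the-viewer perspective cues) raise the FTV probability.
#'
#' @param signed_fov signed FOV angle(s), degrees. Vectorized.
#' @param model an `observer_model`.
#' @return FTV probability/probabilities.
#' @export
p_ftv <- function(signed_fov, model) {
  stopifnot(inherits(model, "observer_model"))
  s <- if (isTRUE(model$inverse)) -1 else 1
  model$guess + (1 - model$guess - model$lapse) *
    stats::pnorm(s * (model$psa - signed_fov) / model$spread)
}

#' Psychometric slope at the point of subjective ambiguity
#'
#' Derivative of the FTV-probability curve with respect to the FOV angle at
#' the PSA, in proportion per degree:
#' `-(1 - guess - lapse) / (spread * sqrt(2*pi))`.
#'
#' @param spread Gaussian spread, degrees.
#' @param lapse,guess lapse and guess rates.
#' @return Signed slope (proportion/degree); negative for the canonical
#'   decreasing curve.
#' @export
slope_at_psa <- function(spread, lapse = 0, guess = 0) {
  -(1 - guess - lapse) / (spread * sqrt(2 * pi))
}

#' Spread implied by a target slope at the PSA
#'
#' Inverse of [slope_at_psa()]: `spread = (1 - guess - lapse) /
#' (|slope| * sqrt(2*pi))`.
#'
#' @param slope target slope magnitude or signed value (proportion/degree).
#' @param lapse,guess lapse and guess rates.
#' @return Spread in degrees.
#' @export
spread_from_slope <- function(slope, lapse = 0, guess = 0) {
  (1 - guess - lapse) / (abs(slope) * sqrt(2 * pi))
}

# per-level mean RT and certainty of an observer (deterministic part)
mean_rt <- function(signed_fov, model) {
  z <- stats::qnorm(p_ftv(signed_fov, model))
  z <- pmin(pmax(z, -model$z_clip), model$z_clip)
  model$rt_constant + model$rt_slope * signed_fov +
    model$rt_curvature * signed_fov^2 -
    model$certainty_coupling * abs(z)
}

#' Simulate an observer's trials
#'
#' For each scheduled trial, draws a Bernoulli FTV/FA response from the
#' observer's psychometric function and a reaction time as
#' `mean_rt(fov) * exp(noise)` with `mean_rt(fov) = c + b*fov + a*fov^2 -
#' kappa*|z(fov)|`, `z` the probit of the FTV probability clipped at
#' `z_clip`, and `noise ~ Normal(0, rt_noise_sigma)`. Fully reproducible
#' from the observer's seed.
#'
#' @param model an `observer_model`.
#' @param schedule a `trial_schedule` from [build_schedule()].
#' @return A data.frame of trial records: `observer_id`, `sex_group`,
#'   `trial`, `block`, `signed_fov`, `start_phase`, `response`
#'   (`"FTV"`/`"FA"`), `rt` (ms), `is_practice`.
#' @export
simulate_trials <- function(model, schedule) {
  stopifnot(inherits(model, "observer_model"), is.data.frame(schedule))
  fov <- schedule$signed_fov
  mu <- mean_rt(fov, model)
  if (any(mu <= 0)) {
    stop(sprintf(
      "RT model yields non-positive mean RT (%.1f ms) at FOV %.2f deg",
      min(mu), fov[which.min(mu)]), call. = FALSE)
  }
  p <- p_ftv(fov, model)
  n <- length(fov)
  draws <- with_seed(model$seed, {
    resp <- stats::rbinom(n, 1L, p)
    noise <- stats::rnorm(n, 0, model$rt_noise_sigma)
    list(resp = resp, noise = noise)
  })
  data.frame(
    observer_id = model$observer_id,
    sex_group = model$sex_group,
    trial = schedule$trial,
    block = schedule$block,
    signed_fov = fov,
    start_phase = schedule$start_phase,
    response = ifelse(draws$resp == 1L, "FTV", "FA"),
    rt = mu * exp(draws$noise),
    is_practice = schedule$is_practice
  )
}

#' Default cohort calibration
#'
#' Group-level generative distributions for a synthetic cohort. Calibrated
#' once to the canonical group values of the paradigm: mean psychometric
#' slope at the PSA of -0.0068 proportion/degree for male and -0.0034 for
#' female observers, PSA centered on 47.3 degrees (the facing bias: a
#' positive PSA means the orthographic walker is seen as facing the viewer
#' more than half the time), RT constants near 2012 ms (male) and 1780 ms
#' (female), a positive RT slope and negative curvature, and a positive
#' RT-certainty coupling. `flip_prob` is the probability that an observer's
#' psychometric slope is sign-inverted (a stable "inverse" observer),
#' default 1/11 for females and 0 for males.
#'
#' @return Named list with one parameter list per sex group.
#' @export
cohort_defaults <- function() {
  base <- list(
    psa_mean = 47.3, psa_sd = 15,
    slope_mean = NA_real_,       # proportion/degree, magnitude
    slope_rel_sd = 0.25,         # lognormal relative sd of slope magnitude
    lapse_max = 0.04, guess_max = 0.04,
    rt_constant_mean = NA_real_, rt_constant_sd = 250,
    rt_slope_mean = 1.5, rt_slope_sd = 0.5,         # ms/degree
    rt_curvature_mean = -0.020, rt_curvature_sd = 0.008, # ms/degree^2
    certainty_coupling = 150, rt_noise_sigma = 0.25,
    flip_prob = 0
  )
  female <- utils::modifyList(base, list(
    slope_mean = 0.0034, rt_constant_mean = 1780, flip_prob = 1 / 11))
  male <- utils::modifyList(base, list(
    slope_mean = 0.0068, rt_constant_mean = 2012))
  list(female = female, male = male)
}

#' Sample a cohort of synthetic observers
#'
#' Draws `n_per_sex` observers per sex group from the group distributions:
#' PSA normal, slope magnitude lognormal around the group mean (spread
#' derived via [spread_from_slope()]), lapse/guess uniform on
#' `[0, *_max]`, RT constant/slope/curvature normal (constant truncated to
#' stay positive). With probability `flip_prob` an observer is an "inverse"
#' phenotype: its psychometric curve is mirrored so FTV probability
#' increases with FOV. Each observer receives a deterministic seed derived
#' from `seed` and its id.
#'
#' @param n_per_sex observers per sex group (default 11).
#' @param group_params per-group parameter lists, as [cohort_defaults()].
#' @param seed integer master seed for the cohort draw.
#' @return List of `observer_model` objects, females first.
#' @export
sample_cohort <- function(n_per_sex = 11L, group_params = cohort_defaults(),
                          seed = 1L) {
  check_scalar(n_per_sex, "n_per_sex"); check_scalar(seed, "seed")
  n_per_sex <- as.integer(n_per_sex)
  if (n_per_sex < 1L) stop("`n_per_sex` must be >= 1", call. = FALSE)
  for (g in c("female", "male")) {
    gp <- group_params[[g]]
    if (is.null(gp)) stop("missing group parameters for ", g, call. = FALSE)
    if (!is.finite(gp$slope_mean) || gp$slope_mean <= 0 ||
        gp$rt_constant_mean <= 0 || gp$slope_rel_sd < 0) {
      stop("invalid group distribution parameters for ", g, call. = FALSE)
    }
  }
  models <- list()
  for (g in c("female", "male")) {
    gp <- group_params[[g]]
    for (i in seq_len(n_per_sex)) {
      id <- sprintf("%s%02d", substr(g, 1, 1), i)
      obs_seed <- derive_seed(seed, "observer", id)
      par <- with_seed(derive_seed(seed, "cohort_draw", id), {
        sl <- gp$slope_mean *
          stats::rlnorm(1, -gp$slope_rel_sd^2 / 2, gp$slope_rel_sd)
        list(
          psa = stats::rnorm(1, gp$psa_mean, gp$psa_sd),
          lapse = stats::runif(1, 0, gp$lapse_max),
          guess = stats::runif(1, 0, gp$guess_max),
          slope = sl,
          flip = stats::runif(1) < gp$flip_prob,
          rt_c = max(stats::rnorm(1, gp$rt_constant_mean, gp$rt_constant_sd),
                     600),
          rt_b = stats::rnorm(1, gp$rt_slope_mean, gp$rt_slope_sd),
          rt_a = stats::rnorm(1, gp$rt_curvature_mean, gp$rt_curvature_sd)
        )
      })
      m <- observer_model(
        observer_id = id, sex_group = g,
        psa = par$psa,
        spread = spread_from_slope(par$slope, par$lapse, par$guess),
        lapse = par$lapse, guess = par$guess,
        rt_constant = par$rt_c, rt_slope = par$rt_b,
        rt_curvature = par$rt_a,
        certainty_coupling = gp$certainty_coupling,
        rt_noise_sigma = gp$rt_noise_sigma,
        inverse = par$flip,
        seed = obs_seed
      )
      models[[id]] <- m
    }
  }
  models
}
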