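#' Boundary-safe probit transform of a binomial proportion
#'
#' `qnorm((k + 0.5) / (n + 1))`: maps `k = n/2` to exactly 0 and keeps the
#' boundary cases `k = 0` and `k = n` finite. Vectorized.
#'
#' @param k success count(s).
#' @param n trial count(s), > 0.
#' @return z-score(s).
#' @export
#' @examples
#' probit_transform(20, 40)  # 0
#' probit_transform(0, 40)   # finite negative
probit_transform <- function(k, n) {
  if (any(n <= 0)) stop("`n` must be > 0", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  stats::qnorm((k + 0.5) / (n + 1))
}

#' Per-observer, per-level response summaries
#'
#' Collapses trial records to one row per observer x level: FTV proportion,
#' its boundary-safe probit `z_ftv`, and mean/median reaction time.
#' Practice trials are excluded.
#'
#' @param trials data.frame of trial records (columns `observer_id`,
#'   `sex_group`, `signed_fov`, `response`, `rt`, optionally
#'   `is_practice`).
#' @return Data.frame with columns `observer_id`, `sex_group`,
#'   `signed_fov`, `n`, `k`, `prop_ftv`, `z_ftv`, `mean_rt`, `median_rt`.
#' @export
observer_level_summary <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!is.null(trials$is_practice)) trials <- trials[!trials$is_practice, ]
  if (nrow(trials) == 0L) stop("no analysable trials", call. = FALSE)
  key <- interaction(trials$observer_id, trials$signed_fov, drop = TRUE)
  agg <- function(f, v) as.vector(tapply(v, key, f))
  first_chr <- function(v) as.vector(tapply(as.character(v), key, `[`, 1L))
  out <- data.frame(
    observer_id = first_chr(trials$observer_id),
    sex_group = first_chr(trials$sex_group),
    signed_fov = agg(function(v) v[1L], trials$signed_fov),
    n = agg(length, trials$rt),
    k = agg(sum, trials$response == "FTV"),
    mean_rt = agg(mean, trials$rt),
    median_rt = agg(stats::median, trials$rt)
  )
  out$prop_ftv <- out$k / out$n
  out$z_ftv <- probit_transform(out$k, out$n)
  out <- out[order(out$observer_id, out$signed_fov),
             c("observer_id", "sex_group", "signed_fov", "n", "k",
               "prop_ftv", "z_ftv", "mean_rt", "median_rt")]
  rownames(out) <- NULL
  out
}

#' Mixed repeated-measures ANOVA (one within, one between factor)
#'
#' Classical balanced sums-of-squares decomposition for a design with one
#' within-subject factor (`signed_fov` level) and one between-subjects
#' factor (`sex_group`), one observation per observer x level cell. F
#' ratios use the subjects-within-groups stratum for the between effect
#' and the level x subjects-within-groups stratum for the within and
#' interaction effects; no sphericity correction is applied (an option in
#' [gg_correct()]). With 2 groups of 11 observers and 13 levels the df
#' pairs are (1, 20) for sex and (12, 240) for level and the interaction.
#'
#' @param summaries output of [observer_level_summary()] (or any
#'   data.frame with `observer_id`, `sex_group`, `signed_fov`, and the
#'   response variable).
#' @param dv name of the dependent variable column (`"z_ftv"` or
#'   `"mean_rt"`).
#' @return An `anova_table` data.frame with one row per effect
#'   (`between`, `within`, `interaction`, plus the two error strata):
#'   `effect`, `ss`, `df`, `ms`, `f`, `df_error`, `p`.
#' @export
mixed_rm_anova <- function(summaries, dv = "z_ftv") {
  stopifnot(is.data.frame(summaries), dv %in% names(summaries))
  obs <- factor(summaries$observer_id)
  grp <- factor(summaries$sex_group)
  lev <- factor(summaries$signed_fov)
  y <- summaries[[dv]]
  if (anyNA(y)) stop("missing values in the dependent variable",
                     call. = FALSE)
  tab <- table(obs, lev)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "design is not complete/balanced: observer %s has %d observations at level %s",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]),
      call. = FALSE)
  }
  obs_grp <- tapply(as.character(grp), obs, `[`, 1L)
  n_per <- table(factor(obs_grp, levels = levels(grp)))
  if (length(unique(n_per)) != 1L) {
    stop("groups must have equal numbers of observers", call. = FALSE)
  }
  N <- nlevels(obs); G <- nlevels(grp); L <- nlevels(lev)
  grand <- mean(y)
  m_o <- tapply(y, obs, mean)                # per-observer means
  m_g <- tapply(y, grp, mean)                # group means
  m_l <- tapply(y, lev, mean)                # level means
  m_gl <- tapply(y, list(grp, lev), mean)    # cell means
  n_g <- as.integer(n_per[1])

  ss_between_grp <- L * n_g * sum((m_g - grand)^2)
  ss_subj <- L * sum((m_o - m_g[obs_grp])^2)
  ss_level <- N * sum((m_l - grand)^2)
  ss_int <- n_g * sum((m_gl - outer(m_g, rep(1, L)) -
                         outer(rep(1, G), m_l) + grand)^2)
  # residual = y - cell mean - (observer mean - group mean)
  fitted_cell <- m_gl[cbind(as.character(grp), as.character(lev))]
  ss_resid <- sum((y - fitted_cell - (m_o[as.character(obs)] -
                                        m_g[obs_grp[as.character(obs)]]))^2)

  df_grp <- G - 1L
  df_subj <- N - G
  df_level <- L - 1L
  df_int <- (G - 1L) * (L - 1L)
  df_resid <- (L - 1L) * (N - G)

  ms <- c(ss_between_grp / df_grp, ss_subj / df_subj, ss_level / df_level,
          ss_int / df_int, ss_resid / df_resid)
  f_grp <- ms[1] / ms[2]
  f_level <- ms[3] / ms[5]
  f_int <- ms[4] / ms[5]
  p_of <- function(f, d1, d2) {
    if (!is.finite(f)) NA_real_ else stats::pf(f, d1, d2, lower.tail = FALSE)
  }
  out <- data.frame(
    effect = c("between", "subjects_error", "within", "interaction",
               "within_error"),
    ss = c(ss_between_grp, ss_subj, ss_level, ss_int, ss_resid),
    df = c(df_grp, df_subj, df_level, df_int, df_resid),
    ms = ms,
    f = c(f_grp, NA, f_level, f_int, NA),
    df_error = c(df_subj, NA, df_resid, df_resid, NA),
    p = c(p_of(f_grp, df_grp, df_subj), NA,
          p_of(f_level, df_level, df_resid),
          p_of(f_int, df_int, df_resid), NA)
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Greenhouse-Geisser correction for a mixed RM-ANOVA
#'
#' Estimates the sphericity epsilon from the observer x level matrix of
#' the dependent variable and returns the within and interaction rows of
#' the table with epsilon-scaled degrees of freedom and recomputed p
#' values. Off by default in [mixed_rm_anova()], matching reports that use
#' uncorrected dfs.
#'
#' @param summaries as in [mixed_rm_anova()].
#' @param dv dependent-variable column name.
#' @return List with `epsilon` and the corrected `anova_table`.
#' @export
gg_correct <- function(summaries, dv = "z_ftv") {
  tab <- mixed_rm_anova(summaries, dv)
  y <- stats::xtabs(stats::reformulate("observer_id + signed_fov",
                                       response = dv), data = summaries)
  S <- stats::cov(unclass(y))
  L <- ncol(S)
  dbar <- mean(diag(S)); mbar <- mean(S); rowm <- rowMeans(S)
  eps <- (L * (dbar - mbar))^2 /
    ((L - 1) * (sum(S^2) - 2 * L * sum(rowm^2) + L^2 * mbar^2))
  for (e in c("within", "interaction")) {
    i <- tab$effect == e
    tab$p[i] <- stats::pf(tab$f[i], eps * tab$df[i],
                          eps * tab$df_error[i], lower.tail = FALSE)
  }
  list(epsilon = eps, table = tab)
}

#' Per-observer second-order polynomial fit of reaction times
#'
#' Ordinary least squares of the per-level mean RT on the signed FOV angle
#' and its square: `rt = constant + slope*fov + curvature*fov^2`.
#'
#' @param signed_fov stimulus levels, degrees (>= 3 distinct values).
#' @param rt reaction times, ms (same length).
#' @return List with `constant` (ms), `slope` (ms/degree), `curvature`
#'   (ms/degree^2).
#' @export
fit_rt_polynomial <- function(signed_fov, rt) {
  if (length(unique(signed_fov)) < 3L) {
    stop("need >= 3 distinct levels for a quadratic fit", call. = FALSE)
  }
  fit <- stats::lm(rt ~ signed_fov + I(signed_fov^2))
  co <- stats::coef(fit)
  if (anyNA(co)) stop("rank-deficient RT polynomial fit", call. = FALSE)
  list(constant = unname(co[1]), slope = unname(co[2]),
       curvature = unname(co[3]))
}

#' RT polynomial coefficients for every observer
#'
#' Fits [fit_rt_polynomial()] to each observer's per-level mean RTs.
#'
#' @param summaries output of [observer_level_summary()].
#' @return Data.frame with `observer_id`, `sex_group`, `constant`,
#'   `slope`, `curvature`.
#' @export
rt_poly_table <- function(summaries) {
  ids <- unique(summaries$observer_id)
  rows <- lapply(ids, function(id) {
    d <- summaries[summaries$observer_id == id, ]
    co <- fit_rt_polynomial(d$signed_fov, d$mean_rt)
    data.frame(observer_id = id, sex_group = d$sex_group[1],
               constant = co$constant, slope = co$slope,
               curvature = co$curvature)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' t-tests on RT polynomial coefficients
#'
#' For each coefficient (constant, slope, curvature): a one-sample t-test
#' across all observers against zero, a Welch two-sample test between sex
#' groups, and a paired-by-rank variant in which the two groups' sorted
#' coefficient vectors are paired (df = n_per_group - 1, the convention
#' that yields t(10) with 11 observers per group).
#'
#' @param fits output of [rt_poly_table()].
#' @return Data.frame with `coefficient`, `test`, `estimate`, `t`, `df`,
#'   `p`. Degenerate cases (zero variance) yield `NA` statistics.
#' @export
group_ttests <- function(fits) {
  stopifnot(all(c("sex_group", "constant", "slope", "curvature") %in%
                  names(fits)))
  res <- list()
  safe_t <- function(expr) {
    tryCatch(expr, error = function(e) list(statistic = NA_real_,
                                            parameter = NA_real_,
                                            p.value = NA_real_))
  }
  for (co in c("constant", "slope", "curvature")) {
    v <- fits[[co]]
    f <- v[fits$sex_group == "female"]
    m <- v[fits$sex_group == "male"]
    one <- if (stats::sd(v) == 0) {
      # degenerate: all coefficients identical
      list(statistic = if (mean(v) == 0) 0 else sign(mean(v)) * Inf,
           parameter = length(v) - 1L,
           p.value = if (mean(v) == 0) 1 else 0)
    } else safe_t(stats::t.test(v, mu = 0))
    res[[length(res) + 1L]] <- data.frame(
      coefficient = co, test = "one_sample", estimate = mean(v),
      t = unname(one$statistic), df = unname(one$parameter),
      p = one$p.value)
    two <- safe_t(stats::t.test(m, f))
    res[[length(res) + 1L]] <- data.frame(
      coefficient = co, test = "two_sample", estimate = mean(m) - mean(f),
      t = unname(two$statistic), df = unname(two$parameter),
      p = two$p.value)
    if (length(f) == length(m) && length(f) >= 2L) {
      pr <- safe_t(stats::t.test(sort(m), sort(f), paired = TRUE))
      res[[length(res) + 1L]] <- data.frame(
        coefficient = co, test = "paired_by_rank",
        estimate = mean(m) - mean(f),
        t = unname(pr$statistic), df = unname(pr$parameter),
        p = pr$p.value)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spearman correlation between reaction time and response certainty
#'
#' Certainty is the absolute probit of the FTV proportion per observer x
#' level cell; proportions near 0.5 mean high uncertainty (|z| near 0).
#' Average ranks are used for ties; the p value comes from the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param summaries output of [observer_level_summary()].
#' @return List with `rho`, `df` (n - 2), `p`, `n`.
#' @export
spearman_rt_certainty <- function(summaries) {
  x <- abs(summaries$z_ftv)
  y <- summaries$mean_rt
  n <- length(x)
  if (n < 3L) stop("need at least 3 cells", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, df = n - 2L,
       p = 2 * stats::pt(-abs(tt), n - 2L), n = n)
}

#' Notched boxplot summary statistics
#'
#' Quartiles by linear interpolation (type-7 quantiles), whiskers at the
#' most extreme observations within 1.5 IQR of the box edges, points
#' beyond listed as outliers, and the notch (a 95% interval around the
#' median) at `median +/- 1.57 * IQR / sqrt(n)`.
#'
#' @param values numeric vector, `n >= 1`.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `notch_lo`, `notch_hi`, `outliers`, `n`.
#' @export
#' @examples
#' boxplot_stats(1:7)
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    notch_lo = q[2] - 1.57 * iqr / sqrt(n),
    notch_hi = q[2] + 1.57 * iqr / sqrt(n),
    outliers = sort(values[values < lo_fence | values > hi_fence]),
    n = n
  )
}
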