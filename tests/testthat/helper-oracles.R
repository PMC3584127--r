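# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the projection oracle solves the ray/plane
# intersection explicitly, the ANOVA oracle goes through stats::aov error
# strata, the likelihood oracle uses dbinom.

# central projection of a single 3D point by explicit ray/plane
# intersection: convergence point C on the depth axis at signed depth
# z_c relative to the projection plane z = 0
ray_project_oracle <- function(xyz, z_c) {
  # ray: C + t * (P - C) with C = (0, 0, z_c); the z component hits the
  # plane z = 0 at t = z_c / (z_c - z), where the x/y components are t*(x, y)
  t <- z_c / (z_c - xyz[3])
  c(t * xyz[1], t * xyz[2])
}

# mixed RM-ANOVA through aov() error strata (between: Error(observer);
# within + interaction: the observer:level stratum)
aov_oracle <- function(summaries, dv) {
  d <- data.frame(
    y = summaries[[dv]],
    obs = factor(summaries$observer_id),
    grp = factor(summaries$sex_group),
    lev = factor(summaries$signed_fov)
  )
  fit <- stats::aov(y ~ grp * lev + Error(obs / lev), data = d)
  s <- summary(fit)
  between <- s[["Error: obs"]][[1]]
  within <- s[["Error: obs:lev"]][[1]]
  clean <- function(tab) {
    rn <- trimws(rownames(tab))
    stats::setNames(
      lapply(seq_len(nrow(tab)), function(i) {
        list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
             f = if ("F value" %in% colnames(tab)) tab[i, "F value"] else NA)
      }), rn)
  }
  list(between = clean(between), within = clean(within))
}

# small balanced summaries fixture: g groups x l levels x n observers per
# group, one value per cell
make_summary_fixture <- function(n_per_group = 4, n_levels = 3, seed = 42,
                                 dv_fun = NULL) {
  set.seed(seed)
  levels <- seq(-30, 30, length.out = n_levels)
  rows <- list()
  for (g in c("female", "male")) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s%02d", substr(g, 1, 1), i)
      for (l in levels) {
        y <- if (is.null(dv_fun)) rnorm(1) else dv_fun(g, i, l)
        rows[[length(rows) + 1L]] <- data.frame(
          observer_id = id, sex_group = g, signed_fov = l, z_ftv = y,
          mean_rt = 1800 + y)
      }
    }
  }
  do.call(rbind, rows)
}

# counts simulated from a known decreasing cumulative-Gaussian observer
simulate_counts <- function(psa, spread, levels, n_per_level, seed,
                            lapse = 0, guess = 0) {
  p <- guess + (1 - guess - lapse) * pnorm((psa - levels) / spread)
  set.seed(seed)
  level_counts(levels, rep(n_per_level, length(levels)),
               rbinom(length(levels), n_per_level, p))
}
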