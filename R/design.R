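#' Build a randomized trial schedule
#'
#' Expands the full factorial list of `length(levels) * reps` trials,
#' permutes it uniformly at random, partitions it into consecutive blocks
#' of `block_size`, and draws each trial's gait start phase uniformly from
#' the integer frame grid `0 .. cycle_frames - 1`. The permutation is
#' global: blocks are rest pauses, not per-level strata. With `practice =
#' TRUE` a single familiarization block of `block_size` trials is drawn
#' instead, levels sampled uniformly with replacement.
#'
#' @param levels numeric vector of signed FOV levels (degrees).
#' @param reps repetitions per level (default 40).
#' @param block_size trials per block (default 40); `reps * length(levels)`
#'   must be divisible by it.
#' @param seed integer seed; required, for reproducibility.
#' @param cycle_frames frames per gait cycle (default 117) — the start
#'   phase grid.
#' @param practice generate a practice block instead of the main schedule.
#' @return A `trial_schedule` data.frame with columns `trial`, `block`,
#'   `signed_fov`, `start_phase` (frame index), `is_practice`, and
#'   attributes `n_levels`, `reps`, `block_size`, `seed`.
#' @export
#' @examples
#' sched <- build_schedule(default_levels(), reps = 40, seed = 1)
#' nrow(sched)           # 520
#' max(sched$block)      # 13
build_schedule <- function(levels, reps = 40L, block_size = 40L, seed,
                           cycle_frames = 117L, practice = FALSE) {
  if (length(levels) < 1L || anyNA(levels) || any(!is.finite(levels))) {
    stop("`levels` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (anyDuplicated(levels)) stop("`levels` must be distinct", call. = FALSE)
  check_scalar(reps, "reps"); check_scalar(block_size, "block_size")
  check_scalar(cycle_frames, "cycle_frames")
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_scalar(seed, "seed")
  check_flag(practice, "practice")
  reps <- as.integer(reps); block_size <- as.integer(block_size)

  if (practice) {
    n <- block_size
    fovs <- with_seed(seed, sample(levels, n, replace = TRUE))
  } else {
    n <- length(levels) * reps
    if (n %% block_size != 0L) {
      stop(sprintf(
        "trial count %d is not divisible into blocks of %d", n, block_size),
        call. = FALSE)
    }
    full <- rep(levels, each = reps)
    fovs <- with_seed(seed, sample(full, n, replace = FALSE))
  }
  phases <- with_seed(derive_seed(seed, "start_phase"),
                      sample.int(cycle_frames, n, replace = TRUE) - 1L)
  out <- data.frame(
    trial = seq_len(n),
    block = if (practice) 0L else rep(seq_len(n %/% block_size),
                                      each = block_size),
    signed_fov = fovs,
    start_phase = phases,
    is_practice = practice
  )
  attr(out, "n_levels") <- length(levels)
  attr(out, "reps") <- reps
  attr(out, "block_size") <- block_size
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Write a trial schedule to CSV
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}
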