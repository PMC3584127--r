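#' @section Coordinate convention:
#' Throughout the package, x is lateral, y is vertical, z is depth toward
#' the viewer; right-handed, origin at the pelvis mean position; all lengths
#' in walker-height units unless stated otherwise.
#' @name facingbias-conventions
#' @keywords internal
NULL

#' The 15 anatomical point-light markers, in canonical order
#' @export
MARKER_NAMES <- c(
  "head", "sternum", "pelvis",
  "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_wrist", "r_wrist",
  "l_hip", "r_hip", "l_knee", "r_knee", "l_ankle", "r_ankle"
)

AXIS_NAMES <- c("x", "y", "z")
N_MARKERS <- 15L
N_HARMONICS <- 2L

#' Construct gait parameters for a 15-marker point-light walker
#'
#' A walker trajectory is, per marker and axis, a mean position plus up to
#' two harmonics of the gait cycle: `mean + sum_k amp[k] * sin(k*theta +
#' phase[k])` with `theta = 2*pi*t/cycle_frames + start_phase`. The marker
#' set is fixed at the standard 15 anatomical points; contralateral limb
#' markers must mirror each other with a half-cycle phase offset.
#'
#' @param mean numeric 15 x 3 matrix of mean positions (rows in
#'   [MARKER_NAMES] order, columns x/y/z), walker-height units.
#' @param amp numeric 15 x 3 x 2 array of harmonic amplitudes
#'   (marker x axis x harmonic order).
#' @param phase numeric 15 x 3 x 2 array of harmonic phases, radians.
#' @param cycle_frames frames per gait cycle (default 117).
#' @param normalize if `TRUE` (default) rescale so the mean-pose vertical
#'   extent (head to lowest ankle) is exactly 1.
#' @return An object of class `gait_parameters`.
#' @seealso [default_gait()], [synthesize_walker()]
#' @export
gait_parameters <- function(mean, amp, phase, cycle_frames = 117L,
                            normalize = TRUE) {
  mean <- as.matrix(mean)
  if (!all(dim(mean) == c(N_MARKERS, 3L))) {
    stop("`mean` must be a 15 x 3 matrix", call. = FALSE)
  }
  if (!all(dim(amp) == c(N_MARKERS, 3L, N_HARMONICS)) ||
      !all(dim(phase) == c(N_MARKERS, 3L, N_HARMONICS))) {
    stop("`amp` and `phase` must be 15 x 3 x 2 arrays", call. = FALSE)
  }
  if (!all(is.finite(mean)) || !all(is.finite(amp)) || !all(is.finite(phase))) {
    stop("gait parameters must be finite", call. = FALSE)
  }
  check_scalar(cycle_frames, "cycle_frames")
  cycle_frames <- as.integer(cycle_frames)
  if (cycle_frames < 2L) stop("`cycle_frames` must be >= 2", call. = FALSE)
  dimnames(mean) <- list(MARKER_NAMES, AXIS_NAMES)
  dimnames(amp) <- dimnames(phase) <-
    list(MARKER_NAMES, AXIS_NAMES, paste0("h", seq_len(N_HARMONICS)))
  p <- structure(
    list(mean = mean, amp = amp, phase = phase,
         cycle_frames = cycle_frames, height = 1.0),
    class = "gait_parameters"
  )
  if (normalize) p <- normalize_gait(p)
  p
}

# vertical extent of the mean pose (head-to-lowest-marker span)
mean_pose_extent <- function(mean) {
  diff(range(mean[, "y"]))
}

normalize_gait <- function(params) {
  ext <- mean_pose_extent(params$mean)
  if (ext <= .Machine$double.eps) {
    stop("degenerate figure: mean pose has zero vertical extent", call. = FALSE)
  }
  params$mean <- params$mean / ext
  params$amp <- params$amp / ext
  params
}

# Build the left-side marker parameters from the right-side ones so that
# x_L(theta) = -x_R(theta + pi) and (y,z)_L(theta) = (y,z)_R(theta + pi):
# the half-cycle, laterally mirrored contralateral relation.
mirror_contralateral <- function(mean_r, amp_r, phase_r) {
  mean_l <- mean_r * c(-1, 1, 1)
  amp_l <- amp_r
  phase_l <- phase_r
  for (k in seq_len(N_HARMONICS)) {
    # shifting theta by pi adds k*pi to harmonic k's phase
    phase_l[, k] <- phase_r[, k] + k * pi
    # mirroring x negates the amplitude; fold the sign into a pi phase shift
    phase_l[1L, k] <- phase_l[1L, k] + pi
  }
  list(mean = mean_l, amp = amp_l, phase = phase_l %% (2 * pi))
}

#' Default parametric gender-neutral walker
#'
#' A hand-tuned, anatomically plausible treadmill (walking-in-place) gait:
#' leg and arm swing at the fundamental of the gait cycle with arms in
#' antiphase to the ipsilateral leg, vertical bounce of the trunk at the
#' second harmonic, and exact bilateral symmetry (left markers are the
#' mirrored, half-cycle-shifted copies of the right markers). Normalized to
#' unit mean-pose height. It stands in for a motion-capture-derived neutral
#' walker; the downstream geometry and statistics are independent of the
#' exact gait coefficients.
#'
#' @param cycle_frames frames per gait cycle (default 117).
#' @return A `gait_parameters` object.
#' @export
#' @examples
#' g <- default_gait()
#' seq0 <- synthesize_walker(g, start_phase = 0)
#' dim(seq0$coordinates)
default_gait <- function(cycle_frames = 117L) {
  mean <- matrix(0, N_MARKERS, 3L, dimnames = list(MARKER_NAMES, AXIS_NAMES))
  amp <- array(0, c(N_MARKERS, 3L, N_HARMONICS))
  phase <- array(0, c(N_MARKERS, 3L, N_HARMONICS))
  dimnames(amp) <- dimnames(phase) <-
    list(MARKER_NAMES, AXIS_NAMES, c("h1", "h2"))

  set_mean <- function(m, v) mean[m, ] <<- v
  set_h <- function(m, axis, k, a, ph) {
    amp[m, axis, k] <<- a
    phase[m, axis, k] <<- ph
  }

  # axial markers (pre-normalization units; pelvis at the origin)
  set_mean("head",    c(0, 0.72, 0))
  set_mean("sternum", c(0, 0.45, 0))
  set_mean("pelvis",  c(0, 0.00, 0))
  # trunk bounce: twice per cycle (once per step)
  for (m in c("head", "sternum", "pelvis")) set_h(m, "y", 2L, 0.020, 0)
  # gentle lateral sway once per cycle
  for (m in c("head", "sternum", "pelvis")) set_h(m, "x", 1L, 0.015, 0)

  # right-side limb markers; left side is derived below
  right <- c("r_shoulder", "r_elbow", "r_wrist", "r_hip", "r_knee", "r_ankle")
  set_mean("r_shoulder", c(0.18, 0.52, 0))
  set_mean("r_elbow",    c(0.23, 0.28, 0))
  set_mean("r_wrist",    c(0.25, 0.05, 0))
  set_mean("r_hip",      c(0.09, -0.02, 0))
  set_mean("r_knee",     c(0.10, -0.45, 0))
  set_mean("r_ankle",    c(0.11, -0.88, 0))
  # leg swing (depth axis), fundamental; right leg at phase 0
  set_h("r_hip",   "z", 1L, 0.040, 0)
  set_h("r_knee",  "z", 1L, 0.220, 0)
  set_h("r_ankle", "z", 1L, 0.350, 0)
  # foot/knee lift while swinging, second harmonic
  set_h("r_knee",  "y", 2L, 0.035, pi / 2)
  set_h("r_ankle", "y", 2L, 0.060, pi / 2)
  # arm swing in antiphase with the ipsilateral leg
  set_h("r_shoulder", "z", 1L, 0.030, pi)
  set_h("r_elbow",    "z", 1L, 0.110, pi)
  set_h("r_wrist",    "z", 1L, 0.190, pi)
  # slight elbow flexion twice per cycle
  set_h("r_wrist", "y", 2L, 0.025, 0)

  for (m in right) {
    l <- sub("^r_", "l_", m)
    parts <- mirror_contralateral(mean[m, ], amp[m, , ], phase[m, , ])
    mean[l, ] <- parts$mean
    amp[l, , ] <- parts$amp
    phase[l, , ] <- parts$phase
  }

  gait_parameters(mean, amp, phase, cycle_frames = cycle_frames)
}

#' Synthesize one (or more) gait cycles of 3D marker motion
#'
#' Evaluates each marker's mean-plus-harmonics trajectory on the frame grid
#' `theta_t = 2*pi*t/cycle_frames + start_phase`, `t = 0, ...,
#' n_cycles*cycle_frames - 1`.
#'
#' @param params a [gait_parameters()] object.
#' @param start_phase starting phase in radians, in `[0, 2*pi)` (values
#'   outside are wrapped).
#' @param n_cycles number of full cycles to synthesize (default 1).
#' @return A `motion_sequence`: list with `coordinates` (frames x 15 x 3
#'   array), `cycle_frames`, and `start_phase`.
#' @export
synthesize_walker <- function(params, start_phase = 0, n_cycles = 1L) {
  if (!inherits(params, "gait_parameters")) {
    stop("`params` must be a `gait_parameters` object", call. = FALSE)
  }
  check_scalar(start_phase, "start_phase")
  start_phase <- start_phase %% (2 * pi)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1", call. = FALSE)

  nf <- params$cycle_frames * n_cycles
  theta <- 2 * pi * (seq_len(nf) - 1L) / params$cycle_frames + start_phase
  coords <- array(0, c(nf, N_MARKERS, 3L),
                  dimnames = list(NULL, MARKER_NAMES, AXIS_NAMES))
  for (ax in 1:3) {
    # frames x markers: mean + sum_k amp_k sin(k theta + phase_k)
    v <- matrix(params$mean[, ax], nf, N_MARKERS, byrow = TRUE)
    for (k in seq_len(N_HARMONICS)) {
      arg <- outer(k * theta, params$phase[, ax, k], `+`)
      v <- v + sin(arg) * matrix(params$amp[, ax, k], nf, N_MARKERS,
                                 byrow = TRUE)
    }
    coords[, , ax] <- v
  }
  structure(
    list(coordinates = coords, cycle_frames = params$cycle_frames,
         start_phase = start_phase),
    class = "motion_sequence"
  )
}

#' Rescale a motion sequence to unit mean-pose height
#'
#' Uniformly scales all coordinates so that the vertical extent of the mean
#' pose (coordinates averaged over frames) is exactly 1. Idempotent and
#' scale-invariant.
#'
#' @param seq a `motion_sequence`.
#' @return The rescaled `motion_sequence`.
#' @export
normalize_height <- function(seq) {
  stopifnot(inherits(seq, "motion_sequence"))
  mean_pose <- apply(seq$coordinates, c(2, 3), mean)
  ext <- diff(range(mean_pose[, "y"]))
  if (!is.finite(ext) || ext <= .Machine$double.eps) {
    stop("degenerate figure: zero vertical extent", call. = FALSE)
  }
  seq$coordinates <- seq$coordinates / ext
  seq
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat("<gait_parameters> 15 markers,", x$cycle_frames, "frames/cycle,",
      "mean-pose height", format(mean_pose_extent(x$mean)), "\n")
  invisible(x)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("<motion_sequence>", dim(x$coordinates)[1], "frames x 15 markers,",
      "start phase", format(x$start_phase, digits = 4), "rad\n")
  invisible(x)
}

#' Write / read gait parameters as JSON
#'
#' @param params a `gait_parameters` object.
#' @param path file path.
#' @return `write_gait_json` returns `path` invisibly; `read_gait_json`
#'   returns a `gait_parameters` object.
#' @export
write_gait_json <- function(params, path) {
  stopifnot(inherits(params, "gait_parameters"))
  markers <- lapply(seq_len(N_MARKERS), function(i) {
    list(
      name = MARKER_NAMES[i],
      mean = unname(params$mean[i, ]),
      harmonics = lapply(seq_len(N_HARMONICS), function(k) {
        list(order = k,
             amp = unname(params$amp[i, , k]),
             phase = unname(params$phase[i, , k]))
      })
    )
  })
  obj <- list(
    convention = "x lateral, y vertical, z depth toward viewer; origin at pelvis mean; walker-height units",
    cycle_frames = params$cycle_frames,
    markers = markers
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gait_json
#' @export
read_gait_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- obj$markers
  mean <- matrix(0, N_MARKERS, 3L)
  amp <- array(0, c(N_MARKERS, 3L, N_HARMONICS))
  phase <- array(0, c(N_MARKERS, 3L, N_HARMONICS))
  for (i in seq_len(nrow(mk))) {
    j <- match(mk$name[i], MARKER_NAMES)
    if (is.na(j)) stop("unknown marker name: ", mk$name[i], call. = FALSE)
    mean[j, ] <- mk$mean[[i]]
    h <- mk$harmonics[[i]]
    for (r in seq_len(nrow(h))) {
      k <- h$order[r]
      amp[j, , k] <- h$amp[[r]]
      phase[j, , k] <- h$phase[[r]]
    }
  }
  gait_parameters(mean, amp, phase, cycle_frames = obj$cycle_frames,
                  normalize = FALSE)
}

#' Export a motion sequence as a tidy CSV
#'
#' One row per (frame, marker) with columns `frame`, `marker`, `x`, `y`,
#' `z`. Frames are 0-based.
#'
#' @param seq a `motion_sequence`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(seq, path) {
  stopifnot(inherits(seq, "motion_sequence"))
  nf <- dim(seq$coordinates)[1]
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = N_MARKERS),
    marker = rep(MARKER_NAMES, each = nf),
    x = as.vector(seq$coordinates[, , 1]),
    y = as.vector(seq$coordinates[, , 2]),
    z = as.vector(seq$coordinates[, , 3])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
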