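#' Field-of-view angle from convergence-point distance
#'
#' The field-of-view (FOV) angle of a central projection whose convergence
#' point sits `distance_ratio` walker heights from the projection plane,
#' with a projection window `window_ratio` walker heights tall:
#' `fov = 2 * atan((window_ratio/2) / distance_ratio)` in degrees.
#' `Inf` distance gives the orthographic limit, 0 degrees. With the default
#' window of 4 walker heights, distances of 16, 8, 6, 4, 3 and 2 heights
#' give FOV angles rounding to 14, 28, 37, 53, 67 and 90 degrees.
#'
#' @param distance_ratio convergence-point distance in walker heights
#'   (positive, possibly `Inf`). Vectorized.
#' @param window_ratio projection-window height in walker heights
#'   (default 4).
#' @return FOV angle(s) in degrees.
#' @export
#' @examples
#' fov_from_distance(c(16, 8, 6, 4, 3, 2))
fov_from_distance <- function(distance_ratio, window_ratio = 4) {
  check_scalar(window_ratio, "window_ratio")
  if (window_ratio <= 0) stop("`window_ratio` must be > 0", call. = FALSE)
  if (any(!is.nan(distance_ratio) & distance_ratio <= 0)) {
    stop("`distance_ratio` must be > 0 (or Inf for orthographic)",
         call. = FALSE)
  }
  ifelse(is.infinite(distance_ratio), 0,
         2 * atan((window_ratio / 2) / distance_ratio) * 180 / pi)
}

#' Convergence-point distance from field-of-view angle
#'
#' Exact inverse of [fov_from_distance()] on (0, 180) degrees.
#'
#' @param fov FOV angle in degrees, in (0, 180). Vectorized.
#' @param window_ratio projection-window height in walker heights.
#' @return Distance(s) in walker heights.
#' @export
distance_from_fov <- function(fov, window_ratio = 4) {
  check_scalar(window_ratio, "window_ratio")
  if (window_ratio <= 0) stop("`window_ratio` must be > 0", call. = FALSE)
  if (any(fov <= 0 | fov >= 180)) {
    stop("`fov` must lie strictly between 0 and 180 degrees", call. = FALSE)
  }
  (window_ratio / 2) / tan(fov * pi / 360)
}

#' Visual angle subtended by a physical extent
#'
#' @param physical_extent extent in cm (or any length unit).
#' @param viewing_distance distance in the same unit.
#' @return Angle in degrees: `2 * atan(extent / (2 * distance))`.
#' @export
#' @examples
#' angular_size(6.97, 57) # about 7 degrees
angular_size <- function(physical_extent, viewing_distance) {
  if (any(physical_extent <= 0) || any(viewing_distance <= 0)) {
    stop("arguments must be positive", call. = FALSE)
  }
  2 * atan(physical_extent / (2 * viewing_distance)) * 180 / pi
}

#' Define one perspective level
#'
#' A projection level is identified by a signed field-of-view angle:
#' negative values put the convergence point on the far side of the walker
#' (perspective cues consistent with a figure facing the viewer), positive
#' values on the viewer's side (cues consistent with facing away), and 0 is
#' the orthographic, perfectly depth-ambiguous projection. Dot size is
#' carried along as metadata only: it is constant across levels and never
#' enters the projection.
#'
#' @param signed_fov signed FOV angle in degrees, in (-180, 180).
#' @param window_ratio projection-window height in walker heights
#'   (default 4).
#' @param dot_radius dot radius in arcmin (default 15; constant by design).
#' @return An object of class `projection_spec` with fields `signed_fov`,
#'   `distance_ratio` (`Inf` when orthographic), `window_ratio`,
#'   `dot_radius`.
#' @export
projection_spec <- function(signed_fov, window_ratio = 4, dot_radius = 15) {
  check_scalar(signed_fov, "signed_fov")
  if (abs(signed_fov) >= 180) {
    stop("`signed_fov` must lie in (-180, 180)", call. = FALSE)
  }
  d <- if (signed_fov == 0) Inf else distance_from_fov(abs(signed_fov),
                                                       window_ratio)
  structure(
    list(signed_fov = signed_fov, distance_ratio = d,
         window_ratio = window_ratio, dot_radius = dot_radius),
    class = "projection_spec"
  )
}

#' @export
print.projection_spec <- function(x, ...) {
  cat(sprintf(
    "<projection_spec> signed FOV %+.2f deg (D = %s walker heights), dots %g arcmin\n",
    x$signed_fov, format(x$distance_ratio, digits = 5), x$dot_radius))
  invisible(x)
}

#' Project a 3D walker to 2D dot positions
#'
#' Central projection onto the frontoparallel plane through the walker's
#' depth midpoint. The convergence point lies on the depth axis at distance
#' `D = distance_from_fov(|signed_fov|)` walker heights from that plane: on
#' the viewer's side (+z) for positive `signed_fov`, on the far side for
#' negative, giving the mirror-antisymmetric pair of cue patterns that
#' makes the facing-the-viewer/facing-away ambiguity. `signed_fov = 0`
#' drops the depth axis (orthographic). Dot radius is not scaled — the
#' projected pattern alone carries the perspective information.
#'
#' @param seq a `motion_sequence` from [synthesize_walker()].
#' @param spec a [projection_spec()].
#' @return A `stimulus_2d`: list with `positions` (frames x 15 x 2 array of
#'   x/y in walker-height units on the projection plane), `dot_radius`, and
#'   `spec`.
#' @export
project <- function(seq, spec) {
  stopifnot(inherits(seq, "motion_sequence"),
            inherits(spec, "projection_spec"))
  co <- seq$coordinates
  z <- co[, , 3, drop = FALSE]
  zmid <- (max(z) + min(z)) / 2
  dz <- co[, , 3] - zmid
  if (spec$signed_fov == 0) {
    scale <- matrix(1, dim(co)[1], dim(co)[2])
  } else {
    D <- spec$distance_ratio
    # signed depth of each marker toward the convergence point
    toward <- if (spec$signed_fov > 0) dz else -dz
    bad <- which(toward >= D, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "marker '%s' at frame %d lies at or behind the convergence point (D = %.3f walker heights)",
        MARKER_NAMES[bad[1, 2]], bad[1, 1], D), call. = FALSE)
    }
    scale <- D / (D - toward)
  }
  pos <- array(0, c(dim(co)[1], N_MARKERS, 2L),
               dimnames = list(NULL, MARKER_NAMES, c("x", "y")))
  pos[, , 1] <- co[, , 1] * scale
  pos[, , 2] <- co[, , 2] * scale
  structure(list(positions = pos, dot_radius = spec$dot_radius, spec = spec),
            class = "stimulus_2d")
}

#' @export
print.stimulus_2d <- function(x, ...) {
  cat("<stimulus_2d>", dim(x$positions)[1], "frames x 15 dots, signed FOV",
      sprintf("%+.2f", x$spec$signed_fov), "deg\n")
  invisible(x)
}

#' Export a 2D stimulus as CSV plus a JSON sidecar
#'
#' Writes dot positions (`frame`, `marker`, `x`, `y`; frames 0-based) to
#' `path` and the projection spec and conventions to `<path>.json`.
#'
#' @param stim a `stimulus_2d`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_2d"))
  nf <- dim(stim$positions)[1]
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = N_MARKERS),
    marker = rep(MARKER_NAMES, each = nf),
    x = as.vector(stim$positions[, , 1]),
    y = as.vector(stim$positions[, , 2])
  )
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    signed_fov = stim$spec$signed_fov,
    distance_ratio = if (is.infinite(stim$spec$distance_ratio)) "Inf"
                     else stim$spec$distance_ratio,
    window_ratio = stim$spec$window_ratio,
    dot_radius_arcmin = stim$spec$dot_radius,
    convention = "x lateral, y vertical, walker-height units on the projection plane; negative signed_fov cues facing-the-viewer"
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' The 13 signed perspective levels of the standard design
#'
#' Six convergence distances (16, 8, 6, 4, 3, 2 walker heights) on each
#' side of the walker plus the orthographic projection, expressed as signed
#' FOV angles in degrees (negative = facing-the-viewer cues), sorted
#' ascending.
#'
#' @param distances convergence distances in walker heights used on each
#'   side (default `c(16, 8, 6, 4, 3, 2)`).
#' @param window_ratio projection-window height in walker heights.
#' @return Numeric vector of 2 * length(distances) + 1 signed FOV degrees.
#' @export
#' @examples
#' round(default_levels())
default_levels <- function(distances = c(16, 8, 6, 4, 3, 2),
                           window_ratio = 4) {
  fov <- fov_from_distance(distances, window_ratio)
  sort(c(-fov, 0, fov))
}
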