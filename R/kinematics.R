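#' Savitzky-Golay smoothing and differentiation of a tip trajectory
#'
#' Fits a local least-squares polynomial of order `polyorder` in a
#' centred window of `window_length` samples and evaluates it (and its
#' first three derivatives) at the window centre. Derivatives are scaled
#' by the true sample period, so units are mm, mm/s, mm/s^2, mm/s^3.
#'
#' Edge handling is shrink-to-valid: a sample is valid only when its
#' centred window lies entirely inside one contiguous in-view run, so
#' boundary artefacts cannot leak into downstream averages (jerk in
#' particular). In-view runs shorter than the window are fully masked.
#'
#' @param track An [instrument_track()].
#' @param window_length Odd window length in samples (> `polyorder`).
#' @param polyorder Polynomial order (>= 3 for a non-trivial jerk).
#' @return An object of class `kinematic_series`: list with `timestamps`,
#'   `position` (n x 3, smoothed), `deriv1`..`deriv3` (n x 3),
#'   `valid_mask`, `sample_rate`, `instrument_id`, `port_position`, and
#'   the raw `attitude`, `gripper_angle`, `in_view` channels carried
#'   through for the metric layer.
#' @export
savgol_smooth <- function(track, window_length = 21L, polyorder = 3L) {
  window_length <- as.integer(window_length)
  polyorder <- as.integer(polyorder)
  if (window_length %% 2L != 1L || window_length <= polyorder) {
    stop("configuration error: window_length must be odd and exceed polyorder",
         call. = FALSE)
  }
  n <- length(track$timestamps)
  if (window_length > n) {
    stop("configuration error: window_length (", window_length,
         ") exceeds track length (", n, ")", call. = FALSE)
  }
  dt <- 1 / track$sample_rate
  half <- (window_length - 1L) %/% 2L

  # full sgolay filter matrices for value and derivatives 1..3; only the
  # centre-row (fully supported) outputs are kept below
  filt <- lapply(0:3, function(m) {
    signal::sgolay(p = polyorder, n = window_length, m = m, ts = dt)
  })

  pos <- matrix(NA_real_, n, 3)
  d1 <- matrix(NA_real_, n, 3)
  d2 <- matrix(NA_real_, n, 3)
  d3 <- matrix(NA_real_, n, 3)
  valid <- rep(FALSE, n)

  runs <- rle(track$in_view)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$values)) {
    if (!runs$values[r] || runs$lengths[r] < window_length) next
    idx <- starts[r]:ends[r]
    core_rel <- (half + 1L):(length(idx) - half)
    core <- idx[core_rel]
    for (k in 1:3) {
      x <- track$tip_position[idx, k]
      pos[core, k] <- signal::filter(filt[[1]], x)[core_rel]
      d1[core, k] <- signal::filter(filt[[2]], x)[core_rel]
      d2[core, k] <- signal::filter(filt[[3]], x)[core_rel]
      d3[core, k] <- signal::filter(filt[[4]], x)[core_rel]
    }
    valid[core] <- TRUE
  }

  structure(list(
    instrument_id = track$instrument_id,
    sample_rate = track$sample_rate,
    timestamps = track$timestamps,
    position = pos,
    deriv1 = d1,
    deriv2 = d2,
    deriv3 = d3,
    valid_mask = valid,
    port_position = track$port_position,
    attitude = track$attitude,
    gripper_angle = track$gripper_angle,
    in_view = track$in_view
  ), class = "kinematic_series")
}
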