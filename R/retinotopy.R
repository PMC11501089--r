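#' Retinotopic map
#'
#' Per-vertex amplitude and preferred phase of the response to a periodic
#' traveling-wave stimulus.  Phase is in degrees, wrapped to `[0, 360)`.
#' For eccentricity maps, 0 degrees is the center of the visual field and
#' 360 the most peripheral part; for polar-angle maps, 0/180 degrees are
#' the vertical meridians and 90/270 the horizontal meridians.
#'
#' @param amplitude non-negative numeric vector.
#' @param phase_deg numeric vector of phases in degrees.
#' @param kind `"eccentricity"` or `"polar_angle"`.
#' @export
retinotopic_map <- function(amplitude, phase_deg,
                            kind = c("eccentricity", "polar_angle")) {
  kind <- match.arg(kind)
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  if (length(amplitude) == 1) amplitude <- rep(amplitude, length(phase_deg))
  stopifnot(length(amplitude) == length(phase_deg))
  structure(list(amplitude = as.numeric(amplitude),
                 phase = wrap_degrees(as.numeric(phase_deg)),
                 kind = kind),
            class = "retinotopic_map")
}

#' Sine/cosine encoding of a retinotopic map
#'
#' A vertex with amplitude A and preferred phase theta responds to a
#' stimulus at phase phi as `A cos(theta - phi) = x cos(phi) + y
#' sin(phi)` with `x = A cos(theta)`, `y = A sin(theta)`.  Unlike the
#' circular phase, the weight maps x and y are linear in the response and
#' can be predicted with linear models; `decode_retinotopy()` inverts the
#' encoding exactly wherever the amplitude is positive (zero-amplitude
#' vertices decode to phase 0 by convention).
#'
#' @param map a [retinotopic_map()].
#' @return `encode_retinotopy`: list with components `x` and `y`.
#' @export
encode_retinotopy <- function(map) {
  stopifnot(inherits(map, "retinotopic_map"))
  th <- map$phase * pi / 180
  list(x = map$amplitude * cos(th), y = map$amplitude * sin(th),
       kind = map$kind)
}

#' @rdname encode_retinotopy
#' @param enc list with numeric components `x` and `y` (and optionally
#'   `kind`).
#' @param kind map kind, overriding `enc$kind`.
#' @export
decode_retinotopy <- function(enc, kind = NULL) {
  a <- sqrt(enc$x^2 + enc$y^2)
  th <- ifelse(a > 0, atan2(enc$y, enc$x) * 180 / pi, 0)
  retinotopic_map(a, wrap_degrees(th),
                  kind = if (!is.null(kind)) kind
                         else if (!is.null(enc$kind)) enc$kind
                         else "eccentricity")
}

#' Predict an individualized retinotopic map
#'
#' Two descriptor vectors -- one for the cosine weight map x, one for the
#' sine weight map y -- are multiplied by the participant's tuning matrix
#' and the resulting encoded maps are decoded back to amplitude and
#' phase.
#'
#' @param descriptors_x,descriptors_y k-vectors estimated from training
#'   participants' encoded maps.
#' @param tuning the participant's `tuning_matrix`.
#' @param kind map kind.
#' @return A [retinotopic_map()].
#' @export
predict_retinotopic_map <- function(descriptors_x, descriptors_y, tuning,
                                    kind = c("eccentricity", "polar_angle")) {
  kind <- match.arg(kind)
  stopifnot(inherits(tuning, "tuning_matrix"))
  if (length(descriptors_x) != nrow(tuning$data) ||
      length(descriptors_y) != nrow(tuning$data))
    stop("descriptor length does not match the tuning basis")
  decode_retinotopy(list(x = as.numeric(descriptors_x %*% tuning$data),
                         y = as.numeric(descriptors_y %*% tuning$data)),
                    kind = kind)
}

#' Fourier estimation of a phase-encoded retinotopic map
#'
#' Extracts, for every vertex, the discrete Fourier component at the
#' stimulus frequency (`n_cycles` cycles over `n_timepoints` TRs of the
#' stimulation window).  The component's amplitude (scaled as `2/n |c|`)
#' indicates how strongly the vertex follows the traveling-wave stimulus
#' and its phase indicates the preferred stimulus phase (eccentricity or
#' polar angle).  The phase is corrected for hemodynamic delay by
#' subtracting `360 * delay_seconds / cycle_seconds` degrees.
#'
#' @param run a [subject_timeseries()] containing the retinotopy run.
#' @param n_cycles stimulus cycles in the window (default 5).
#' @param n_timepoints TRs in the stimulation window (default 80).
#' @param delay_seconds assumed hemodynamic delay (default 5).
#' @param cycle_seconds stimulus period in seconds (default 32).
#' @param skip_tr TRs to discard before the stimulation window.
#' @param kind map kind.
#' @return A [retinotopic_map()].
#' @export
fourier_phase_map <- function(run, n_cycles = 5, n_timepoints = 80,
                              delay_seconds = 5, cycle_seconds = 32,
                              skip_tr = 0,
                              kind = c("eccentricity", "polar_angle")) {
  kind <- match.arg(kind)
  stopifnot(inherits(run, "subject_timeseries"))
  if (nrow(run$data) < skip_tr + n_timepoints)
    stop("run too short for the requested stimulation window")
  x <- run$data[skip_tr + seq_len(n_timepoints), , drop = FALSE]
  tt <- seq_len(n_timepoints) - 1
  w <- 2 * pi * n_cycles * tt / n_timepoints
  re <- as.numeric(crossprod(x, cos(w)))
  im <- as.numeric(crossprod(x, sin(w)))
  amplitude <- 2 * sqrt(re^2 + im^2) / n_timepoints
  phase <- atan2(im, re) * 180 / pi - 360 * delay_seconds / cycle_seconds
  retinotopic_map(amplitude, wrap_degrees(phase), kind = kind)
}

circular_mean_deg <- function(...) {
  th <- do.call(rbind, lapply(list(...), function(x) x * pi / 180))
  wrap_degrees(atan2(colMeans(sin(th)), colMeans(cos(th))) * 180 / pi)
}

#' Combine forward and reversed retinotopy runs
#'
#' Retinotopy protocols run the traveling wave in both directions (e.g.
#' expanding and contracting rings) so that residual hemodynamic delay
#' cancels: the delay shifts the measured phase the same way in both
#' runs, while the stimulus phase runs in opposite directions.  The
#' reversed run's phases are mapped into the forward convention by
#' negation, then averaged circularly with the forward run; amplitudes
#' are averaged arithmetically.
#'
#' @param forward,reversed [retinotopic_map()]s of the same kind.
#' @return A [retinotopic_map()].
#' @export
combine_retinotopy_runs <- function(forward, reversed) {
  stopifnot(inherits(forward, "retinotopic_map"),
            inherits(reversed, "retinotopic_map"))
  if (forward$kind != reversed$kind)
    stop("cannot combine maps of different kinds")
  retinotopic_map((forward$amplitude + reversed$amplitude) / 2,
                  circular_mean_deg(forward$phase,
                                    wrap_degrees(-reversed$phase)),
                  kind = forward$kind)
}
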