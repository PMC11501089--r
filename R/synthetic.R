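#' Specification of a synthetic cohort
#'
#' Describes a simulated multi-participant dataset with the statistical
#' structure the tuning model assumes: all participants share a low-rank
#' orthogonal stimulus basis, their tuning matrices share a controllable
#' fraction of variance, topography can be scrambled by an individual
#' linear warp, and i.i.d. Gaussian noise is added on top.  Tuning
#' entries are scaled by `1/sqrt(k_latent)` so the noiseless response
#' entries have approximately unit variance; `noise_sd = 1` therefore
#' corresponds to a signal-to-noise ratio of about 1.
#'
#' @param n_subjects number of participants (default 10).
#' @param t_time time points per participant (default 600).
#' @param v_vertex number of vertices (default 400; must be a perfect
#'   square for the default grid geometry).
#' @param k_latent rank of the shared stimulus structure (default 40).
#' @param tr_seconds sampling interval (default 1).
#' @param noise_sd additive noise standard deviation (default 1).
#' @param tuning_between_subject_corr expected correlation between two
#'   participants' flattened tuning matrices, in `[0, 1)` (default 0.5).
#' @param topographic_warp `"none"`, `"local_rotation"` (random
#'   orthogonal mixing within non-overlapping vertex blocks), or
#'   `"smooth_displacement"` (vertices resampled from a smoothly
#'   displaced grid location).
#' @param warp_block vertex block size for `"local_rotation"`.
#' @param geometry a [surface_geometry()], or `NULL` for a 3 mm grid.
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_subjects = 10L, t_time = 600L, v_vertex = 400L,
                        k_latent = 40L, tr_seconds = 1,
                        noise_sd = 1, tuning_between_subject_corr = 0.5,
                        topographic_warp = c("none", "local_rotation",
                                             "smooth_displacement"),
                        warp_block = 4L, geometry = NULL, seed = 1L) {
  topographic_warp <- match.arg(topographic_warp)
  if (k_latent > min(t_time, v_vertex))
    stop("k_latent must be <= min(t_time, v_vertex)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  c_bs <- tuning_between_subject_corr
  if (c_bs < 0 || c_bs >= 1)
    stop("tuning_between_subject_corr must be in [0, 1)")
  if (is.null(geometry)) {
    side <- round(sqrt(v_vertex))
    if (side * side != v_vertex)
      stop("v_vertex must be a perfect square for the default grid geometry")
    geometry <- grid_geometry(side)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 t_time = as.integer(t_time),
                 v_vertex = as.integer(v_vertex),
                 k_latent = as.integer(k_latent),
                 tr_seconds = tr_seconds, noise_sd = noise_sd,
                 tuning_between_subject_corr = c_bs,
                 topographic_warp = topographic_warp,
                 warp_block = as.integer(warp_block),
                 geometry = geometry, seed = as.integer(seed)),
            class = "cohort_spec")
}

random_orthogonal <- function(q) {
  qr_ <- qr(matrix(stats::rnorm(q * q), q))
  qmat <- qr.Q(qr_)
  qmat %*% diag(sign(diag(qr.R(qr_))), q)
}

make_warp <- function(spec) {
  v <- spec$v_vertex
  if (spec$topographic_warp == "local_rotation") {
    W <- matrix(0, v, v)
    starts <- seq(1, v, by = spec$warp_block)
    for (s in starts) {
      idx <- s:min(s + spec$warp_block - 1L, v)
      W[idx, idx] <- random_orthogonal(length(idx))
    }
    W
  } else {  # smooth_displacement: resample from a smoothly shifted location
    co <- spec$geometry$coordinates
    span <- apply(co, 2, function(x) diff(range(x)))
    span[span == 0] <- 1
    amp <- 1.5 * min(span[1:2]) / sqrt(v)   # ~half a grid spacing
    shift <- sapply(1:2, function(d) {
      ph <- stats::runif(2, 0, 2 * pi)
      amp * (sin(2 * pi * co[, 1] / span[1] + ph[1]) +
             cos(2 * pi * co[, 2] / span[2] + ph[2]))
    })
    W <- matrix(0, v, v)
    for (j in seq_len(v)) {
      target <- co[j, 1:2] + shift[j, ]
      d2 <- (co[, 1] - target[1])^2 + (co[, 2] - target[2])^2
      W[which.min(d2), j] <- 1
    }
    W
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a shared orthogonal stimulus basis `S_true` (t x k, unit-variance
#' columns), a shared tuning component and individual tuning components
#' combined as `T_p = sqrt(c) T_base + sqrt(1 - c) T_indiv_p` (so the
#' expected between-subject tuning correlation is `c`), optional
#' individual topographic warps, and additive Gaussian noise.  Each
#' participant's matrix is `B_p = S_true T_p W_p + E`, z-scored per
#' vertex.  Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List with `cohort` (list of [subject_timeseries()]) and
#'   `truth` (list with `S_true`, `T_true`, `W_true`, `spec`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    t <- spec$t_time; v <- spec$v_vertex; k <- spec$k_latent
    S <- qr.Q(qr(matrix(stats::rnorm(t * k), t, k)))
    S <- fix_signs(S)
    S <- sweep(S, 2, apply(S, 2, stats::sd), "/")
    c_bs <- spec$tuning_between_subject_corr
    sd_T <- 1 / sqrt(k)
    T_base <- matrix(stats::rnorm(k * v, sd = sd_T), k, v)
    cohort <- vector("list", spec$n_subjects)
    T_true <- vector("list", spec$n_subjects)
    W_true <- if (spec$topographic_warp == "none") NULL
              else vector("list", spec$n_subjects)
    for (p in seq_len(spec$n_subjects)) {
      Tp <- sqrt(c_bs) * T_base +
        sqrt(1 - c_bs) * matrix(stats::rnorm(k * v, sd = sd_T), k, v)
      T_true[[p]] <- Tp
      signal <- S %*% Tp
      if (!is.null(W_true)) {
        W_true[[p]] <- make_warp(spec)
        signal <- signal %*% W_true[[p]]
      }
      noise <- matrix(stats::rnorm(t * v, sd = spec$noise_sd), t, v)
      ts <- subject_timeseries(signal + noise,
                               subject_id = sprintf("sub-%02d", p),
                               tr_seconds = spec$tr_seconds)
      cohort[[p]] <- normalize_timeseries(ts)
    }
    list(cohort = cohort,
         truth = list(S_true = S, T_true = T_true, W_true = W_true,
                      spec = spec))
  })
}

#' Synthetic localizer fixture
#'
#' Emulates a block-design localizer: a shared condition descriptor
#' `s_star` (k-vector) defines each participant's true selectivity map
#' `s_star %*% T_p`, and each of `n_runs` run maps adds independent
#' Gaussian noise.  With tuning variance `var_T` and noise variance
#' `run_noise_sd^2`, the single-run reliability is
#' `var_T / (var_T + run_noise_sd^2)` and the fixture's Cronbach's alpha
#' follows the Spearman-Brown prediction for `n_runs`.
#'
#' @param truth the `truth` element returned by [make_cohort()].
#' @param n_runs number of localizer runs (default 4).
#' @param run_noise_sd per-run noise SD (default 1).
#' @param seed RNG seed.
#' @return List with `maps` (list of [selectivity_map()] with `run_maps`),
#'   `true_maps`, and the descriptor `s_star`.
#' @export
make_localizer_fixture <- function(truth, n_runs = 4L, run_noise_sd = 1,
                                   seed = 1L) {
  with_seed(seed, {
    k <- nrow(truth$T_true[[1]])
    s_star <- stats::rnorm(k)
    maps <- vector("list", length(truth$T_true))
    true_maps <- vector("list", length(truth$T_true))
    for (p in seq_along(truth$T_true)) {
      tm <- as.numeric(s_star %*% truth$T_true[[p]])
      true_maps[[p]] <- tm
      runs <- lapply(seq_len(n_runs), function(i)
        tm + stats::rnorm(length(tm), sd = run_noise_sd))
      maps[[p]] <- selectivity_map(Reduce(`+`, runs) / n_runs,
                                   subject_id = sprintf("sub-%02d", p),
                                   condition = "synthetic_contrast",
                                   run_maps = runs)
    }
    list(maps = maps, true_maps = true_maps, s_star = s_star)
  })
}

#' Synthetic traveling-wave retinotopy fixture
#'
#' Builds forward and reversed phase-encoded runs from a smooth phase
#' field and amplitude field over the vertices: each vertex's time series
#' is `A(v) cos(w (t - delay) -+ theta(v))` (sign flipped for the
#' reversed stimulus direction) plus optional noise.  Processing the two
#' runs with [fourier_phase_map()] and [combine_retinotopy_runs()]
#' recovers the phase field exactly in the noiseless case.
#'
#' @param geom a [surface_geometry()].
#' @param n_timepoints TRs per run (default 80).
#' @param n_cycles stimulus cycles per run (default 5).
#' @param tr_seconds TR in seconds (default 2).
#' @param delay_seconds simulated hemodynamic delay (default 5).
#' @param phase_field,amplitude_field optional per-vertex fields; by
#'   default the phase ramps smoothly across the first grid axis and the
#'   amplitude across the second.
#' @param noise_sd additive noise SD (default 0).
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return List with `forward`, `reversed` ([subject_timeseries()]),
#'   `phase`, `amplitude`.
#' @export
make_retinotopy_fixture <- function(geom, n_timepoints = 80L, n_cycles = 5L,
                                    tr_seconds = 2, delay_seconds = 5,
                                    phase_field = NULL,
                                    amplitude_field = NULL,
                                    noise_sd = 0, seed = 1L) {
  co <- geom$coordinates
  rng <- function(x) if (diff(range(x)) == 0) rep(0.5, length(x))
                     else (x - min(x)) / diff(range(x))
  if (is.null(phase_field)) phase_field <- wrap_degrees(350 * rng(co[, 1]))
  if (is.null(amplitude_field)) amplitude_field <- 1 + rng(co[, 2])
  with_seed(seed, {
    tt <- seq_len(n_timepoints) - 1
    w <- 2 * pi * n_cycles / n_timepoints
    delay_tr <- delay_seconds / tr_seconds
    th <- phase_field * pi / 180
    mk <- function(sign_) {
      x <- outer(tt, seq_along(th), function(t_, j)
        amplitude_field[j] * cos(w * (t_ - delay_tr) - sign_ * th[j]))
      if (noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
      subject_timeseries(x, subject_id = "retino", tr_seconds = tr_seconds)
    }
    list(forward = mk(1), reversed = mk(-1),
         phase = phase_field, amplitude = amplitude_field)
  })
}
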