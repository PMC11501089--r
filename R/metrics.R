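#' Cross-split tuning similarity matrix
#'
#' Pearson correlations between flattened tuning matrices estimated from
#' two independent data splits: entry (i, j) correlates participant i's
#' split-1 tuning with participant j's split-2 tuning.  The diagonal
#' holds within-subject similarities, the off-diagonal between-subject
#' similarities; a wide gap between the two indicates reliable,
#' individual-specific tuning.
#'
#' @param tunings_half1,tunings_half2 lists of `tuning_matrix` objects
#'   (same participants, same order, same basis).
#' @return A `similarity_matrix`: list with `values` (n x n correlation
#'   matrix), `fisher_z` (arctanh transform), `subjects`.
#' @export
tuning_similarity_matrix <- function(tunings_half1, tunings_half2) {
  stopifnot(length(tunings_half1) == length(tunings_half2))
  check_same_basis(c(tunings_half1, tunings_half2))
  n <- length(tunings_half1)
  a <- vapply(tunings_half1, function(tm) as.numeric(tm$data),
              numeric(length(tunings_half1[[1]]$data)))
  b <- vapply(tunings_half2, function(tm) as.numeric(tm$data),
              numeric(length(tunings_half2[[1]]$data)))
  vals <- stats::cor(a, b)
  structure(list(values = vals, fisher_z = atanh(pmin(pmax(vals, -1 + 1e-15),
                                                      1 - 1e-15)),
                 subjects = vapply(tunings_half1, `[[`, "", "subject_id")),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<similarity_matrix: %d participants, within = %.3f, between = %.3f>\n",
              n, mean(diag(x$values)),
              mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' Distinctiveness index of one participant's tuning
#'
#' Cohen's-d-style contrast between a participant's within-subject
#' similarity and the distribution of that participant's between-subject
#' similarities, computed on Fisher-transformed correlations from the
#' participant's row of the similarity matrix:
#' `(z_within - mean(z_between)) / sd(z_between)` with the sample
#' standard deviation.  Because Fisher-z similarities are approximately
#' normal, the index behaves like a z statistic and feeds
#' [identification_error_rate()].  A zero between-subject spread returns
#' `Inf` with a warning.
#'
#' @param sim a [tuning_similarity_matrix()].
#' @param subject_row row index of the participant.
#' @export
distinctiveness_index <- function(sim, subject_row) {
  stopifnot(inherits(sim, "similarity_matrix"))
  n <- nrow(sim$values)
  if (n < 3) stop("need at least 3 participants to estimate the spread")
  z <- sim$fisher_z[subject_row, ]
  between <- z[-subject_row]
  s <- stats::sd(between)
  if (s == 0) {
    warning("zero spread of between-subject similarities")
    return(Inf)
  }
  (z[subject_row] - mean(between)) / s
}

#' Identification error rate from a distinctiveness index
#'
#' Treats the distinctiveness index as a z statistic and returns the
#' standard-normal upper-tail probability beyond it, `pnorm(-d)`: the
#' probability that a between-subject similarity would exceed the
#' within-subject similarity.
#'
#' @param d distinctiveness index (finite numeric).
#' @export
identification_error_rate <- function(d) {
  stopifnot(is.numeric(d))
  stats::pnorm(-d)
}

#' Nearest-neighbor participant identification accuracy
#'
#' Fraction of participants whose split-1 tuning matrix is most similar
#' to their own split-2 tuning matrix (row-wise argmax of the similarity
#' matrix).
#'
#' @param sim a [tuning_similarity_matrix()].
#' @export
identification_accuracy <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  mean(max.col(sim$values, ties.method = "first") == seq_len(nrow(sim$values)))
}

#' Cronbach's alpha of a set of parallel maps
#'
#' Reliability of the average of k parallel measurements (e.g. k
#' localizer-run maps), `alpha = k/(k-1) * (1 - sum(var_i) / var_sum)`
#' with variances taken across vertices.
#'
#' @param run_maps list of k numeric vectors of equal length.
#' @export
cronbach_alpha <- function(run_maps) {
  k <- length(run_maps)
  if (k < 2) stop("need at least 2 runs")
  stopifnot(length(unique(vapply(run_maps, length, 1L))) == 1)
  item_var <- sum(vapply(run_maps, stats::var, 1))
  total_var <- stats::var(Reduce(`+`, run_maps))
  if (total_var == 0) stop("total variance is zero; alpha undefined")
  k / (k - 1) * (1 - item_var / total_var)
}

#' Spearman-Brown reliability prediction
#'
#' Predicted reliability of the average of `k` parallel tests given
#' single-test reliability `rho`: `k rho / (1 + (k - 1) rho)`.
#'
#' @param rho_single single-test reliability in `[0, 1]`.
#' @param k number of tests averaged (any positive real).
#' @export
spearman_brown <- function(rho_single, k) {
  if (any(rho_single < 0 | rho_single > 1)) stop("rho must be in [0, 1]")
  if (any(k <= 0)) stop("k must be positive")
  k * rho_single / (1 + (k - 1) * rho_single)
}

#' Expected correlation between two noisy maps
#'
#' Two measurements of the same true map with reliabilities `rho_i` and
#' `rho_j` correlate at `sqrt(rho_i * rho_j)` in expectation.
#'
#' @param rho_i,rho_j reliabilities in `[0, 1]`.
#' @export
expected_map_correlation <- function(rho_i, rho_j) {
  if (any(c(rho_i, rho_j) < 0 | c(rho_i, rho_j) > 1))
    stop("reliabilities must be in [0, 1]")
  sqrt(rho_i * rho_j)
}

#' Localizer data equivalent to a predicted map's quality
#'
#' Converts an observed correlation between a model-predicted map and a
#' k0-run localizer average into the amount of localizer scanning that
#' would be needed to reach the same quality.  Single-run reliability is
#' recovered by inverting the Spearman-Brown formula from the average
#' map's Cronbach's alpha; the predicted map's implied reliability is
#' `r^2 / alpha` (from the expected correlation
#' `sqrt(rho_pred * rho_avg)`); the returned
#' duration is the number of runs whose average attains that reliability,
#' times the run duration.  This inference chain is model-dependent (it
#' assumes the parallel-test model throughout) and is intended for
#' descriptive comparisons, not precise claims.
#'
#' @param alpha_k0 Cronbach's alpha of the k0-run average map, in (0, 1).
#' @param k0_runs number of localizer runs behind `alpha_k0`.
#' @param run_minutes duration of one run in minutes.
#' @param observed_r correlation between predicted map and the k0-run
#'   average (> 0).
#' @return Equivalent scan time in minutes (`Inf` if the implied
#'   reliability reaches 1).
#' @export
equivalent_localizer_minutes <- function(alpha_k0, k0_runs, run_minutes,
                                         observed_r) {
  if (alpha_k0 <= 0 || alpha_k0 >= 1) stop("alpha must be in (0, 1)")
  if (observed_r <= 0) stop("observed_r must be positive")
  rho1 <- alpha_k0 / (k0_runs - (k0_runs - 1) * alpha_k0)
  rho_pred <- observed_r^2 / alpha_k0
  if (rho_pred >= 1) return(Inf)
  k_star <- rho_pred * (1 - rho1) / (rho1 * (1 - rho_pred))
  k_star * run_minutes
}

#' Mean absolute circular phase difference
#'
#' Average over a region of the wrap-around phase difference between two
#' retinotopic maps, `min(|a - b| mod 360, 360 - |a - b| mod 360)`, in
#' degrees (range 0-180).  For unrelated phase maps the expectation
#' is 90 degrees.
#'
#' @param map_a,map_b [retinotopic_map()]s of the same kind.
#' @param mask optional [region_mask()] restricting the average.
#' @export
circular_phase_difference <- function(map_a, map_b, mask = NULL) {
  stopifnot(inherits(map_a, "retinotopic_map"),
            inherits(map_b, "retinotopic_map"))
  if (map_a$kind != map_b$kind) stop("maps have different kinds")
  idx <- if (is.null(mask)) seq_along(map_a$phase) else mask$members
  if (!length(idx)) stop("empty mask")
  d <- abs(map_a$phase[idx] - map_b$phase[idx]) %% 360
  mean(pmin(d, 360 - d))
}

#' Searchlight map of tuning distinctiveness
#'
#' Computes, for every searchlight, the tuning similarity matrix
#' restricted to the member vertices, derives each participant's
#' distinctiveness index, and assigns the across-participant mean to the
#' center vertex.  The resulting map localizes where individual
#' functional organization is most distinctive.  Degenerate searchlights
#' (zero between-subject spread) yield `Inf` indices, which propagate to
#' the map.
#'
#' @param tunings_half1,tunings_half2 lists of `tuning_matrix` objects.
#' @param geom a [surface_geometry()].
#' @param radius searchlight radius in mm.
#' @param searchlights optional precomputed searchlights.
#' @return Numeric vector of mean distinctiveness, one value per vertex.
#' @export
searchlight_distinctiveness_map <- function(tunings_half1, tunings_half2,
                                            geom, radius = 20,
                                            searchlights = NULL) {
  check_same_basis(c(tunings_half1, tunings_half2))
  n <- length(tunings_half1)
  if (n < 3) stop("need at least 3 participants")
  if (is.null(searchlights)) searchlights <- build_searchlights(geom, radius)
  vapply(searchlights, function(sl) {
    h1 <- lapply(tunings_half1, function(tm) {
      tm$data <- tm$data[, sl$members, drop = FALSE]; tm
    })
    h2 <- lapply(tunings_half2, function(tm) {
      tm$data <- tm$data[, sl$members, drop = FALSE]; tm
    })
    sim <- tuning_similarity_matrix(h1, h2)
    mean(vapply(seq_len(n), function(i)
      suppressWarnings(distinctiveness_index(sim, i)), 1))
  }, 1)
}
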