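#' Shared stimulus matrix from group SVD
#'
#' Decomposes the column-concatenated (modeled) response matrices of the
#' training participants by SVD and returns the left singular vectors,
#' rescaled so that every column has unit variance, as the shared
#' stimulus matrix `S`.  The columns of `S` are mutually orthogonal basis
#' response profiles: every vertex's response time series, in every
#' participant, is a linear combination of them, with the weights forming
#' that vertex's tuning profile.  Orthogonality makes differences between
#' tuning matrices proportional to differences between the modeled
#' responses, and unit variance keeps tuning estimates on the same scale
#' regardless of how many time points they are estimated from.  The
#' number of columns `k` equals the numerical rank of the concatenation
#' (singular values below `1e-10` of the largest are discarded).
#'
#' @param modeled list of time x vertex matrices (typically the modeled
#'   responses `M W_p` of the training participants).
#' @param scaling `"unit_variance"` (default) rescales each left singular
#'   vector to unit column variance; `"sqrt_n"` multiplies `U` by
#'   `sqrt(n)` instead.
#' @return A `stimulus_matrix`: list with `data` (t x k), `column_scale`,
#'   `basis_id`, `n_train`.
#' @export
compute_stimulus_matrix <- function(modeled,
                                    scaling = c("unit_variance", "sqrt_n")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(modeled), length(modeled) >= 1)
  tdims <- unique(vapply(modeled, nrow, 1L))
  if (length(tdims) != 1) stop("matrices have mismatched time axes")
  x <- do.call(cbind, modeled)
  t_time <- nrow(x)
  s <- svd(x, nu = min(dim(x)), nv = 0)
  k <- sum(s$d > 1e-10 * max(s$d))
  u <- fix_signs(s$u[, seq_len(k), drop = FALSE])
  s <- if (scaling == "unit_variance") {
    sweep(u, 2, apply(u, 2, stats::sd), "/")
  } else {
    u * sqrt(length(modeled))
  }
  structure(list(data = s, column_scale = scaling,
                 basis_id = basis_signature(s),
                 n_train = length(modeled),
                 row_index = seq_len(t_time)),
            class = "stimulus_matrix")
}

basis_signature <- function(s) {
  sprintf("%dx%d-%.10e", nrow(s), ncol(s),
          sum(s * rep_len(c(1, -0.5, 0.25), length(s))))
}

#' @export
print.stimulus_matrix <- function(x, ...) {
  cat(sprintf("<stimulus_matrix: %d time points x %d features (%s scaling)>\n",
              nrow(x$data), ncol(x$data), x$column_scale))
  invisible(x)
}

#' Restrict a stimulus matrix to a subset of rows
#'
#' Keeps the basis identity so that tuning matrices estimated from
#' different row subsets (e.g. movie halves) remain comparable.
#'
#' @param s a `stimulus_matrix`.
#' @param rows integer row indices.
#' @export
stimulus_rows <- function(s, rows) {
  stopifnot(inherits(s, "stimulus_matrix"))
  out <- s
  out$data <- s$data[rows, , drop = FALSE]
  out$row_index <- s$row_index[rows]
  out
}

#' Estimate a participant's tuning matrix
#'
#' Solves `modeled = S T` for the feature x vertex tuning matrix by
#' least squares.  When the observed rows of `S` have full column rank
#' the solution is exact up to the least-squares residual; with fewer
#' observed rows than features the minimum-norm (pseudoinverse) solution
#' is returned.  Because the basis `S` is shared, tuning matrices of
#' different participants -- or of the same participant estimated from
#' different stimuli -- are directly comparable, provided they were
#' estimated under the same basis (checked via `basis_id`).
#'
#' @param S a `stimulus_matrix` (possibly row-restricted via
#'   [stimulus_rows()]).
#' @param modeled matrix of (modeled) responses with rows matching the
#'   rows of `S`.
#' @param subject_id participant label.
#' @return A `tuning_matrix`: list with `data` (k x v), `subject_id`,
#'   `basis_id`.
#' @export
estimate_tuning <- function(S, modeled, subject_id = "subj") {
  stopifnot(inherits(S, "stimulus_matrix"))
  modeled <- as.matrix(modeled)
  if (nrow(modeled) != nrow(S$data))
    stop("row count of `modeled` does not match the stimulus matrix rows")
  if (nrow(modeled) == 0) stop("no observed rows")
  Tm <- pinv_solve(S$data, modeled)
  structure(list(subject_id = subject_id, data = Tm,
                 basis_id = S$basis_id),
            class = "tuning_matrix")
}

# Minimum-norm least-squares solution of A x = b via SVD.
pinv_solve <- function(A, b, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], b) / s$d[keep])
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf("<tuning_matrix '%s': %d features x %d vertices>\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

check_same_basis <- function(tunings) {
  ids <- unique(vapply(tunings, `[[`, "", "basis_id"))
  if (length(ids) != 1)
    stop("tuning matrices were estimated under different stimulus bases ",
         "and cannot be compared")
  invisible(ids)
}

#' Extend the stimulus matrix to new stimuli
#'
#' Estimates stimulus descriptors (rows of `S`) for stimuli that were not
#' part of the data used to build the template, from a group of
#' participants' responses to the new stimuli and their known tuning
#' matrices: for each new stimulus, the response pattern is regressed on
#' the tuning features across the concatenated vertices of the
#' participants using the bagged ensemble ridge procedure of
#' [estimate_contrast_descriptor()].
#'
#' @param new_responses list (one element per participant, same order as
#'   `tunings`) of matrices n_new_stimuli x vertex.
#' @param tunings list of `tuning_matrix` objects sharing one basis.
#' @param cfg an [ensemble_regression_config()].
#' @return Matrix n_new_stimuli x k of estimated descriptors.
#' @export
extend_stimulus_matrix <- function(new_responses, tunings,
                                   cfg = ensemble_regression_config()) {
  check_same_basis(tunings)
  stopifnot(length(new_responses) == length(tunings))
  n_new <- unique(vapply(new_responses, nrow, 1L))
  if (length(n_new) != 1) stop("participants report different stimulus counts")
  k <- nrow(tunings[[1]]$data)
  out <- matrix(0, n_new, k)
  for (i in seq_len(n_new)) {
    maps <- lapply(seq_along(tunings), function(p)
      selectivity_map(new_responses[[p]][i, ],
                      subject_id = tunings[[p]]$subject_id,
                      condition = sprintf("new_stimulus_%d", i)))
    out[i, ] <- estimate_contrast_descriptor(maps, tunings, cfg)
  }
  out
}
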