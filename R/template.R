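#' Group PCA of a searchlight across participants
#'
#' Concatenates all training participants' searchlight blocks along the
#' vertex (column) dimension and extracts principal-component score time
#' series by SVD, keeping as many components as one participant has
#' vertices so that the local template has the same dimensionality as a
#' single participant's local data matrix.  Scores are divided by
#' `sqrt(n)` (default) so that the total variance of the local template
#' matches that of one participant rather than the n-fold concatenation;
#' `scaling = "n"` divides by `n` instead.
#'
#' Component signs are fixed so the largest-magnitude score is positive,
#' which makes the result invariant to participant ordering.  If the
#' number of time points is smaller than the searchlight size the result
#' is rank-deficient: the available components are kept and the remaining
#' columns are zero-padded (with a warning).
#'
#' @param blocks list of numeric matrices (time x searchlight vertices),
#'   one per training participant, all the same shape.
#' @param scaling `"sqrt_n"` or `"n"`.
#' @return Matrix of PC score time series, time x searchlight-vertices.
#' @export
local_group_pca <- function(blocks, scaling = c("sqrt_n", "n")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  dims <- unique(lapply(blocks, dim))
  if (length(dims) != 1) stop("all blocks must share the same shape")
  t_time <- dims[[1]][1]; v_sl <- dims[[1]][2]
  n <- length(blocks)
  x <- do.call(cbind, blocks)
  q <- min(v_sl, t_time, ncol(x))
  if (t_time < v_sl)
    warning("fewer time points than searchlight vertices; zero-padding rank-deficient components")
  # scores via eigen-decomposition of the t x t outer-product matrix
  g <- tcrossprod(x)
  e <- eigen(g, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(q)], 0)
  keep <- ev > max(ev[1], 0) * 1e-20
  scores <- matrix(0, t_time, v_sl)
  if (any(keep))
    scores[, which(keep)] <- e$vectors[, which(keep), drop = FALSE] %*%
      diag(sqrt(ev[keep]), sum(keep))
  scores <- fix_signs(scores)
  div <- if (scaling == "sqrt_n") sqrt(n) else n
  scores / div
}

#' Orthogonal Procrustes solution
#'
#' Returns the orthogonal matrix `R` minimizing `||source %*% R - target||_F`,
#' computed as `U V'` from the SVD of `t(source) %*% target`.  `R` may be an
#' improper rotation (determinant -1).  A degenerate (all-zero) covariance
#' returns the identity with a warning.
#'
#' @param source,target numeric matrices of identical shape.
#' @return Orthogonal q x q matrix.
#' @export
procrustes_solve <- function(source, target) {
  if (!identical(dim(source), dim(target))) stop("shape mismatch")
  m <- crossprod(source, target)
  if (max(abs(m)) == 0) {
    warning("degenerate covariance in Procrustes problem; returning identity")
    return(diag(ncol(source)))
  }
  s <- svd(m)
  s$u %*% t(s$v)
}

#' Rotate a local PC template into vertex space
#'
#' Finds the single orthogonal rotation that best aligns the PC score
#' matrix with every training participant's searchlight block
#' simultaneously (minimizing the summed Frobenius error), which equals
#' the Procrustes solution for the participant-concatenated matrices, and
#' applies it to the PC scores.  The rotation leaves the representational
#' geometry of the template unchanged while making its vertex topography
#' representative of the group.
#'
#' @param pc_scores time x v_sl PC score matrix from [local_group_pca()].
#' @param participant_blocks list of time x v_sl participant matrices.
#' @param searchlight optional [build_searchlights()] element stored for
#'   provenance.
#' @return A `local_template` object with fields `pc_scores`, `rotation`,
#'   `vertex_template`, and `searchlight`.
#' @export
rotate_local_template <- function(pc_scores, participant_blocks,
                                  searchlight = NULL) {
  # SVD of sum_p t(pc_scores) %*% B_p equals the stacked-matrix solution
  m <- matrix(0, ncol(pc_scores), ncol(pc_scores))
  for (b in participant_blocks) m <- m + crossprod(pc_scores, b)
  r <- if (max(abs(m)) == 0) {
    warning("degenerate covariance in Procrustes problem; returning identity")
    diag(ncol(pc_scores))
  } else {
    s <- svd(m)
    s$u %*% t(s$v)
  }
  structure(list(searchlight = searchlight, pc_scores = pc_scores,
                 rotation = r, vertex_template = pc_scores %*% r),
            class = "local_template")
}

#' Aggregate local templates into a whole-brain template
#'
#' Each vertex receives the distance-weighted average of its modeled
#' response profiles across all searchlights containing it, with weight
#' `(r - d) / r` ([aggregation_weight()]): searchlights centered closer to
#' the vertex contribute more, and averaging (rather than summation) keeps
#' the profile on the scale of a single searchlight estimate.
#'
#' @param locals list of `local_template` objects covering all vertices.
#' @param geom the [surface_geometry()] the searchlights were built on.
#' @param n_train number of training participants (provenance metadata).
#' @param scaling PC scaling convention tag (provenance metadata).
#' @return A `functional_template` object: list with `data` (time x
#'   vertex matrix), `radius`, `n_train`, `scaling`.
#' @export
aggregate_to_whole_brain <- function(locals, geom, n_train = NA_integer_,
                                     scaling = "sqrt_n") {
  v <- n_vertices(geom)
  t_time <- nrow(locals[[1]]$vertex_template)
  num <- matrix(0, t_time, v)
  den <- numeric(v)
  radius <- locals[[1]]$searchlight$radius
  for (lt in locals) {
    sl <- lt$searchlight
    w <- aggregation_weight(sl$distances, sl$radius)
    num[, sl$members] <- num[, sl$members] +
      sweep(lt$vertex_template, 2, w, "*")
    den[sl$members] <- den[sl$members] + w
  }
  uncovered <- which(den <= 0)
  if (length(uncovered))
    stop("vertices not covered by any searchlight (or only at zero weight): ",
         paste(uncovered, collapse = ", "))
  structure(list(data = sweep(num, 2, den, "/"), radius = radius,
                 n_train = n_train, scaling = scaling),
            class = "functional_template")
}

#' @export
print.functional_template <- function(x, ...) {
  cat(sprintf("<functional_template: %d time points x %d vertices, radius %g mm, %s participants>\n",
              nrow(x$data), ncol(x$data), x$radius,
              ifelse(is.na(x$n_train), "?", x$n_train)))
  invisible(x)
}

#' Build the group functional template
#'
#' Orchestrates the searchlight PCA-Procrustes algorithm over a training
#' cohort: for every searchlight, a group-PCA local template is computed
#' from the concatenated participant blocks, rotated into vertex space
#' with a single orthogonal Procrustes rotation, and the local templates
#' are combined into a whole-brain time x vertex template by
#' distance-weighted averaging.  The template has the same shape as one
#' participant's data matrix and is representative of the group both in
#' representational geometry (PCA step) and cortical topography
#' (Procrustes step).
#'
#' @param cohort list of z-scored [subject_timeseries()] with matching
#'   time axes.
#' @param geom a [surface_geometry()].
#' @param radius searchlight radius in mm (default 20).
#' @param searchlights optionally precomputed [build_searchlights()]
#'   result for `geom` and `radius`.
#' @param scaling PC scaling convention, see [local_group_pca()].
#' @return A `functional_template`.
#' @export
build_template <- function(cohort, geom, radius = 20, searchlights = NULL,
                           scaling = c("sqrt_n", "n")) {
  scaling <- match.arg(scaling)
  stopifnot(length(cohort) >= 1)
  tdims <- unique(vapply(cohort, function(s) nrow(s$data), 1L))
  if (length(tdims) != 1)
    stop("participants have mismatched numbers of time points")
  if (is.null(searchlights)) searchlights <- build_searchlights(geom, radius)
  locals <- lapply(searchlights, function(sl) {
    blocks <- lapply(cohort, function(s) s$data[, sl$members, drop = FALSE])
    pc <- suppressWarnings(local_group_pca(blocks, scaling = scaling))
    rotate_local_template(pc, blocks, searchlight = sl)
  })
  aggregate_to_whole_brain(locals, geom, n_train = length(cohort),
                           scaling = scaling)
}
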