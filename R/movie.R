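#' Predict response patterns to held-out movie time points
#'
#' Multiplies the stimulus-matrix rows of the held-out movie segment by
#' the participant's tuning matrix: `S2 %*% T_p` gives the predicted
#' time x vertex response patterns in the participant's own space, built
#' entirely from other participants' responses (via the template and the
#' shared basis) plus the participant's tuning.
#'
#' @param S_heldout a `stimulus_matrix` (e.g. from [stimulus_rows()]) or
#'   plain t2 x k matrix of held-out stimulus descriptors.
#' @param tuning the participant's `tuning_matrix`.
#' @return t2 x vertex matrix of predicted patterns.
#' @export
predict_movie_patterns <- function(S_heldout, tuning) {
  stopifnot(inherits(tuning, "tuning_matrix"))
  if (inherits(S_heldout, "stimulus_matrix")) {
    if (!identical(S_heldout$basis_id, tuning$basis_id))
      stop("stimulus matrix and tuning matrix use different bases")
    S_heldout <- S_heldout$data
  }
  if (ncol(S_heldout) != nrow(tuning$data))
    stop("feature dimension mismatch")
  S_heldout %*% tuning$data
}

#' PCA reduction of response patterns
#'
#' Fits a principal component analysis on a training pattern matrix (time
#' points as samples, vertices as features) and projects further pattern
#' matrices into the leading component space.  Components are normalized
#' by their training-set standard deviation, so pattern similarity is
#' computed on equal-variance components rather than being dominated by
#' the first few.
#'
#' @param train_patterns t1 x v matrix used to fit the PCA.
#' @param apply_patterns list of matrices (each `* x v`) to project.
#' @param n_components number of leading components to keep.
#' @return List with `train` (normalized training scores), `applied`
#'   (list of normalized projections), `rotation`, `center`, `sdev`.
#' @export
reduce_patterns_pca <- function(train_patterns, apply_patterns = list(),
                                n_components) {
  train_patterns <- as.matrix(train_patterns)
  if (n_components > min(dim(train_patterns)))
    stop("n_components exceeds the rank bound of the training patterns")
  ctr <- colMeans(train_patterns)
  xc <- sweep(train_patterns, 2, ctr)
  s <- svd(xc, nu = n_components, nv = n_components)
  rot <- s$v
  scores <- s$u %*% diag(s$d[seq_len(n_components)], n_components)
  sdev <- apply(scores, 2, stats::sd)
  sdev[sdev == 0] <- 1
  norm_scores <- sweep(scores, 2, sdev, "/")
  applied <- lapply(apply_patterns, function(p) {
    sweep(sweep(as.matrix(p), 2, ctr) %*% rot, 2, sdev, "/")
  })
  list(train = norm_scores, applied = applied, rotation = rot,
       center = ctr, sdev = sdev)
}

pattern_correlations <- function(measured, predicted) {
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (!identical(dim(measured), dim(predicted)))
    stop("measured and predicted patterns must have identical shapes")
  if (nrow(measured) < 2) stop("need at least 2 time points")
  stats::cor(t(measured), t(predicted))
}

#' Binary movie time-point classification
#'
#' Two-alternative forced choice: for each time point, the measured
#' response pattern is compared (by Pearson correlation) to the predicted
#' pattern of the same time point and to the predicted pattern of a foil
#' time point, for every possible foil.  A pair counts as correct when
#' the same-time-point correlation is strictly higher, 0.5 on ties.
#' Chance is 0.5 regardless of movie length.
#'
#' @param measured,predicted t x q pattern matrices (rows are time
#'   points), typically PCA-reduced.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
classify_timepoints_binary <- function(measured, predicted) {
  cc <- pattern_correlations(measured, predicted)
  n <- nrow(cc)
  acc <- vapply(seq_len(n), function(i) {
    diff <- cc[i, i] - cc[i, -i]
    (sum(diff > 0) + 0.5 * sum(diff == 0)) / (n - 1)
  }, 1)
  mean(acc)
}

#' Multiclass movie time-point classification
#'
#' For each time point, the measured pattern is compared to the predicted
#' patterns of all time points (neighbors included); classification is
#' correct only when the same-time-point correlation is the strict
#' maximum.  Chance is `1 / t`.
#'
#' @inheritParams classify_timepoints_binary
#' @return Accuracy fraction in `[0, 1]`.
#' @export
classify_timepoints_multiclass <- function(measured, predicted) {
  cc <- pattern_correlations(measured, predicted)
  n <- nrow(cc)
  correct <- vapply(seq_len(n), function(i) {
    all(cc[i, i] > cc[i, -i])
  }, TRUE)
  mean(correct)
}
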