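#' Selectivity map
#'
#' A per-vertex contrast statistic (e.g. a faces-vs-other t map) for one
#' participant, optionally with the per-run maps it was averaged from.
#'
#' @param values numeric vector, one value per vertex.
#' @param subject_id participant label.
#' @param condition contrast label.
#' @param run_maps optional list of per-run vectors of the same length.
#' @export
selectivity_map <- function(values, subject_id = "subj",
                            condition = "contrast", run_maps = NULL) {
  values <- as.numeric(values)
  if (!is.null(run_maps)) {
    stopifnot(all(vapply(run_maps, length, 1L) == length(values)))
  }
  structure(list(subject_id = subject_id, values = values,
                 condition = condition, run_maps = run_maps),
            class = "selectivity_map")
}

#' Ensemble ridge configuration for descriptor estimation
#'
#' Configuration of the bagged ridge ensemble that regresses response
#' maps on tuning features across participants.  With the defaults the
#' ensemble comprises `k_folds * repetitions = 50` models; participants
#' are the bootstrap unit (each model bootstraps the out-of-fold
#' participants with replacement), each drawn participant additionally
#' has `run_bootstrap` localizer runs bootstrapped and averaged, and a
#' single penalty is selected from `lambda_grid` (21 values log-spaced
#' between 0.01 and 100) by out-of-bag squared error pooled over models.
#' Setting `k_folds = 1` disables the fold partition and the participant
#' bootstrap, reducing the ensemble to plain ridge fits (useful for
#' oracle checks and single-participant designs).
#'
#' @param k_folds folds over participants (default 5).
#' @param repetitions k-fold repetitions (default 10).
#' @param lambda_grid candidate ridge penalties.
#' @param run_bootstrap number of runs drawn with replacement per chosen
#'   participant (0 = use the averaged map as is).
#' @param seed RNG seed.
#' @export
ensemble_regression_config <- function(k_folds = 5L, repetitions = 10L,
                                       lambda_grid = 10^seq(-2, 2,
                                                            length.out = 21),
                                       run_bootstrap = 4L, seed = 1L) {
  if (k_folds < 1) stop("k_folds must be >= 1")
  if (any(lambda_grid <= 0)) stop("lambda_grid must be positive")
  structure(list(k_folds = as.integer(k_folds),
                 repetitions = as.integer(repetitions),
                 lambda_grid = lambda_grid,
                 run_bootstrap = as.integer(run_bootstrap),
                 seed = as.integer(seed),
                 models_total = as.integer(k_folds) * as.integer(repetitions)),
            class = "ensemble_regression_config")
}

# Ridge path over a penalty grid from one SVD of the design matrix.
ridge_path <- function(X, y, lambda_grid) {
  s <- svd(X)
  uy <- crossprod(s$u, y)
  vapply(lambda_grid, function(l)
    as.numeric(s$v %*% (uy * s$d / (s$d^2 + l))), numeric(ncol(X)))
}

#' Estimate stimulus descriptors for a new condition
#'
#' Regresses training participants' selectivity maps on their tuning
#' features to recover the condition's stimulus descriptor (a k-vector):
#' the map is modeled as `descriptor %*% T_p` at every vertex, so across
#' the concatenated vertices of several participants the descriptor is
#' the coefficient vector of a linear regression.  A bagged ridge
#' ensemble (participant bootstrap, optional run bootstrap,
#' out-of-bag-selected penalty) is used instead of ordinary least squares
#' for accuracy and generalizability; the final descriptor averages the
#' model coefficients at the selected penalty.
#'
#' @param maps list of [selectivity_map()]s, one per training participant.
#' @param tunings list of `tuning_matrix` objects in the same order,
#'   sharing one basis.
#' @param cfg an [ensemble_regression_config()].
#' @return Numeric k-vector of descriptors.
#' @export
estimate_contrast_descriptor <- function(maps, tunings,
                                         cfg = ensemble_regression_config()) {
  check_same_basis(tunings)
  n <- length(maps)
  stopifnot(n == length(tunings), n >= 1)
  if (cfg$k_folds > 1 && n < 2)
    stop("participant-bootstrapped ensembles need at least 2 participants")
  k <- nrow(tunings[[1]]$data)
  Xs <- lapply(tunings, function(tm) t(tm$data))
  avg_map <- function(m) {
    if (is.null(m$run_maps)) m$values
    else Reduce(`+`, m$run_maps) / length(m$run_maps)
  }
  ys <- lapply(maps, avg_map)
  nl <- length(cfg$lambda_grid)
  betas <- array(0, c(k, nl, cfg$models_total))
  oob_err <- matrix(NA_real_, cfg$models_total, nl)
  with_seed(cfg$seed, {
    mi <- 0L
    for (rep_i in seq_len(cfg$repetitions)) {
      fold_of <- if (cfg$k_folds > 1)
        sample(rep(seq_len(cfg$k_folds), length.out = n)) else rep(0L, n)
      for (fold in seq_len(cfg$k_folds)) {
        mi <- mi + 1L
        cand <- which(fold_of != fold)
        chosen <- if (cfg$k_folds > 1)
          sample(cand, length(cand), replace = TRUE) else cand
        yparts <- lapply(chosen, function(p) {
          m <- maps[[p]]
          if (!is.null(m$run_maps) && cfg$run_bootstrap > 0 &&
              cfg$k_folds > 1) {
            runs <- sample(length(m$run_maps), cfg$run_bootstrap,
                           replace = TRUE)
            Reduce(`+`, m$run_maps[runs]) / cfg$run_bootstrap
          } else avg_map(m)
        })
        X <- do.call(rbind, Xs[chosen])
        y <- unlist(yparts)
        betas[, , mi] <- ridge_path(X, y, cfg$lambda_grid)
        oob <- setdiff(seq_len(n), chosen)
        if (length(oob)) {
          Xo <- do.call(rbind, Xs[oob])
          yo <- unlist(ys[oob])
          oob_err[mi, ] <- colMeans((yo - Xo %*% betas[, , mi])^2)
        }
      }
    }
  })
  mean_err <- colMeans(oob_err, na.rm = TRUE)
  best <- if (all(is.na(mean_err))) 1L else which.min(mean_err)
  rowMeans(betas[, best, , drop = FALSE], dims = 1)
}

#' Predict an individualized selectivity map
#'
#' The model-predicted map for a participant is simply the estimated
#' stimulus descriptor times the participant's tuning matrix.
#'
#' @param descriptor k-vector from [estimate_contrast_descriptor()].
#' @param tuning the participant's `tuning_matrix`.
#' @param condition contrast label for the returned map.
#' @return A [selectivity_map()].
#' @export
predict_selectivity_map <- function(descriptor, tuning,
                                    condition = "predicted") {
  stopifnot(inherits(tuning, "tuning_matrix"))
  if (length(descriptor) != nrow(tuning$data))
    stop("descriptor length does not match the tuning basis")
  selectivity_map(as.numeric(descriptor %*% tuning$data),
                  subject_id = tuning$subject_id, condition = condition)
}
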