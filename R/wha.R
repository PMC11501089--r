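#' Bagging configuration for warp hyperalignment
#'
#' Parameters of the k-fold bagging ensemble used to regularize the local
#' ridge transformations: time points are grouped into short segments,
#' segments are assigned to k folds, and each fold trains one ridge model
#' on a bootstrap (with replacement) of the non-held-out time points that
#' are at least `buffer_seconds` away from every held-out point.  The
#' scheme is repeated `repetitions` times, giving
#' `k_folds * repetitions` models in total (100 by default) whose
#' coefficients are averaged.
#'
#' @param k_folds number of folds per repetition (default 5).
#' @param repetitions number of k-fold repetitions (default 20).
#' @param buffer_seconds minimum temporal gap in seconds between any
#'   training and any test time point within a run (default 10); guards
#'   against temporal autocorrelation from the hemodynamic response.
#' @param segment_seconds segment length in seconds used to group time
#'   points before fold assignment (default 10).
#' @param seed integer seed for the fold/bootstrap randomization.
#' @export
bagging_config <- function(k_folds = 5L, repetitions = 20L,
                           buffer_seconds = 10, segment_seconds = 10,
                           seed = 1L) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (buffer_seconds < 0 || segment_seconds <= 0)
    stop("buffer must be >= 0 and segment length > 0")
  structure(list(k_folds = as.integer(k_folds),
                 repetitions = as.integer(repetitions),
                 buffer_seconds = buffer_seconds,
                 segment_seconds = segment_seconds,
                 seed = as.integer(seed),
                 models_total = as.integer(k_folds) * as.integer(repetitions)),
            class = "bagging_config")
}

#' Build a k-fold bagging plan over time points
#'
#' Groups time points into segments of `segment_seconds` (segments never
#' span run boundaries), randomly assigns segments to folds, and for each
#' fold draws a bootstrap training sample from the time points more than
#' `buffer_seconds` away (within-run) from every candidate test point.
#' Time points eligible for out-of-bag evaluation of a model are the
#' candidate test points plus any unsampled candidate training points
#' that are more than the buffer away from every sampled training point.
#' Every time point is a candidate test point in exactly one fold per
#' repetition, so each point has at least `repetitions` out-of-bag
#' models.
#'
#' @param t_time number of time points.
#' @param tr_seconds sampling interval in seconds.
#' @param cfg a [bagging_config()].
#' @param run_boundaries 0-based indices of run starts.
#' @return A `fold_plan`: list with `models` (each with `repetition`,
#'   `fold`, `train_idx` (bootstrapped, with duplicates), `test_idx`),
#'   `segment_of` (segment id per time point), `fold_of` (repetitions x
#'   segments fold assignment), and the configuration.
#' @export
make_fold_plan <- function(t_time, tr_seconds, cfg = bagging_config(),
                           run_boundaries = 0L) {
  if (t_time * tr_seconds < cfg$k_folds * cfg$segment_seconds)
    stop("time series too short for the requested fold configuration")
  seg_len <- max(1L, as.integer(ceiling(cfg$segment_seconds / tr_seconds)))
  run_of <- run_labels(t_time, run_boundaries)
  segment_of <- integer(t_time)
  seg <- 0L
  for (r in unique(run_of)) {
    idx <- which(run_of == r)
    segment_of[idx] <- seg + (seq_along(idx) - 1L) %/% seg_len + 1L
    seg <- max(segment_of[idx])
  }
  n_seg <- seg
  buffer_tr <- cfg$buffer_seconds / tr_seconds
  pos <- seq_len(t_time)
  models <- vector("list", cfg$models_total)
  fold_of <- matrix(0L, cfg$repetitions, n_seg)
  with_seed(cfg$seed, {
    mi <- 0L
    for (rep_i in seq_len(cfg$repetitions)) {
      fold_of[rep_i, ] <- sample(rep(seq_len(cfg$k_folds),
                                     length.out = n_seg))
      for (fold in seq_len(cfg$k_folds)) {
        cand_test <- which(fold_of[rep_i, segment_of] == fold)
        # gap to nearest candidate-test point, within run; cross-run
        # pairs are treated as infinitely far apart
        gap <- gap_to_set(pos, run_of, cand_test)
        cand_train <- which(gap > buffer_tr)
        if (!length(cand_train))
          stop("buffer leaves no candidate training points; reduce buffer_seconds")
        boot <- sort(sample(cand_train, length(cand_train), replace = TRUE))
        gap_tr <- gap_to_set(pos, run_of, unique(boot))
        unsampled <- setdiff(cand_train, boot)
        eligible <- sort(c(cand_test,
                           unsampled[gap_tr[unsampled] > buffer_tr]))
        mi <- mi + 1L
        models[[mi]] <- list(repetition = rep_i, fold = fold,
                             train_idx = boot, test_idx = eligible)
      }
    }
  })
  structure(list(models = models, segment_of = segment_of,
                 fold_of = fold_of, t_time = t_time,
                 tr_seconds = tr_seconds, cfg = cfg,
                 run_of = run_of),
            class = "fold_plan")
}

# For each time point, temporal distance (in TRs) to the nearest member of
# `set` in the same run; Inf if the run contains no member of `set`.
gap_to_set <- function(pos, run_of, set) {
  gap <- rep(Inf, length(pos))
  for (r in unique(run_of)) {
    in_run <- which(run_of == r)
    s <- intersect(set, in_run)
    if (!length(s)) next
    # distances to a sorted set via findInterval
    s <- sort(s)
    below <- findInterval(in_run, s)
    d_lo <- ifelse(below >= 1, in_run - s[pmax(below, 1)], Inf)
    d_hi <- ifelse(below < length(s), s[pmin(below + 1L, length(s))] - in_run,
                   Inf)
    gap[in_run] <- pmin(d_lo, d_hi)
  }
  gap
}

#' Ridge regression coefficients
#'
#' Closed-form ridge solution `(X'X + lambda I)^-1 X'Y` without an
#' intercept (inputs are assumed z-scored).
#'
#' @param X predictor matrix (m x q).
#' @param Y response matrix (m x p) or vector.
#' @param lambda positive regularization parameter.
#' @export
ridge_fit <- function(X, Y, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  Y <- as.matrix(Y)
  g <- crossprod(X)
  diag(g) <- diag(g) + lambda
  solve(g, crossprod(X, Y))
}

#' Bagged local ridge transformation
#'
#' Ensemble estimate of the searchlight-level linear map from the local
#' template to a participant's local data: one ridge model per bagging
#' model, each trained on its bootstrapped rows, with the coefficient
#' matrices averaged.
#'
#' @param M_sl local template block (time x v_sl).
#' @param B_sl participant block (time x v_sl).
#' @param plan a [make_fold_plan()] for the same time axis.
#' @param lambda ridge penalty (default 1e3).
#' @return v_sl x v_sl matrix of averaged ridge coefficients.
#' @export
fit_local_transform <- function(M_sl, B_sl, plan, lambda = 1e3) {
  stopifnot(inherits(plan, "fold_plan"), nrow(M_sl) == plan$t_time,
            identical(dim(M_sl), dim(B_sl)))
  acc <- matrix(0, ncol(M_sl), ncol(M_sl))
  for (m in plan$models) {
    acc <- acc + ridge_fit(M_sl[m$train_idx, , drop = FALSE],
                           B_sl[m$train_idx, , drop = FALSE], lambda)
  }
  acc / length(plan$models)
}

#' Fit a whole-brain warp-hyperalignment transformation
#'
#' Models the participant's data matrix as the functional template times a
#' sparse linear transformation, `B ~ M W`.  For each searchlight a local
#' transformation is estimated by bagged ridge regression
#' ([fit_local_transform()]) and the local estimates are combined
#' column-wise (per target vertex) by the distance-based weighted average
#' used for template aggregation.  Entries of `W` that never co-occur
#' with the target vertex in a searchlight are exactly zero.
#'
#' Unlike the orthogonal Procrustes transformation of classic
#' hyperalignment, the ridge-estimated `W` admits scaling and shearing,
#' so it can warp the template's representational geometry toward the
#' participant's in addition to resolving topographic differences.
#'
#' @param template a `functional_template` (or time x vertex matrix).
#' @param ts the participant's z-scored [subject_timeseries()].
#' @param geom the [surface_geometry()].
#' @param radius searchlight radius in mm.
#' @param lambda ridge penalty (default 1e3).
#' @param bagging a [bagging_config()].
#' @param searchlights optional precomputed searchlights.
#' @param plan optional precomputed [make_fold_plan()] (overrides
#'   `bagging`).
#' @param engine `"cpp"` (fast path) or `"r"` (reference implementation).
#' @return A `whole_brain_transform`: list with `subject_id`, `W` (sparse
#'   dgCMatrix, source vertex x target vertex), `lambda`, `bagging`.
#' @export
fit_wha <- function(template, ts, geom, radius = 20, lambda = 1e3,
                    bagging = bagging_config(), searchlights = NULL,
                    plan = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  M <- if (inherits(template, "functional_template")) template$data else template
  stopifnot(inherits(ts, "subject_timeseries"))
  if (nrow(M) != nrow(ts$data))
    stop("template and participant data have different numbers of time points")
  if (is.null(searchlights)) searchlights <- build_searchlights(geom, radius)
  if (is.null(plan))
    plan <- make_fold_plan(nrow(ts$data), ts$tr_seconds, bagging,
                           ts$run_boundaries)
  members <- lapply(searchlights, `[[`, "members")
  weights <- lapply(searchlights, function(sl)
    aggregation_weight(sl$distances, sl$radius))
  if (engine == "cpp") {
    boot <- lapply(plan$models, `[[`, "train_idx")
    W <- cpp_fit_wha_multi(M, list(ts$data), boot, members, weights,
                           lambda)[[1]]
  } else {
    v <- ncol(M)
    num <- matrix(0, v, v)
    den <- numeric(v)
    for (s in seq_along(searchlights)) {
      mem <- members[[s]]
      Wsl <- fit_local_transform(M[, mem, drop = FALSE],
                                 ts$data[, mem, drop = FALSE], plan, lambda)
      num[mem, mem] <- num[mem, mem] + sweep(Wsl, 2, weights[[s]], "*")
      den[mem] <- den[mem] + weights[[s]]
    }
    W <- sweep(num, 2, den, "/")
  }
  structure(list(subject_id = ts$subject_id,
                 W = methods::as(methods::as(Matrix::Matrix(W), "CsparseMatrix"),
                                 "generalMatrix"),
                 lambda = lambda, bagging = plan$cfg, radius = radius),
            class = "whole_brain_transform")
}

# Batched warp fits for several participants sharing one template and
# fold plan; returns dense v x v matrices.  The shared local Gram
# factorizations make this much faster than separate fit_wha() calls.
fit_wha_cohort <- function(M, data_list, searchlights, plan, lambda) {
  members <- lapply(searchlights, `[[`, "members")
  weights <- lapply(searchlights, function(sl)
    aggregation_weight(sl$distances, sl$radius))
  boot <- lapply(plan$models, `[[`, "train_idx")
  cpp_fit_wha_multi(M, data_list, boot, members, weights, lambda)
}

#' @export
print.whole_brain_transform <- function(x, ...) {
  cat(sprintf("<whole_brain_transform '%s': %d x %d, %.1f%% nonzero, lambda = %g>\n",
              x$subject_id, nrow(x$W), ncol(x$W),
              100 * Matrix::nnzero(x$W) / prod(dim(x$W)), x$lambda))
  invisible(x)
}

#' Apply a whole-brain transformation to the template
#'
#' Returns the modeled response matrix `M W`, the portion of the
#' participant's responses accounted for by the linearly transformed
#' template.
#'
#' @param template `functional_template` or time x vertex matrix.
#' @param transform `whole_brain_transform` or a v x v matrix.
#' @export
apply_transform <- function(template, transform) {
  M <- if (inherits(template, "functional_template")) template$data else template
  W <- if (inherits(transform, "whole_brain_transform")) transform$W else transform
  if (ncol(M) != nrow(W)) stop("shape mismatch between template and transform")
  as.matrix(M %*% W)
}

#' Procrustes baseline transformation
#'
#' Same searchlight-and-aggregate scheme as [fit_wha()], but each local
#' transformation is the orthogonal Procrustes solution instead of a
#' bagged ridge fit.  This is the classic rotation-only hyperalignment
#' baseline: it resolves topography but cannot warp representational
#' geometry.
#'
#' @inheritParams fit_wha
#' @export
fit_procrustes_baseline <- function(template, ts, geom, radius = 20,
                                    searchlights = NULL) {
  M <- if (inherits(template, "functional_template")) template$data else template
  stopifnot(inherits(ts, "subject_timeseries"))
  if (nrow(M) != nrow(ts$data))
    stop("template and participant data have different numbers of time points")
  if (is.null(searchlights)) searchlights <- build_searchlights(geom, radius)
  v <- ncol(M)
  num <- matrix(0, v, v)
  den <- numeric(v)
  for (sl in searchlights) {
    mem <- sl$members
    R <- procrustes_solve(M[, mem, drop = FALSE],
                          ts$data[, mem, drop = FALSE])
    w <- aggregation_weight(sl$distances, sl$radius)
    num[mem, mem] <- num[mem, mem] + sweep(R, 2, w, "*")
    den[mem] <- den[mem] + w
  }
  W <- sweep(num, 2, den, "/")
  structure(list(subject_id = ts$subject_id,
                 W = methods::as(methods::as(Matrix::Matrix(W), "CsparseMatrix"),
                                 "generalMatrix"),
                 lambda = NA_real_, bagging = NULL, radius = radius),
            class = "whole_brain_transform")
}
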