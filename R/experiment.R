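#' Leave-one-subject-out experiment driver
#'
#' For each fold, a functional template and stimulus basis are built from
#' the n-1 training participants and the requested evaluation arms are
#' run for the left-out participant:
#'
#' * `"identification"` -- every participant's tuning matrix is estimated
#'   from each half of the time series under the fold's template; the
#'   test participant's distinctiveness index and nearest-neighbor
#'   identification outcome are recorded.
#' * `"movie"` -- the test participant's tuning is estimated from the
#'   first half only, held-out second-half patterns are predicted from
#'   the stimulus basis, and binary/multiclass time-point classification
#'   accuracies are computed on PCA-reduced patterns.
#' * `"maps"` -- requires `localizer`; a stimulus descriptor is estimated
#'   from the training participants' maps and tunings, and the predicted
#'   map is correlated with the test participant's localizer map (within
#'   subject) and with the other participants' predicted maps swapped in
#'   (between subjects).
#'
#' Fully deterministic given `seed`.
#'
#' @param cohort list of [subject_timeseries()].
#' @param geom a [surface_geometry()].
#' @param arms character subset of `c("identification", "movie", "maps")`.
#' @param localizer list of [selectivity_map()] (one per participant),
#'   needed for the `"maps"` arm.
#' @param radius,lambda,seed model parameters, see [int_fit()].
#' @param n_components PCA components for the movie arm.
#' @param ensemble an [ensemble_regression_config()] for the maps arm.
#' @param verbose print progress.
#' @return List with `folds` (per-fold results) and `summary`
#'   (aggregated data frame, one row per participant).
#' @export
run_loso_experiment <- function(cohort, geom,
                                arms = c("identification", "movie"),
                                localizer = NULL, radius = 20,
                                lambda = 1e3, seed = 1L,
                                n_components = 10,
                                ensemble = NULL, verbose = FALSE) {
  n <- length(cohort)
  if (n < 3) stop("leave-one-subject-out needs at least 3 participants")
  arms <- match.arg(arms, c("identification", "movie", "maps"),
                    several.ok = TRUE)
  if ("maps" %in% arms && is.null(localizer))
    stop("the maps arm requires `localizer`")
  folds <- vector("list", n)
  for (test in seq_len(n)) {
    if (verbose) message(sprintf("fold %d/%d", test, n))
    fit <- int_fit(cohort, geom, radius = radius, lambda = lambda,
                   seed = substream_seed(seed, sprintf("fold-%d", test)),
                   split = TRUE, template_subjects = setdiff(seq_len(n), test))
    res <- list(test_subject = cohort[[test]]$subject_id)
    if ("identification" %in% arms) {
      sim <- tuning_similarity_matrix(coef(fit, 1), coef(fit, 2))
      res$distinctiveness <- suppressWarnings(distinctiveness_index(sim, test))
      res$identified <- which.max(sim$values[test, ]) == test
      res$within <- sim$values[test, test]
      res$between <- mean(sim$values[test, -test])
    }
    if ("movie" %in% arms) {
      rows2 <- seq(length(fit$halves[[1]]) + 1L,
                   length.out = length(fit$halves[[2]]))
      predicted <- predict_movie_patterns(stimulus_rows(fit$stimulus, rows2),
                                          fit$tunings[[test]][[1]])
      measured1 <- cohort[[test]]$data[fit$halves[[1]], , drop = FALSE]
      measured2 <- cohort[[test]]$data[fit$halves[[2]], , drop = FALSE]
      red <- reduce_patterns_pca(measured1, list(measured2, predicted),
                                 n_components = n_components)
      res$binary_accuracy <- classify_timepoints_binary(red$applied[[1]],
                                                        red$applied[[2]])
      res$multiclass_accuracy <-
        classify_timepoints_multiclass(red$applied[[1]], red$applied[[2]])
    }
    if ("maps" %in% arms) {
      train <- setdiff(seq_len(n), test)
      cfg <- if (is.null(ensemble))
        ensemble_regression_config(seed = substream_seed(seed,
                                                         sprintf("maps-%d", test)))
      else ensemble
      desc <- estimate_contrast_descriptor(localizer[train],
                                           coef(fit, 1)[train], cfg)
      pred <- predict_selectivity_map(desc, fit$tunings[[test]][[1]])
      res$map_correlation <- vcor(pred$values, localizer[[test]]$values)
      others <- vapply(setdiff(seq_len(n), test), function(q) {
        vcor(predict_selectivity_map(desc, fit$tunings[[q]][[1]])$values,
             localizer[[test]]$values)
      }, 1)
      res$map_correlation_between <- mean(others)
    }
    folds[[test]] <- res
  }
  summary_df <- do.call(rbind, lapply(folds, function(r)
    as.data.frame(r[vapply(r, function(x) length(x) == 1, TRUE)])))
  list(folds = folds, summary = summary_df)
}

#' Data-volume sweep of tuning distinctiveness
#'
#' Refits the split-half tuning estimates with each half truncated to a
#' series of durations and records reliability, distinctiveness, and
#' identification accuracy as a function of data volume.  The template
#' is rebuilt from the full data each time; only the per-participant
#' transformation and tuning estimation see less data.
#'
#' @param cohort list of [subject_timeseries()].
#' @param geom a [surface_geometry()].
#' @param durations_minutes vector of per-half durations to evaluate.
#' @param radius,lambda,seed model parameters.
#' @param bagging optional [bagging_config()] forwarded to [int_fit()].
#' @param verbose print progress.
#' @return Data frame with one row per duration.
#' @export
run_volume_sweep <- function(cohort, geom, durations_minutes, radius = 20,
                             lambda = 1e3, seed = 1L, bagging = NULL,
                             verbose = FALSE) {
  if (!length(durations_minutes)) stop("no durations given")
  tr <- cohort[[1]]$tr_seconds
  t_half <- floor(nrow(cohort[[1]]$data) / 2)
  rows <- lapply(durations_minutes, function(m) {
    ntr <- as.integer(floor(m * 60 / tr))
    if (ntr < 2 || ntr > t_half) {
      warning(sprintf("duration %g min outside the available data; skipped", m))
      return(NULL)
    }
    ntr
  })
  keep <- !vapply(rows, is.null, TRUE)
  # template, full-series transformations, and the stimulus basis do not
  # depend on the truncation; build them once
  base <- int_fit(cohort, geom, radius = radius, lambda = lambda,
                  bagging = bagging, seed = seed, split = TRUE,
                  verbose = verbose)
  searchlights <- build_searchlights(geom, radius)
  cohort_n <- lapply(cohort, normalize_timeseries)
  cut <- floor(nrow(cohort[[1]]$data) / 2)
  out <- lapply(which(keep), function(i) {
    if (verbose) message(sprintf("duration %g min", durations_minutes[i]))
    halves <- lapply(list(seq_len(cut), cut + seq_len(cut)),
                     function(h) h[seq_len(rows[[i]])])
    est <- tryCatch(
      estimate_half_tunings(base$template, base$stimulus, cohort_n,
                            searchlights, halves, lambda, bagging, seed,
                            radius),
      error = function(e) {
        warning(sprintf("duration %g min: %s; skipped",
                        durations_minutes[i], conditionMessage(e)))
        NULL
      })
    if (is.null(est)) return(NULL)
    sim <- tuning_similarity_matrix(lapply(est$tunings, `[[`, 1),
                                    lapply(est$tunings, `[[`, 2))
    d <- vapply(seq_along(cohort), function(p)
      suppressWarnings(distinctiveness_index(sim, p)), 1)
    data.frame(duration_minutes = durations_minutes[i],
               n_tr_per_half = rows[[i]],
               within = mean(diag(sim$values)),
               between = mean(sim$values[row(sim$values) !=
                                         col(sim$values)]),
               mean_distinctiveness = mean(d),
               identification_accuracy = identification_accuracy(sim))
  })
  do.call(rbind, out)
}

#' Recovery report on a synthetic cohort
#'
#' Generates a cohort from a [cohort_spec()], fits the full model, and
#' tabulates how well the pipeline recovers the ground truth: split-half
#' tuning reliability and identification, agreement between estimated
#' and true tuning structure (correlation of modeled and true noiseless
#' responses), and, optionally, distinctiveness across a data-volume
#' sweep.
#'
#' @param spec a [cohort_spec()].
#' @param durations_minutes optional vector for a volume sweep.
#' @param radius,lambda,seed model parameters.
#' @param bagging optional [bagging_config()] forwarded to [int_fit()].
#' @param verbose print progress.
#' @return List with `identification` (summary of the full-data fit),
#'   `signal_recovery` (per-participant correlation between modeled and
#'   true noiseless responses), and `sweep` (data frame or `NULL`).
#' @export
recovery_report <- function(spec, durations_minutes = NULL, radius = 20,
                            lambda = 1e3, seed = 1L, bagging = NULL,
                            verbose = FALSE) {
  sim <- make_cohort(spec)
  fit <- int_fit(sim$cohort, spec$geometry, radius = radius,
                 lambda = lambda, bagging = bagging, seed = seed,
                 verbose = verbose)
  s <- summary(fit)
  recov <- vapply(seq_along(sim$cohort), function(p) {
    truth_p <- sim$truth$S_true %*% sim$truth$T_true[[p]]
    if (!is.null(sim$truth$W_true)) truth_p <- truth_p %*% sim$truth$W_true[[p]]
    modeled <- do.call(rbind, lapply(seq_along(fit$halves), function(h)
      as.matrix(fit$template$data[fit$halves[[h]], , drop = FALSE] %*%
                fit$transforms[[p]][[h]]$W)))
    rows <- unlist(fit$halves)
    vcor(as.numeric(modeled), as.numeric(truth_p[rows, , drop = FALSE]))
  }, 1)
  sweep_df <- if (!is.null(durations_minutes))
    run_volume_sweep(sim$cohort, spec$geometry, durations_minutes,
                     radius = radius, lambda = lambda, seed = seed,
                     bagging = bagging, verbose = verbose)
  else NULL
  list(identification = s, signal_recovery = recov, sweep = sweep_df,
       spec = spec)
}
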