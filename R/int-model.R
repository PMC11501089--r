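#' Fit an individualized neural tuning model
#'
#' End-to-end estimation for a cohort sharing one stimulus time axis:
#'
#' 1. a group functional template is built from the (z-scored) training
#'    participants with the searchlight PCA-Procrustes algorithm
#'    ([build_template()]);
#' 2. each participant's data are modeled as the linearly transformed
#'    template via warp hyperalignment ([fit_wha()]);
#' 3. the modeled responses of the training participants are decomposed
#'    into a shared orthogonal stimulus matrix
#'    ([compute_stimulus_matrix()]) and per-participant tuning matrices
#'    ([estimate_tuning()]).
#'
#' The stimulus basis is always computed from the training participants'
#' full-series modeled responses (one transformation per training
#' participant, fit on all time points).  This matters: the basis must
#' carry structure that spans the whole time axis, otherwise tuning
#' matrices estimated from disjoint time ranges would live in unrelated
#' (in the degenerate full-rank case, exactly orthogonal) feature
#' subspaces and could not be compared.
#'
#' With `split = TRUE` (the default) the time axis is additionally
#' halved and each participant's transformation and tuning matrix are
#' re-estimated independently from each half (the basis is
#' row-restricted per half), so the two tuning estimates share no data
#' beyond the template and basis; this enables the split-half
#' reliability and participant-identification analyses of
#' [summary.int_model()].  `max_half_tr` truncates each half to its
#' first time points, for data-volume analyses.
#'
#' @param cohort list of [subject_timeseries()] with matching time axes.
#' @param geom a [surface_geometry()].
#' @param radius searchlight radius in mm (default 20).
#' @param lambda ridge penalty of the warp transformation (default 1e3).
#' @param bagging a [bagging_config()]; its seed is derived from `seed`
#'   when not supplied.
#' @param seed master seed for all randomized components.
#' @param split estimate transformations and tunings per half (default
#'   `TRUE`) or once from the full time series.
#' @param template_subjects indices of the participants used to build the
#'   template and the stimulus basis (default: all).
#' @param max_half_tr optional truncation of each half to its first
#'   `max_half_tr` time points.
#' @param normalize z-score the inputs first (default `TRUE`; idempotent).
#' @param engine `"cpp"` or `"r"` warp-fitting backend.
#' @param verbose print progress.
#' @return An object of class `int_model`.
#' @export
int_fit <- function(cohort, geom, radius = 20, lambda = 1e3, bagging = NULL,
                    seed = 1L, split = TRUE, template_subjects = NULL,
                    max_half_tr = NULL, normalize = TRUE,
                    engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(length(cohort) >= 1)
  tdims <- unique(vapply(cohort, function(s) nrow(s$data), 1L))
  if (length(tdims) != 1)
    stop("participants have mismatched numbers of time points")
  t_time <- tdims
  if (normalize) cohort <- lapply(cohort, normalize_timeseries)
  if (is.null(template_subjects)) template_subjects <- seq_along(cohort)
  tr <- cohort[[1]]$tr_seconds
  subjects <- vapply(cohort, `[[`, "", "subject_id")

  searchlights <- build_searchlights(geom, radius)
  if (verbose) message("building functional template...")
  template <- build_template(cohort[template_subjects], geom, radius,
                             searchlights = searchlights)

  sub_cfg <- function(label) derive_bagging(bagging, seed, label)
  mk_transform <- function(W, p, cfg_used)
    new_wbt(W, subjects[p], lambda, cfg_used, radius)

  # full-series transformations of the training participants define the
  # modeled responses that the stimulus basis is computed from
  full_subjects <- if (split) template_subjects else seq_along(cohort)
  if (verbose) message("warp hyperalignment (full series)...")
  cfg_full <- sub_cfg("wha-full")
  plan_full <- make_fold_plan(t_time, tr, cfg_full,
                              cohort[[1]]$run_boundaries)
  W_full <- fit_wha_cohort(template$data,
                           lapply(cohort[full_subjects], `[[`, "data"),
                           searchlights, plan_full, lambda)
  names(W_full) <- as.character(full_subjects)
  modeled_full <- lapply(W_full, function(W) template$data %*% W)
  if (verbose) message("computing stimulus basis...")
  stimulus <- compute_stimulus_matrix(
    modeled_full[as.character(intersect(full_subjects, template_subjects))])

  transforms_full <- lapply(seq_along(cohort), function(p) {
    key <- as.character(p)
    if (key %in% names(W_full)) mk_transform(W_full[[key]], p, cfg_full)
    else NULL
  })

  halves <- if (split) {
    cut <- floor(t_time / 2)
    list(seq_len(cut), (cut + 1L):t_time)
  } else list(seq_len(t_time))
  if (!is.null(max_half_tr))
    halves <- lapply(halves, function(h) h[seq_len(min(max_half_tr,
                                                       length(h)))])

  if (split) {
    est <- estimate_half_tunings(template, stimulus, cohort, searchlights,
                                 halves, lambda, bagging, seed, radius,
                                 verbose = verbose)
    transforms_half <- est$transforms
    tunings <- est$tunings
  } else {
    transforms_half <- NULL
    rows <- halves[[1]]
    S_r <- stimulus_rows(stimulus, rows)
    tunings <- lapply(seq_along(cohort), function(p)
      list(estimate_tuning(S_r,
                           as.matrix(template$data[rows, , drop = FALSE] %*%
                                     transforms_full[[p]]$W),
                           subject_id = subjects[p])))
  }

  structure(list(template = template, stimulus = stimulus,
                 transforms = transforms_half,
                 transforms_full = transforms_full, tunings = tunings,
                 subjects = subjects, halves = halves, split = split,
                 geom = geom, radius = radius, lambda = lambda,
                 seed = seed, template_subjects = template_subjects,
                 call = match.call()),
            class = "int_model")
}

half_run_boundaries <- function(run_boundaries, rows) {
  lab <- run_labels(max(rows), run_boundaries)[rows]
  as.integer(which(!duplicated(lab)) - 1L)
}

derive_bagging <- function(bagging, seed, label) {
  if (is.null(bagging)) bagging_config(seed = substream_seed(seed, label))
  else {
    b <- bagging
    b$seed <- substream_seed(seed, paste0(label, "-", bagging$seed))
    b
  }
}

new_wbt <- function(W, subject_id, lambda, cfg, radius) {
  structure(list(subject_id = subject_id,
                 W = methods::as(methods::as(Matrix::Matrix(W),
                                             "CsparseMatrix"),
                                 "generalMatrix"),
                 lambda = lambda, bagging = cfg, radius = radius),
            class = "whole_brain_transform")
}

# Per-half transformation and tuning estimation shared by int_fit() and
# run_volume_sweep(): the template and stimulus basis are fixed inputs,
# only the per-participant half fits are recomputed.
estimate_half_tunings <- function(template, stimulus, cohort, searchlights,
                                  halves, lambda, bagging, seed, radius,
                                  verbose = FALSE) {
  subjects <- vapply(cohort, `[[`, "", "subject_id")
  tr <- cohort[[1]]$tr_seconds
  transforms <- rep(list(vector("list", length(halves))), length(cohort))
  tunings <- rep(list(vector("list", length(halves))), length(cohort))
  for (h in seq_along(halves)) {
    if (verbose) message(sprintf("warp hyperalignment (half %d)...", h))
    rows <- halves[[h]]
    rb <- half_run_boundaries(cohort[[1]]$run_boundaries, rows)
    cfg_h <- derive_bagging(bagging, seed,
                            sprintf("wha-half%d-n%d", h, length(rows)))
    plan_h <- make_fold_plan(length(rows), tr, cfg_h, rb)
    M_h <- template$data[rows, , drop = FALSE]
    W_h <- fit_wha_cohort(M_h,
                          lapply(cohort, function(s)
                            s$data[rows, , drop = FALSE]),
                          searchlights, plan_h, lambda)
    S_h <- stimulus_rows(stimulus, rows)
    for (p in seq_along(cohort)) {
      transforms[[p]][[h]] <- new_wbt(W_h[[p]], subjects[p], lambda, cfg_h,
                                      radius)
      tunings[[p]][[h]] <- estimate_tuning(S_h, M_h %*% W_h[[p]],
                                           subject_id = subjects[p])
    }
  }
  list(transforms = transforms, tunings = tunings)
}

#' @export
print.int_model <- function(x, ...) {
  cat(sprintf("<int_model: %d participants, %d time points x %d vertices, k = %d features>\n",
              length(x$subjects), nrow(x$template$data),
              ncol(x$template$data), ncol(x$stimulus$data)))
  cat(sprintf("  radius %g mm, lambda %g, %s\n", x$radius, x$lambda,
              if (x$split) "split-half tuning estimates" else "full-series tuning estimates"))
  invisible(x)
}

#' Tuning matrices of a fitted model
#'
#' @param object an `int_model`.
#' @param half which split (1 or 2) when the model was fit with
#'   `split = TRUE`; ignored otherwise.
#' @param ... unused.
#' @return List of `tuning_matrix` objects, one per participant.
#' @export
coef.int_model <- function(object, half = 1L, ...) {
  lapply(object$tunings, `[[`, min(half, length(object$tunings[[1]])))
}

#' Summarize reliability and distinctiveness of a fitted model
#'
#' For split-half fits, computes the cross-half tuning similarity matrix,
#' within- and between-subject similarity summaries, each participant's
#' distinctiveness index, the nearest-neighbor identification accuracy,
#' and the identification error rate implied by the mean distinctiveness.
#'
#' @param object an `int_model` fit with `split = TRUE`.
#' @param ... unused.
#' @export
summary.int_model <- function(object, ...) {
  if (!object$split)
    stop("summary requires a model fit with split = TRUE")
  sim <- tuning_similarity_matrix(coef(object, 1), coef(object, 2))
  n <- length(object$subjects)
  d <- vapply(seq_len(n), function(i)
    suppressWarnings(distinctiveness_index(sim, i)), 1)
  out <- list(similarity = sim,
              within = diag(sim$values),
              between_mean = mean(sim$values[row(sim$values) !=
                                             col(sim$values)]),
              distinctiveness = d,
              mean_distinctiveness = mean(d),
              identification_accuracy = identification_accuracy(sim),
              error_rate = identification_error_rate(mean(d)),
              subjects = object$subjects)
  class(out) <- "summary.int_model"
  out
}

#' @export
print.summary.int_model <- function(x, ...) {
  cat(sprintf("Split-half tuning reliability over %d participants\n",
              length(x$subjects)))
  cat(sprintf("  within-subject similarity : %.3f (mean; range %.3f-%.3f)\n",
              mean(x$within), min(x$within), max(x$within)))
  cat(sprintf("  between-subject similarity: %.3f (mean)\n", x$between_mean))
  cat(sprintf("  distinctiveness index     : %.2f (mean)\n",
              x$mean_distinctiveness))
  cat(sprintf("  identification accuracy   : %.1f%%\n",
              100 * x$identification_accuracy))
  cat(sprintf("  identification error rate : %.3g\n", x$error_rate))
  invisible(x)
}

#' Predict from a fitted tuning model
#'
#' `type = "patterns"` predicts response patterns for a subset of the
#' model's time points from a participant's tuning matrix (estimated
#' from the complementary data when `split = TRUE`).
#' `type = "selectivity"` and `type = "retinotopy"` forward to
#' [predict_selectivity_map()] / [predict_retinotopic_map()] given
#' descriptors estimated externally.
#'
#' @param object an `int_model`.
#' @param subject participant index or id.
#' @param type prediction type.
#' @param rows model time-point indices to predict (default: second
#'   half).
#' @param descriptor,descriptors_x,descriptors_y descriptor vectors for
#'   map predictions.
#' @param ... unused.
#' @export
predict.int_model <- function(object, subject = 1L,
                              type = c("patterns", "selectivity",
                                       "retinotopy"),
                              rows = NULL, descriptor = NULL,
                              descriptors_x = NULL, descriptors_y = NULL,
                              ...) {
  type <- match.arg(type)
  if (is.character(subject)) subject <- match(subject, object$subjects)
  if (is.na(subject)) stop("unknown subject")
  if (type == "patterns") {
    if (is.null(rows)) {
      if (!object$split) stop("specify `rows` for a full-series model")
      rows <- seq(length(object$halves[[1]]) + 1L,
                  length.out = length(object$halves[[2]]))
    }
    tun <- object$tunings[[subject]][[1]]
    return(predict_movie_patterns(stimulus_rows(object$stimulus, rows), tun))
  }
  tun <- object$tunings[[subject]][[1]]
  if (type == "selectivity") {
    if (is.null(descriptor)) stop("`descriptor` required")
    predict_selectivity_map(descriptor, tun)
  } else {
    if (is.null(descriptors_x) || is.null(descriptors_y))
      stop("`descriptors_x` and `descriptors_y` required")
    predict_retinotopic_map(descriptors_x, descriptors_y, tun, ...)
  }
}
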