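test_that("fold plans match the canonical 300-second example", {
  cfg <- bagging_config(k_folds = 5, repetitions = 1, seed = 2)
  plan <- make_fold_plan(300, 1, cfg)
  expect_identical(max(plan$segment_of), 30L)            # 30 segments
  expect_identical(as.integer(table(plan$fold_of[1, ])), rep(6L, 5))
  expect_length(plan$models, 5)
  for (m in plan$models) {
    gaps <- abs(outer(unique(m$train_idx), m$test_idx, "-"))
    expect_gt(min(gaps), 10)  # strictly more than the 10 s buffer at TR 1
    # bootstrap size equals the candidate-training count and may repeat
    expect_gte(length(m$train_idx), length(unique(m$train_idx)))
  }
})

test_that("every time point has at least `repetitions` out-of-bag models", {
  cfg <- bagging_config(k_folds = 5, repetitions = 20, seed = 3)
  plan <- make_fold_plan(300, 1, cfg)
  coverage <- integer(300)
  for (m in plan$models) coverage[m$test_idx] <- coverage[m$test_idx] + 1L
  expect_true(all(coverage >= 20))
})

test_that("fold plans are deterministic and respect run boundaries", {
  cfg <- bagging_config(k_folds = 3, repetitions = 2, buffer_seconds = 4,
                        seed = 11)
  p1 <- make_fold_plan(120, 2, cfg, run_boundaries = c(0L, 60L))
  p2 <- make_fold_plan(120, 2, cfg, run_boundaries = c(0L, 60L))
  expect_identical(p1, p2)
  # segments never span the run boundary
  expect_true(all(tapply(p1$run_of, p1$segment_of,
                         function(r) length(unique(r))) == 1))
  expect_error(make_fold_plan(120, 2, bagging_config(buffer_seconds = 500)),
               "buffer")
  expect_error(make_fold_plan(10, 1, bagging_config()), "too short")
})

test_that("ridge matches least squares as the penalty vanishes", {
  set.seed(5)
  X <- matrix(rnorm(50 * 4), 50, 4)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  ols <- qr.solve(X, Y)
  expect_equal(ridge_fit(X, Y, 1e-12), ols, tolerance = 1e-6)
  # identity design, lambda = 1 halves the response
  Yq <- matrix(rnorm(16), 4, 4)
  expect_equal(ridge_fit(diag(4), Yq, 1), Yq / 2, tolerance = 1e-12)
  # shrinkage: coefficient norm decreases monotonically in lambda
  norms <- vapply(10^seq(-2, 4), function(l) norm(ridge_fit(X, Y, l), "F"), 1)
  expect_true(all(diff(norms) < 0))
  expect_error(ridge_fit(X, Y, 0), "positive")
})

test_that("bagged local transforms recover constructed linear maps", {
  set.seed(6)
  M_sl <- matrix(rnorm(200 * 6), 200, 6)
  plan <- make_fold_plan(200, 1, bagging_config(seed = 4))
  # identity recovery
  W_id <- fit_local_transform(M_sl, M_sl, plan, lambda = 1e-6)
  expect_equal(W_id, diag(6), tolerance = 1e-3, ignore_attr = TRUE)
  # known map recovery within 5 percent
  G <- matrix(rnorm(36), 6, 6)
  W <- fit_local_transform(M_sl, M_sl %*% G, plan, lambda = 1e-4)
  expect_lt(norm(W - G, "F") / norm(G, "F"), 0.05)
})

test_that("ensemble mean equals a single fit for degenerate plans", {
  set.seed(7)
  M_sl <- matrix(rnorm(60 * 4), 60, 4)
  B_sl <- matrix(rnorm(60 * 4), 60, 4)
  plan <- make_fold_plan(60, 1, bagging_config(k_folds = 2, repetitions = 3,
                                               buffer_seconds = 0, seed = 8))
  idx <- plan$models[[1]]$train_idx
  for (m in seq_along(plan$models)) plan$models[[m]]$train_idx <- idx
  W <- fit_local_transform(M_sl, B_sl, plan, lambda = 2)
  W1 <- ridge_fit(M_sl[idx, ], B_sl[idx, ], 2)
  expect_equal(W, W1, tolerance = 1e-12)
})

test_that("whole-brain warp equals the local fit for one global searchlight", {
  set.seed(8)
  geom <- surface_geometry(cbind(runif(5), runif(5), 0))
  M <- matrix(rnorm(80 * 5), 80, 5)
  ts <- normalize_timeseries(subject_timeseries(matrix(rnorm(80 * 5), 80, 5)))
  cfg <- tiny_bagging(seed = 5)
  plan <- make_fold_plan(80, 1, cfg)
  wbt <- fit_wha(M, ts, geom, radius = 50, lambda = 10, plan = plan)
  sls <- build_searchlights(geom, 50)
  expect_identical(sls[[1]]$members, 1:5)
  W_local <- fit_local_transform(M, ts$data, plan, lambda = 10)
  expect_equal(as.matrix(wbt$W[, sls[[1]]$members]), W_local,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("R and C++ warp engines agree", {
  set.seed(9)
  geom <- grid_geometry(4, spacing_mm = 5)
  M <- matrix(rnorm(60 * 16), 60, 16)
  ts <- normalize_timeseries(subject_timeseries(matrix(rnorm(60 * 16), 60, 16)))
  plan <- make_fold_plan(60, 1, bagging_config(k_folds = 3, repetitions = 2,
                                               buffer_seconds = 2, seed = 10))
  w_cpp <- fit_wha(M, ts, geom, radius = 8, lambda = 5, plan = plan)
  w_r <- fit_wha(M, ts, geom, radius = 8, lambda = 5, plan = plan,
                 engine = "r")
  expect_equal(as.matrix(w_cpp$W), as.matrix(w_r$W), tolerance = 1e-10)
})

test_that("warp transforms are sparse on the searchlight pattern and exact on noiseless data", {
  sim <- make_cohort(cohort_spec(n_subjects = 3, t_time = 200, v_vertex = 25,
                                 k_latent = 6, noise_sd = 0, seed = 14))
  geom <- sim$truth$spec$geometry
  tmpl <- build_template(sim$cohort, geom, radius = 9)
  ts <- sim$cohort[[1]]
  wbt <- fit_wha(tmpl, ts, geom, radius = 9, lambda = 1e-3,
                 bagging = tiny_bagging(seed = 2))
  # structural sparsity: nonzeros only where vertices share a searchlight
  sls <- build_searchlights(geom, 9)
  allowed <- matrix(FALSE, 25, 25)
  for (sl in sls) allowed[sl$members, sl$members] <- TRUE
  expect_true(all(as.matrix(wbt$W != 0) <= allowed))
  # modeled responses track the participant closely
  Bhat <- apply_transform(tmpl, wbt)
  cors <- vapply(1:25, function(j) cor(Bhat[, j], ts$data[, j]), 1)
  expect_true(all(cors > 0.99))
})

test_that("identical seeds give identical transforms", {
  sim <- tiny_sim()
  geom <- sim$truth$spec$geometry
  tmpl <- build_template(sim$cohort[1:2], geom, radius = 12)
  w1 <- fit_wha(tmpl, sim$cohort[[3]], geom, radius = 12,
                bagging = tiny_bagging(seed = 77))
  w2 <- fit_wha(tmpl, sim$cohort[[3]], geom, radius = 12,
                bagging = tiny_bagging(seed = 77))
  expect_identical(as.matrix(w1$W), as.matrix(w2$W))
})

test_that("apply_transform is plain matrix multiplication", {
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(M, diag(3)), M, ignore_attr = TRUE)
  expect_true(all(apply_transform(M, matrix(0, 3, 3)) == 0))
  W <- matrix(rnorm(9), 3)
  expect_equal(apply_transform(M, W), M %*% W, ignore_attr = TRUE)
})

test_that("Procrustes baseline is orthogonal locally and identity on itself", {
  set.seed(10)
  geom <- surface_geometry(cbind(runif(6), runif(6), 0))
  M <- matrix(rnorm(100 * 6), 100, 6)
  ts <- subject_timeseries(M)   # B = M exactly, no normalization applied
  ts$data <- M
  wbt <- fit_procrustes_baseline(M, ts, geom, radius = 50)
  expect_equal(as.matrix(wbt$W), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # single global searchlight: the transform is exactly orthogonal
  ts2 <- normalize_timeseries(subject_timeseries(matrix(rnorm(600), 100, 6)))
  wbt2 <- fit_procrustes_baseline(M, ts2, geom, radius = 50)
  expect_equal(crossprod(as.matrix(wbt2$W)), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("warping beats rotation on geometry-warped synthetic data", {
  sim <- make_cohort(cohort_spec(n_subjects = 4, t_time = 200, v_vertex = 25,
                                 k_latent = 6, noise_sd = 0.1,
                                 topographic_warp = "local_rotation",
                                 seed = 15))
  geom <- sim$truth$spec$geometry
  tmpl <- build_template(sim$cohort[1:3], geom, radius = 12)
  ts <- sim$cohort[[4]]
  w_wha <- fit_wha(tmpl, ts, geom, radius = 12, lambda = 1,
                   bagging = tiny_bagging(seed = 3))
  w_pro <- fit_procrustes_baseline(tmpl, ts, geom, radius = 12)
  err <- function(w) norm(apply_transform(tmpl, w) - ts$data, "F")
  expect_lt(err(w_wha), err(w_pro))
})
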