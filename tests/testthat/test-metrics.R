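make_tuning_set <- function(n = 4, k = 10, v = 50, reliability = 1,
                            seed = 31) {
  set.seed(seed)
  S <- compute_stimulus_matrix(list(matrix(rnorm(40 * 4), 40, 4)))
  base <- lapply(1:n, function(p) matrix(rnorm(k * v), k, v))
  mk <- function(p, noise) {
    tm <- structure(list(subject_id = sprintf("s%d", p),
                         data = sqrt(reliability) * base[[p]] +
                           sqrt(1 - reliability) * matrix(rnorm(k * v), k, v) +
                           noise * matrix(rnorm(k * v), k, v),
                         basis_id = "shared"),
                    class = "tuning_matrix")
    tm
  }
  list(h1 = lapply(1:n, mk, noise = 0), h2 = lapply(1:n, mk, noise = 0),
       base = base)
}

test_that("similarity matrix has unit diagonal for identical estimates", {
  ts <- make_tuning_set()
  sim <- tuning_similarity_matrix(ts$h1, ts$h1)
  expect_equal(diag(sim$values), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(dim(sim$values), c(4L, 4L))
  # permuting participants permutes rows and columns consistently
  sim_perm <- tuning_similarity_matrix(ts$h1[c(2, 1, 3, 4)],
                                       ts$h1[c(2, 1, 3, 4)])
  expect_equal(sim_perm$values[1, 2], sim$values[2, 1], tolerance = 1e-12)
})

test_that("independent tuning matrices have near-zero similarity", {
  set.seed(32)
  mk <- function(p) structure(list(subject_id = sprintf("s%d", p),
                                   data = matrix(rnorm(1e4), 100),
                                   basis_id = "shared"),
                              class = "tuning_matrix")
  sim <- tuning_similarity_matrix(lapply(1:3, mk), lapply(4:6, mk))
  expect_lt(max(abs(sim$values)), 0.05)
})

test_that("distinctiveness follows the hand-computed Cohen's d", {
  z <- rbind(c(1.0, 0.4, 0.5, 0.6),
             c(0.4, 1.0, 0.5, 0.6),
             c(0.4, 0.5, 1.0, 0.6),
             c(0.4, 0.5, 0.6, 1.0))
  sim <- structure(list(values = tanh(z), fisher_z = z,
                        subjects = letters[1:4]),
                   class = "similarity_matrix")
  # subject 1: within z = 1.0, between {0.4, 0.5, 0.6}, sample SD 0.1
  expect_equal(distinctiveness_index(sim, 1), (1.0 - 0.5) / 0.1,
               tolerance = 1e-12)
  # within equal to the between mean gives zero
  z0 <- z; z0[1, 1] <- 0.5
  sim0 <- structure(list(values = tanh(z0), fisher_z = z0,
                         subjects = letters[1:4]),
                    class = "similarity_matrix")
  expect_equal(distinctiveness_index(sim0, 1), 0, tolerance = 1e-12)
  # monotone in the within similarity
  z2 <- z; z2[1, 1] <- 1.2
  sim2 <- structure(list(values = tanh(z2), fisher_z = z2,
                         subjects = letters[1:4]),
                    class = "similarity_matrix")
  expect_gt(distinctiveness_index(sim2, 1), distinctiveness_index(sim, 1))
  expect_error(distinctiveness_index(
    structure(list(values = diag(2), fisher_z = diag(2)),
              class = "similarity_matrix"), 1), "at least 3")
})

test_that("degenerate between-subject spread yields Inf with a warning", {
  z <- rbind(c(1, 0.5, 0.5), c(0.5, 1, 0.5), c(0.5, 0.5, 1))
  sim <- structure(list(values = tanh(z), fisher_z = z,
                        subjects = letters[1:3]),
                   class = "similarity_matrix")
  expect_warning(d <- distinctiveness_index(sim, 1), "zero spread")
  expect_identical(d, Inf)
})

test_that("identification error rate is the normal upper tail", {
  expect_identical(identification_error_rate(0), 0.5)
  d <- seq(-3, 8, by = 0.25)
  err <- identification_error_rate(d)
  expect_true(all(diff(err) < 0))
  expect_equal(identification_error_rate(d) +
                 identification_error_rate(-d),
               rep(1, length(d)), tolerance = 1e-12)
})

test_that("Cronbach's alpha behaves like the parallel-test model", {
  v <- 1e5
  expect_equal(cronbach_alpha(rep(list(rnorm(10)), 4)), 1, tolerance = 1e-12)
  set.seed(33)
  noise_maps <- lapply(1:4, function(i) rnorm(v))
  expect_lt(abs(cronbach_alpha(noise_maps)), 0.02)
  # true-score model with var(T) = var(E): single-run rho = 0.5, so the
  # 4-run average has predicted reliability 0.8
  truth <- rnorm(v)
  run_maps <- lapply(1:4, function(i) truth + rnorm(v))
  expect_equal(cronbach_alpha(run_maps), spearman_brown(0.5, 4),
               tolerance = 0.02)
  expect_error(cronbach_alpha(list(rnorm(5))), "at least 2")
  expect_error(cronbach_alpha(rep(list(rep(1, 5)), 3)), "zero")
})

test_that("Spearman-Brown prediction is exact arithmetic", {
  expect_identical(spearman_brown(0.5, 4), 0.8)
  expect_identical(spearman_brown(0.37, 1), 0.37)
  expect_identical(spearman_brown(1, 10), 1)
  expect_error(spearman_brown(1.2, 2), "\\[0, 1\\]")
})

test_that("expected map correlation is the geometric mean of reliabilities", {
  expect_identical(expected_map_correlation(0.64, 0.25), 0.4)
  expect_identical(expected_map_correlation(0.7, 0.7), 0.7)
  # empirical check via simulated parallel maps
  set.seed(34)
  v <- 2e4
  truth <- rnorm(v)
  noisy <- function(rho) sqrt(rho) * truth + sqrt(1 - rho) * rnorm(v)
  obs <- cor(noisy(0.8), noisy(0.3))
  expect_equal(obs, expected_map_correlation(0.8, 0.3), tolerance = 0.03)
})

test_that("equivalent localizer minutes inverts Spearman-Brown", {
  # predicted map exactly as reliable as the k0-run average: observed
  # r = sqrt(rho_pred * rho_avg) = alpha, and the fixed point is k0 runs
  expect_equal(equivalent_localizer_minutes(0.6, 4, 3, 0.6), 12,
               tolerance = 1e-10)
  # alpha = 0.5 over 2 runs gives rho1 = 1/3; rho_pred = 0.5 needs 2 runs
  expect_equal(equivalent_localizer_minutes(0.5, 2, 5, sqrt(0.25)), 10,
               tolerance = 1e-10)
  expect_equal(equivalent_localizer_minutes(0.5, 2, 5, 1e-6), 0,
               tolerance = 1e-6)
  expect_identical(equivalent_localizer_minutes(0.5, 2, 5, 0.9), Inf)
  expect_error(equivalent_localizer_minutes(1.2, 4, 3, 0.5), "alpha")
})

test_that("circular phase differences wrap and stay in [0, 180]", {
  a <- retinotopic_map(1, c(10, 359, 180))
  b <- retinotopic_map(1, c(10, 1, 0))
  expect_equal(circular_phase_difference(a, a), 0, tolerance = 1e-12)
  expect_equal(circular_phase_difference(a, b), mean(c(0, 2, 180)),
               tolerance = 1e-12)
  expect_equal(circular_phase_difference(a, b),
               circular_phase_difference(b, a), tolerance = 1e-12)
  m <- region_mask(2)
  expect_equal(circular_phase_difference(a, b, m), 2, tolerance = 1e-12)
  expect_error(circular_phase_difference(a, b, region_mask(integer(0))),
               "empty")
})

test_that("searchlight distinctiveness localizes individual signal", {
  set.seed(35)
  n <- 5; k <- 6
  geom <- grid_geometry(6, spacing_mm = 6)
  v <- 36
  region_a <- which(geom$coordinates[, 1] <= 6)   # left columns
  shared <- matrix(rnorm(k * v), k, v)
  mk <- function(p, indiv) {
    d <- shared + 0.05 * matrix(rnorm(k * v), k, v)
    d[, region_a] <- d[, region_a] + indiv[[p]][, region_a]
    structure(list(subject_id = sprintf("s%d", p), data = d,
                   basis_id = "shared"),
              class = "tuning_matrix")
  }
  indiv <- lapply(1:n, function(p) matrix(rnorm(k * v), k, v))
  h1 <- lapply(1:n, mk, indiv = indiv)
  h2 <- lapply(1:n, mk, indiv = indiv)
  dmap <- searchlight_distinctiveness_map(h1, h2, geom, radius = 7)
  expect_gt(mean(dmap[region_a]) - mean(dmap[-region_a]), 2)
})

test_that("one global searchlight reduces to the whole-matrix index", {
  ts <- make_tuning_set(n = 4, seed = 36)
  geom <- surface_geometry(cbind(runif(50), runif(50), 0))
  dmap <- searchlight_distinctiveness_map(ts$h1, ts$h2, geom, radius = 10)
  sim <- tuning_similarity_matrix(ts$h1, ts$h2)
  d_global <- mean(vapply(1:4, function(i) distinctiveness_index(sim, i), 1))
  expect_equal(dmap, rep(d_global, 50), tolerance = 1e-10)
})

test_that("nearest-neighbor identification is perfect when within exceeds between", {
  fit <- tiny_fit()
  sim <- tuning_similarity_matrix(coef(fit, 1), coef(fit, 2))
  expect_true(all(diag(sim$values) >
                    apply(sim$values - 2 * diag(diag(sim$values)), 1, max)))
  expect_identical(identification_accuracy(sim), 1)
})
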