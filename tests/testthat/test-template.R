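test_that("group PCA keeps a single participant's total variance", {
  X <- ortho_cols(30, 6, seed = 2)
  # n identical copies: scores span col(X), total sum of squares matches
  # one block after the sqrt(n) scaling
  for (n in c(2, 5)) {
    pc <- local_group_pca(rep(list(X), n))
    expect_equal(sum(pc^2), sum(X^2), tolerance = 1e-6)
    # span check: projecting scores onto col(X) changes nothing
    proj <- X %*% crossprod(X, pc)
    expect_equal(proj, pc, tolerance = 1e-6)
  }
})

test_that("group PCA with one participant reduces to plain SVD scores", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  pc <- local_group_pca(list(X))
  s <- svd(X)
  scores <- s$u %*% diag(s$d)
  # same up to the documented sign convention
  for (j in 1:5)
    expect_equal(abs(pc[, j]), abs(scores[, j]), tolerance = 1e-8)
})

test_that("group PCA variance scaling holds for noise blocks of full rank", {
  # when the retained components span the concatenation's full rank
  # (t <= v_sl), the sqrt(n) scaling preserves a single block's total
  # sum of squares exactly, even for pure noise
  set.seed(9)
  blocks <- lapply(1:8, function(i) matrix(rnorm(10 * 30), 10, 30))
  pc <- suppressWarnings(local_group_pca(blocks))
  ratio <- sum(pc^2) / mean(vapply(blocks, function(b) sum(b^2), 1))
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
  # the /n convention divides once more by sqrt(n)
  pc_n <- suppressWarnings(local_group_pca(blocks, scaling = "n"))
  expect_equal(sum(pc_n^2) * 8, sum(pc^2), tolerance = 1e-10)
})

test_that("rank-deficient searchlights are zero-padded with a warning", {
  set.seed(1)
  blocks <- lapply(1:3, function(i) matrix(rnorm(4 * 7), 4, 7))
  expect_warning(pc <- local_group_pca(blocks), "zero-padding")
  expect_identical(dim(pc), c(4L, 7L))
  expect_true(all(pc[, 5:7] == 0))
})

test_that("Procrustes recovers known orthogonal transforms", {
  X <- ortho_cols(25, 2, seed = 4)
  expect_equal(procrustes_solve(X, X), diag(2), tolerance = 1e-12)

  th <- 30 * pi / 180
  R30 <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  R <- procrustes_solve(X, X %*% R30)
  expect_equal(R, R30, tolerance = 1e-10)
  expect_equal(crossprod(R), diag(2), tolerance = 1e-10)

  # column swap is itself an orthogonal (permutation) matrix
  P <- procrustes_solve(X, X[, c(2, 1)])
  expect_equal(P, rbind(c(0, 1), c(1, 0)), tolerance = 1e-10)
})

test_that("Procrustes minimizes over all orthogonal 2x2 candidates", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(40), 20, 2)
  R <- procrustes_solve(X, Y)
  err <- function(R_) sum((X %*% R_ - Y)^2)
  # brute force over the orthogonal group O(2)
  for (th in seq(0, 2 * pi, length.out = 721)) {
    rot <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    refl <- rbind(c(cos(th), sin(th)), c(sin(th), -cos(th)))
    expect_gte(err(rot) + 1e-9, err(R))
    expect_gte(err(refl) + 1e-9, err(R))
  }
})

test_that("degenerate Procrustes covariance returns identity with warning", {
  X <- matrix(0, 5, 3)
  expect_warning(R <- procrustes_solve(X, X), "degenerate")
  expect_identical(R, diag(3))
})

test_that("local template rotation aligns PCs to the group", {
  pc <- ortho_cols(30, 4, seed = 5)
  lt <- rotate_local_template(pc, list(pc))
  expect_equal(lt$rotation, diag(4), tolerance = 1e-8)
  expect_equal(lt$vertex_template, pc, tolerance = 1e-8)

  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  blocks <- rep(list(pc %*% Q), 3)
  lt2 <- rotate_local_template(pc, blocks)
  expect_equal(lt2$rotation, Q, tolerance = 1e-8)
})

test_that("summed-covariance solution equals the stacked Procrustes solve", {
  set.seed(6)
  pc <- matrix(rnorm(15 * 4), 15, 4)
  blocks <- lapply(1:3, function(i) matrix(rnorm(15 * 4), 15, 4))
  lt <- rotate_local_template(pc, blocks)
  stacked_R <- procrustes_solve(do.call(rbind, rep(list(pc), 3)),
                                do.call(rbind, blocks))
  expect_equal(lt$rotation, stacked_R, tolerance = 1e-10)
})

test_that("rotation preserves representational geometry", {
  set.seed(7)
  pc <- matrix(rnorm(12 * 5), 12, 5)
  blocks <- lapply(1:4, function(i) matrix(rnorm(12 * 5), 12, 5))
  lt <- rotate_local_template(pc, blocks)
  expect_equal(crossprod(lt$rotation), diag(5), tolerance = 1e-8)
  expect_equal(as.matrix(dist(pc)), as.matrix(dist(lt$vertex_template)),
               tolerance = 1e-8)
})

test_that("whole-brain aggregation is a weighted average per vertex", {
  geom <- surface_geometry(cbind(c(0, 10), 0, 0))
  sls <- build_searchlights(geom, 20)
  prof <- matrix(rnorm(10 * 2), 10, 2)
  mk_lt <- function(sl, vt) structure(list(searchlight = sl,
                                           vertex_template = vt),
                                      class = "local_template")
  # identical profiles from both searchlights: output identical to input
  lts <- list(mk_lt(sls[[1]], prof), mk_lt(sls[[2]], prof[, c(1, 2)]))
  tmpl <- aggregate_to_whole_brain(lts, geom)
  expect_equal(tmpl$data, prof, tolerance = 1e-12)

  # hand-computed mixing: vertex 1 at d=0 (weight 1) in searchlight 1 and
  # d=10 = r/2 (weight 0.5) in searchlight 2
  a <- rnorm(10); b <- rnorm(10)
  lts2 <- list(mk_lt(sls[[1]], cbind(a, prof[, 2])),
               mk_lt(sls[[2]], cbind(b, prof[, 2])))
  tmpl2 <- aggregate_to_whole_brain(lts2, geom)
  expect_equal(tmpl2$data[, 1], (1 * a + 0.5 * b) / 1.5, tolerance = 1e-12)
})

test_that("aggregation fails loudly on uncovered vertices", {
  geom <- surface_geometry(cbind(c(0, 10), 0, 0))
  sls <- build_searchlights(geom, 20)
  lt <- structure(list(searchlight = sls[[1]],
                       vertex_template = matrix(rnorm(20), 10, 2)),
                  class = "local_template")
  # drop vertex 2's searchlight; it is only covered at the boundary of
  # searchlight 1 where the weight would still be positive -- so shrink
  # the radius instead
  sl_small <- sls[[1]]; sl_small$members <- 1L; sl_small$distances <- 0
  lt$searchlight <- sl_small
  lt$vertex_template <- lt$vertex_template[, 1, drop = FALSE]
  expect_error(aggregate_to_whole_brain(list(lt), geom), "not covered.*2")
})

test_that("template of identical participants reproduces their data", {
  sim <- make_cohort(cohort_spec(n_subjects = 1, t_time = 80, v_vertex = 25,
                                 k_latent = 5, noise_sd = 0, seed = 12))
  cohort <- rep(sim$cohort, 3)
  geom <- sim$truth$spec$geometry
  tmpl <- build_template(cohort, geom, radius = 20)
  B <- cohort[[1]]$data
  cors <- vapply(seq_len(ncol(B)), function(j) cor(tmpl$data[, j], B[, j]), 1)
  expect_true(all(cors > 0.99))
})

test_that("template is invariant to participant order", {
  sim <- tiny_sim()
  geom <- sim$truth$spec$geometry
  t1 <- build_template(sim$cohort, geom, radius = 15)
  t2 <- build_template(rev(sim$cohort), geom, radius = 15)
  expect_equal(t1$data, t2$data, tolerance = 1e-6)
})

test_that("template RDM tracks the shared stimulus geometry", {
  sim <- make_cohort(cohort_spec(n_subjects = 5, t_time = 100, v_vertex = 25,
                                 k_latent = 6, noise_sd = 0.2,
                                 tuning_between_subject_corr = 0.8,
                                 seed = 21))
  geom <- sim$truth$spec$geometry
  tmpl <- build_template(sim$cohort, geom, radius = 20)
  shared <- sim$truth$S_true %*% Reduce(`+`, sim$truth$T_true) /
    length(sim$truth$T_true)
  rdm <- function(x) as.numeric(dist(x))
  expect_gt(cor(rdm(tmpl$data), rdm(shared)), 0.9)
})

test_that("mismatched time axes are rejected", {
  sim <- tiny_sim()
  bad <- sim$cohort
  bad[[2]]$data <- bad[[2]]$data[1:100, ]
  expect_error(build_template(bad, sim$truth$spec$geometry), "mismatched")
})
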