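# Shared miniature fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small cohort that still exercises every pipeline stage: 4 participants,
# 240 time points, a 6 x 6 grid, rank-8 shared structure, SNR ~ 4.
tiny_sim <- function() cached("tiny_sim", function() {
  make_cohort(cohort_spec(n_subjects = 4, t_time = 240, v_vertex = 36,
                          k_latent = 8, noise_sd = 0.5, seed = 3))
})

tiny_bagging <- function(seed = 1L)
  bagging_config(buffer_seconds = 5, seed = seed)

tiny_fit <- function() cached("tiny_fit", function() {
  sim <- tiny_sim()
  int_fit(sim$cohort, sim$truth$spec$geometry, seed = 7,
          bagging = tiny_bagging())
})

# Orthonormal-column matrix of a given size.
ortho_cols <- function(m, q, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(m * q), m, q)))
}
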