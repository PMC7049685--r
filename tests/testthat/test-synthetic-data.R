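test_that("absorbing model stays fully in its start state", {
  m <- three_state_model(0, 0, 0, 0)
  p <- simulate_state_path(m, 50, 0.1, start_state = "open", seed = 1)
  expect_true(all(p$state == 2L))
  expect_equal(p$occupancy[, "open"], rep(1, 50), tolerance = 1e-12)
})

test_that("per-frame occupancy fractions sum to one", {
  set.seed(123)
  for (seed in 1:5) {
    m <- three_state_model(k_open = runif(1, 0.1, 2),
                           k_close = runif(1, 0.1, 2),
                           k_scrunch = runif(1, 0.1, 2),
                           k_unscrunch = runif(1, 0.1, 2))
    p <- simulate_state_path(m, 200, 0.1, seed = seed)
    expect_equal(rowSums(p$occupancy), rep(1, 200), tolerance = 1e-9)
    expect_equal(p$state, max.col(p$occupancy, ties.method = "first"))
  }
})

test_that("long-run occupancy matches the analytic stationary vector", {
  # two-state symmetric chain: exact stationary occupancy 1/2 each
  rates <- matrix(c(0, 1, 1, 0), 2, 2)
  m2 <- kinetic_model(rates, c(0.2, 0.6))
  p2 <- simulate_state_path(m2, 1e5, 0.1, seed = 42)
  occ <- colMeans(p2$occupancy)
  # dwell ~ Exp(1): n_frames*dt = 1e4 s ~ 5000 sojourns; SE ~ 1/sqrt(5000)
  se <- 1 / sqrt(5000)
  expect_lt(abs(occ[1] - 0.5), 3 * se)

  m3 <- three_state_model(k_open = 0.3, k_close = 0.5,
                          k_scrunch = 0.8, k_unscrunch = 0.2)
  p3 <- simulate_state_path(m3, 1e5, 0.1, seed = 43)
  pi_hat <- colMeans(p3$occupancy)
  pi_true <- stationary_distribution(m3)
  expect_equal(unname(pi_hat), unname(pi_true), tolerance = 0.05)
})

test_that("identical master seeds give identical trace sets", {
  m <- three_state_model()
  ph <- photophysics(noise_sd = 15, bleach_rate_d = 0.01,
                     bleach_rate_a = 0.01)
  a <- simulate_trace_set(m, ph, 5, 100, seed = 99)
  b <- simulate_trace_set(m, ph, 5, 100, seed = 99)
  for (i in seq_along(a)) expect_identical(a[[i]], b[[i]])
  c <- simulate_trace_set(m, ph, 5, 100, seed = 100)
  expect_false(identical(a[[1]]$I_D, c[[1]]$I_D))
})

test_that("noiseless rendering inverts exactly through the correction", {
  m <- kinetic_model(matrix(0, 1, 1), fret_means = 0.56, fret_sd = 0,
                     states = "scrunched")
  p <- simulate_state_path(m, 20, 0.1, start_state = "scrunched", seed = 1)
  # no leakage
  ph0 <- photophysics(noise_sd = 0, leakage = 0)
  fs0 <- compute_fret(render_trace(p, m, ph0, seed = 1), leakage = 0)
  expect_equal(fs0$E, rep(0.56, 20), tolerance = 1e-13)
  # leakage injected then corrected: exact cancellation
  ph8 <- photophysics(noise_sd = 0, leakage = 0.08)
  fs8 <- compute_fret(render_trace(p, m, ph8, seed = 1), leakage = 0.08)
  expect_equal(fs8$E, rep(0.56, 20), tolerance = 1e-13)
})

test_that("acceptor bleach zeroes FRET and the end check frames", {
  m <- kinetic_model(matrix(0, 1, 1), fret_means = 0.6, fret_sd = 0,
                     states = "s")
  ph <- photophysics(noise_sd = 0, leakage = 0.08, bleach_rate_a = 0.5,
                     frame_interval = 0.1, n_check_frames = 3)
  # find a seed whose acceptor bleaches mid-movie
  tr <- NULL
  for (seed in 1:50) {
    cand <- render_trace(simulate_state_path(m, 100, 0.1,
                                             start_state = "s", seed = 1),
                         m, ph, seed = seed)
    tb <- attr(cand, "truth")$t_bleach_a
    if (tb > 2 && tb < 8) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  tb <- attr(tr, "truth")$t_bleach_a
  fs <- compute_fret(tr, leakage = 0.08)
  bleached <- fs$frames > ceiling(tb / 0.1) + 3  # payload frame offset
  expect_true(all(abs(fs$E[bleached]) < 1e-10))
  end_check <- tail(tr, 3)
  expect_true(all(end_check$I_A == 0))
})

test_that("titration generator reproduces closed-form values", {
  h <- generate_titration("hyperbola", list(F0 = 1, dF = 1, K_d = 100),
                          x = 100)
  expect_equal(h$y, 1.5)
  q <- generate_titration("quadratic_binding",
                          list(K_d = 0.5, D_t = 5, r_f = 0.15, r_b = 0.3),
                          x = 0)
  expect_equal(q$y, 0.15)
  mm <- generate_titration("michaelis_menten",
                           list(k_cat = 0.4, K_m = 165), x = 165)
  expect_equal(mm$y, 0.2)
  expect_error(generate_titration("sigmoid", list(), x = 1),
               "unsupported model kind")
  expect_error(generate_titration("hyperbola", list(F0 = 1), x = 1),
               "missing parameter")
  # noise is seeded and reproducible
  n1 <- generate_titration("hyperbola", list(F0 = 1, dF = 1, K_d = 100),
                           x = 1:10, noise_sd = 0.1, seed = 7)
  n2 <- generate_titration("hyperbola", list(F0 = 1, dF = 1, K_d = 100),
                           x = 1:10, noise_sd = 0.1, seed = 7)
  expect_identical(n1$y, n2$y)
})

test_that("single-state trace set pools to a unimodal histogram", {
  m <- kinetic_model(matrix(0, 1, 1), fret_means = 0.38, fret_sd = 0.06,
                     states = "open")
  ts <- simulate_trace_set(m, photophysics(), 20, 200, seed = 11,
                           start_state = "open")
  fret <- lapply(ts, compute_fret)
  fit <- fit_gaussian_mixture(build_histogram(fret), n_components = 1)
  expect_equal(fit$means, 0.38, tolerance = 0.02)
})
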