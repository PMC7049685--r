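test_that("scaled forward likelihood equals exhaustive path enumeration", {
  for (seed in 1:4) {
    p <- random_hmm(3, seed)
    x <- rnorm(5, mean = sample(p$mu, 5, TRUE), sd = 0.1)
    ll_fast <- hmm_forward_loglik(x, p$init, p$A, p$mu, p$sigma)
    ll_enum <- enumerate_loglik(x, p$init, p$A, p$mu, p$sigma)
    expect_equal(ll_fast, ll_enum, tolerance = 1e-10)
  }
  # and for a 2-state, T = 6 case
  p <- random_hmm(2, 99)
  x <- rnorm(6, 0.4, 0.2)
  expect_equal(hmm_forward_loglik(x, p$init, p$A, p$mu, p$sigma),
               enumerate_loglik(x, p$init, p$A, p$mu, p$sigma),
               tolerance = 1e-10)
})

test_that("Viterbi equals exhaustive argmax and breaks ties downward", {
  # 2-frame, 2-state toy, hand-set probabilities: all 4 paths enumerated
  p <- list(init = c(0.6, 0.4),
            A = matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE),
            mu = c(0.2, 0.7), sigma = c(0.1, 0.1))
  fit <- list(initial_probs = p$init, transition_matrix = p$A,
              emission_means = p$mu, emission_sds = p$sigma)
  for (x in list(c(0.25, 0.65), c(0.1, 0.1), c(0.9, 0.2))) {
    expect_equal(viterbi_path(fit, x),
                 enumerate_viterbi(x, p$init, p$A, p$mu, p$sigma))
  }
  # equidistant emissions with symmetric model: lower state index wins
  sym <- list(initial_probs = c(0.5, 0.5),
              transition_matrix = matrix(0.5, 2, 2),
              emission_means = c(0.25, 0.75), emission_sds = c(0.1, 0.1))
  # 0.5 is exactly equidistant (binary-exact differences of 0.25)
  expect_equal(viterbi_path(sym, c(0.5, 0.5)), c(1L, 1L))
})

test_that("noiseless block traces decode to the generating blocks", {
  mu <- c(0.14, 0.38, 0.56)
  blocks <- rep(c(1L, 2L, 3L, 2L), each = 25L)
  fit <- list(initial_probs = rep(1 / 3, 3),
              transition_matrix = matrix(c(0.9, 0.05, 0.05,
                                           0.05, 0.9, 0.05,
                                           0.05, 0.05, 0.9), 3, 3,
                                         byrow = TRUE),
              emission_means = mu, emission_sds = rep(0.05, 3))
  expect_equal(viterbi_path(fit, mu[blocks]), blocks)
})

test_that("single-state data fit to a near-identity transition matrix", {
  set.seed(31)
  traces <- replicate(10, rnorm(300, 0.38, 0.05), simplify = FALSE)
  fit <- fit_hmm(traces, n_states = 1, seed = 1)
  expect_equal(fit$emission_means, 0.38, tolerance = 0.01)
  fit2 <- suppressWarnings(fit_hmm(traces, n_states = 2, seed = 1))
  off <- fit2$transition_matrix[row(fit2$transition_matrix) !=
                                  col(fit2$transition_matrix)]
  # either collapses to a dominant state or leaves negligible cross flow
  expect_equal(rowSums(fit2$transition_matrix), c(1, 1), tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and rows stay stochastic", {
  m <- three_state_model()
  ts <- simulate_trace_set(m, photophysics(), 15, 250, seed = 41)
  fret <- lapply(ts, compute_fret)
  fit <- fit_hmm(fret, n_states = 3, seed = 5)
  expect_true(all(diff(fit$loglik_trace) >=
                    -(1e-8 + 1e-10 * abs(fit$log_likelihood))))
  expect_equal(rowSums(fit$transition_matrix), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(fit$emission_means, unname(m$fret_means), tolerance = 0.02)
  expect_true(all(diff(fit$emission_means) > 0))
})

test_that("transition density records one point per state change", {
  fit <- list(emission_means = c(0.14, 0.38, 0.56))
  td <- transition_density(list(c(2L, 2L, 3L, 3L)), fit)
  expect_equal(td$n_transitions, 1L)
  expect_equal(td$points$E_before, 0.38)
  expect_equal(td$points$E_after, 0.56)
  # constant path: empty density is valid
  td0 <- transition_density(list(rep(1L, 10)), fit)
  expect_equal(td0$n_transitions, 0L)
  expect_true(all(td0$grid == 0))
  # symmetric two-state path: counts symmetric about the diagonal
  tds <- transition_density(list(c(rep(c(1L, 2L), 20), 1L)), fit)
  expect_equal(sum(tds$points$E_before < tds$points$E_after),
               sum(tds$points$E_before > tds$points$E_after))
})

test_that("probability-to-rate conversion handles limits and inverts expm", {
  idfit <- list(transition_matrix = diag(3),
                emission_means = c(0.1, 0.4, 0.6))
  r0 <- rates_from_hmm(idfit, 0.1)
  expect_true(all(r0$k == 0))
  expect_true(is.na(r0$keq_scrunch))
  # linear method: k = p / dt
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  rl <- rates_from_hmm(list(transition_matrix = A,
                            emission_means = c(0.2, 0.6)),
                       0.1, method = "linear")
  expect_equal(rl$k[1, 2], 0.1)
  # exact-log method inverts the matrix exponential of a known generator
  m <- three_state_model(0.2, 0.4, 0.6, 0.1)
  A3 <- pracma::expm(m$Q * 0.1)
  rx <- rates_from_hmm(list(transition_matrix = A3,
                            emission_means = c(0.14, 0.38, 0.56)), 0.1)
  expect_equal(unname(rx$k), unname(m$rates), tolerance = 1e-4)
  expect_equal(rx$keq_scrunch, 6, tolerance = 1e-4)
})

test_that("rates and Keq are recovered across slow-to-moderate regimes", {
  # k * dt from 0.02 to 0.3: recovery within 20 percent
  for (cfg in list(list(k = c(0.2, 0.4, 0.6, 0.1), seed = 51),
                   list(k = c(1.0, 2.0, 3.0, 0.5), seed = 52))) {
    m <- three_state_model(cfg$k[1], cfg$k[2], cfg$k[3], cfg$k[4])
    ts <- simulate_trace_set(m, photophysics(), 40, 400, seed = cfg$seed)
    fret <- lapply(ts, compute_fret)
    fit <- fit_hmm(fret, n_states = 3, seed = 1)
    r <- rates_from_hmm(fit, 0.1)
    keq_true <- cfg$k[3] / cfg$k[4]
    expect_equal(r$keq_scrunch, keq_true, tolerance = 0.2 * keq_true)
  }
})

test_that("Keq agrees with the Viterbi occupancy ratio", {
  m <- three_state_model(0.2, 0.4, 0.6, 0.1)
  ts <- simulate_trace_set(m, photophysics(), 40, 400, seed = 61)
  fret <- lapply(ts, compute_fret)
  fit <- fit_hmm(fret, n_states = 3, seed = 1)
  paths <- lapply(fret, function(f) viterbi_path(fit, f))
  all_states <- unlist(paths)
  occ_ratio <- sum(all_states == 3L) / sum(all_states == 2L)
  r <- rates_from_hmm(fit, 0.1)
  expect_equal(r$keq_scrunch, occ_ratio, tolerance = 0.25 * occ_ratio)
})
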