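# Independent oracles used across tests. Deliberately brute-force /
# closed-form so they share no code with the implementation they check.

# Random valid HMM parameter set for property-style checks.
random_hmm <- function(K, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K, 0.05, 1), K, K)
  A <- A / rowSums(A)
  init <- runif(K, 0.1, 1)
  init <- init / sum(init)
  list(init = init, A = A, mu = sort(runif(K, 0, 1)),
       sigma = runif(K, 0.03, 0.15))
}

# Exhaustive path-sum likelihood of a Gaussian-emission HMM: sums
# pi[s1] b_{s1}(x1) * prod A[s_{t-1}, s_t] b_{s_t}(x_t) over all K^T
# state paths. Only feasible for tiny T, which is the point.
enumerate_loglik <- function(x, init, trans, mu, sigma) {
  Tn <- length(x)
  K <- length(mu)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- init[s[1]] * dnorm(x[1], mu[s[1]], sigma[s[1]])
    if (Tn > 1) for (t in 2:Tn)
      p <- p * trans[s[t - 1], s[t]] * dnorm(x[t], mu[s[t]], sigma[s[t]])
    total <- total + p
  }
  log(total)
}

# Exhaustive Viterbi: joint probability of each full path, argmax.
enumerate_viterbi <- function(x, init, trans, mu, sigma) {
  Tn <- length(x)
  K <- length(mu)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best_p <- -Inf
  best <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(init[s[1]]) + dnorm(x[1], mu[s[1]], sigma[s[1]], log = TRUE)
    if (Tn > 1) for (t in 2:Tn)
      p <- p + log(trans[s[t - 1], s[t]]) +
        dnorm(x[t], mu[s[t]], sigma[s[t]], log = TRUE)
    if (p > best_p) { best_p <- p; best <- s }
  }
  as.integer(best)
}

# Stationary distribution by eigen-decomposition of the generator
# transpose (independent of the package's linear-solve route).
stationary_eigen <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# A two-dye composite trace: the intensity sum of two independent
# single-pair renders, i.e. what a spot with two donors/acceptors yields.
make_double_dye_trace <- function(seed = 1) {
  m <- kinetic_model(matrix(0, 1, 1), fret_means = 0.4, fret_sd = 0,
                     states = "s")
  ph <- photophysics(total_intensity = 400, noise_sd = 2,
                     bleach_rate_d = 0.05, frame_interval = 0.1,
                     n_check_frames = 5)
  p <- simulate_state_path(m, 400, 0.1, start_state = "s", seed = seed)
  t1 <- render_trace(p, m, ph, seed = seed + 100)
  t2 <- render_trace(p, m, ph, seed = seed + 200)
  out <- t1
  out$I_D <- t1$I_D + t2$I_D
  out$I_A <- t1$I_A + t2$I_A
  out
}
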