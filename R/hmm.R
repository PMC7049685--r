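#' Fit a Gaussian-emission hidden Markov model to pooled FRET traces
#'
#' Maximum-likelihood Baum-Welch EM over all traces jointly: one global
#' set of emission means/widths, transition matrix and initial
#' distribution per condition (per-trace forward-backward in scaled
#' space, parameters pooled in the M-step). Three states — closed, open,
#' scrunched — is the canonical configuration for the +2 initiation
#' complex. The EM log-likelihood is asserted non-decreasing at every
#' iteration; multi-start with seeded jittered initializations guards
#' against local optima. States are reported sorted by emission mean
#' ascending, so state 1 is closed and state `n_states` is scrunched.
#'
#' @param fret_traces list of `fret_series` (or numeric vectors of
#'   corrected FRET).
#' @param n_states number of hidden states (default 3).
#' @param init `"quantile"` (emission means at data quantiles) — the only
#'   built-in strategy; restarts jitter it.
#' @param n_restarts additional seeded restarts beyond the deterministic
#'   start.
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed for restart jitter.
#' @param var_floor lower bound on emission variances; fits touching the
#'   floor are flagged in `$variance_floored`.
#' @return object of class `hmm_fit`: `n_states`, `emission_means`,
#'   `emission_sds`, `transition_matrix` (rows sum to 1), `initial_probs`,
#'   `log_likelihood`, `loglik_trace` (per EM iteration),
#'   `n_traces_used`, `converged`, `variance_floored`.
#' @export
fit_hmm <- function(fret_traces, n_states = 3L, init = "quantile",
                    n_restarts = 2L, tol = 1e-7, max_iter = 300L,
                    seed = 1L, var_floor = 1e-4) {
  obs <- lapply(fret_traces, function(tr)
    if (inherits(tr, "fret_series")) tr$E else as.numeric(tr))
  obs <- Filter(function(x) length(x) >= 2L * n_states, obs)
  if (length(obs) < 1L)
    stop("need at least one trace with >= 2 * n_states frames")
  n_states <- as.integer(n_states)
  pooled <- unlist(obs)
  sd_floor <- sqrt(var_floor)

  run_em <- function(mu0, sigma0) {
    mu <- mu0
    sigma <- pmax(sigma0, sd_floor)
    A <- matrix(0.05 / (n_states - 1), n_states, n_states)
    diag(A) <- 0.95
    piv <- rep(1 / n_states, n_states)
    ll_old <- -Inf
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ll <- 0
      xi_tot <- matrix(0, n_states, n_states)
      g1 <- numeric(n_states)
      sw <- numeric(n_states)
      swx <- numeric(n_states)
      swx2 <- numeric(n_states)
      for (x in obs) {
        fb <- hmm_forward_backward_cpp(x, piv, A, mu, sigma)
        ll <- ll + fb$loglik
        xi_tot <- xi_tot + fb$xi
        g <- fb$gamma
        g1 <- g1 + g[1L, ]
        sw <- sw + colSums(g)
        swx <- swx + colSums(g * x)
        swx2 <- swx2 + colSums(g * x^2)
      }
      if (length(ll_trace) &&
          ll < ll_trace[length(ll_trace)] - (1e-8 + 1e-10 * abs(ll)))
        stop("internal error: EM log-likelihood decreased")
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      # M-step
      piv <- g1 / sum(g1)
      rs <- rowSums(xi_tot)
      rs[rs < 1e-12] <- 1e-12
      A <- xi_tot / rs
      A <- A / rowSums(A)
      sw_safe <- pmax(sw, 1e-12)
      mu <- swx / sw_safe
      v <- swx2 / sw_safe - mu^2
      sigma <- sqrt(pmax(v, var_floor))
    }
    list(mu = mu, sigma = sigma, A = A, piv = piv, ll = ll_trace,
         converged = converged,
         floored = any(abs(sigma - sd_floor) < 1e-12))
  }

  qs <- quantile(pooled, probs = (seq_len(n_states) - 0.5) / n_states,
                 names = FALSE)
  sigma0 <- rep(max(sd(pooled) / n_states, sd_floor), n_states)
  starts <- list(qs)
  if (n_restarts > 0L) {
    span <- max(diff(range(pooled)), 1e-3)
    jit <- with_seed(seed, matrix(runif(n_restarts * n_states, -1, 1),
                                  n_restarts, n_states))
    for (r in seq_len(n_restarts))
      starts[[r + 1L]] <- qs + 0.2 * span * jit[r, ]
  }
  best <- NULL
  for (mu0 in starts) {
    fit <- run_em(sort(mu0), sigma0)
    if (is.null(best) || max(fit$ll) > max(best$ll)) best <- fit
  }
  if (!best$converged)
    warning("HMM EM did not converge within max_iter; ",
            "returning best fit found")
  if (best$floored)
    warning("an emission variance hit the variance floor")

  ord <- order(best$mu)
  structure(
    list(n_states = n_states,
         emission_means = best$mu[ord],
         emission_sds = best$sigma[ord],
         transition_matrix = best$A[ord, ord, drop = FALSE],
         initial_probs = best$piv[ord],
         log_likelihood = max(best$ll),
         loglik_trace = best$ll,
         n_traces_used = length(obs),
         converged = best$converged,
         variance_floored = best$floored),
    class = "hmm_fit")
}

#' Forward log-likelihood of one trace under fixed HMM parameters
#'
#' Exposes the scaled forward recursion directly, mainly so the
#' implementation can be validated against exhaustive enumeration over all
#' state paths on small problems.
#'
#' @param x numeric observation vector.
#' @param init_probs,transition_matrix,means,sds HMM parameters.
#' @return log-likelihood (numeric scalar).
#' @export
hmm_forward_loglik <- function(x, init_probs, transition_matrix, means,
                               sds) {
  hmm_forward_backward_cpp(as.numeric(x), init_probs,
                           as.matrix(transition_matrix), means,
                           sds)$loglik
}

#' Most probable state sequence (Viterbi) of a trace
#'
#' Log-space Viterbi decoding under a fitted model. Ties are broken toward
#' the lower state index, so observations equidistant from two emission
#' means idealize to the lower-FRET state.
#'
#' @param fit an [fit_hmm()] result (or a list with `initial_probs`,
#'   `transition_matrix`, `emission_means`, `emission_sds`).
#' @param trace a `fret_series` or numeric vector.
#' @return integer vector of 1-based state indices (1 = lowest FRET).
#' @export
viterbi_path <- function(fit, trace) {
  x <- if (inherits(trace, "fret_series")) trace$E else as.numeric(trace)
  if (length(x) < 1L) stop("trace must contain at least one frame")
  hmm_viterbi_cpp(x, fit$initial_probs, as.matrix(fit$transition_matrix),
                  fit$emission_means, fit$emission_sds)
}

#' Transition density of idealized traces
#'
#' Collects one point per state change at (emission mean of the departing
#' state, emission mean of the arriving state) and bins them on a FRET x
#' FRET grid — the transition density plot used to visualize which
#' conformational transitions dominate a condition. Self-transitions are
#' excluded by construction.
#'
#' @param paths list of integer state paths (e.g. from [viterbi_path()]).
#' @param fit the [fit_hmm()] the paths were decoded under.
#' @param grid_edges bin edges of the 2D grid on each FRET axis.
#' @return object of class `transition_density`: `points` (data.frame
#'   `E_before`, `E_after`), `grid` (counts matrix), `grid_edges`,
#'   `n_transitions`.
#' @export
transition_density <- function(paths, fit,
                               grid_edges = seq(-0.2, 1.2, by = 0.05)) {
  if (is.numeric(paths)) paths <- list(paths)
  mu <- fit$emission_means
  before <- numeric(0)
  after <- numeric(0)
  for (p in paths) {
    p <- as.integer(p)
    if (length(p) < 2L) next
    ch <- which(diff(p) != 0L)
    before <- c(before, mu[p[ch]])
    after <- c(after, mu[p[ch + 1L]])
  }
  nb <- length(grid_edges) - 1L
  grid <- matrix(0L, nb, nb)
  if (length(before)) {
    ib <- findInterval(before, grid_edges, rightmost.closed = TRUE)
    ia <- findInterval(after, grid_edges, rightmost.closed = TRUE)
    ok <- ib >= 1L & ib <= nb & ia >= 1L & ia <= nb
    for (t in which(ok)) grid[ib[t], ia[t]] <- grid[ib[t], ia[t]] + 1L
  }
  structure(list(points = data.frame(E_before = before, E_after = after),
                 grid = grid, grid_edges = grid_edges,
                 n_transitions = length(before)),
            class = "transition_density")
}

#' Convert per-frame transition probabilities into rate constants
#'
#' The fitted transition matrix gives probabilities per frame interval.
#' `method = "exact_log"` takes the principal matrix logarithm of the
#' transition matrix divided by the frame interval — exact for a
#' time-homogeneous continuous-time chain observed at discrete times; any
#' small negative off-diagonal entries of the logarithm (a finite-sample
#' artifact) are floored at zero and flagged. `method = "linear"` uses the
#' first-order approximation `k_ij = p_ij / dt`, adequate when
#' `p_ij << 1`. The scrunching equilibrium constant is
#' `k(open -> scrunched) / k(scrunched -> open)`, i.e. `k[2,3] / k[3,2]`
#' for the canonical three-state ordering.
#'
#' @param fit an [fit_hmm()] result.
#' @param frame_interval seconds per frame.
#' @param method `"exact_log"` or `"linear"`.
#' @return object of class `rate_estimates`: `k` (rate matrix, s^-1, zero
#'   diagonal), `keq_scrunch` (NA when undefined), `frame_interval`,
#'   `method`, `projected` (TRUE when negative log entries were floored).
#' @export
rates_from_hmm <- function(fit, frame_interval,
                           method = c("exact_log", "linear")) {
  method <- match.arg(method)
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  A <- as.matrix(fit$transition_matrix)
  K <- nrow(A)
  projected <- FALSE
  if (method == "exact_log") {
    L <- tryCatch(pracma::logm(A), error = function(e) NULL)
    if (is.null(L) || any(!is.finite(L)) ||
        (is.complex(L) && max(abs(Im(L))) > 1e-8)) {
      warning("matrix logarithm not real/finite; ",
              "falling back to linear conversion")
      method <- "linear"
    } else {
      L <- Re(L)
      k <- L / frame_interval
      off <- k[row(k) != col(k)]
      if (any(off < 0)) projected <- TRUE
      k[k < 0 & row(k) != col(k)] <- 0
    }
  }
  if (method == "linear") k <- A / frame_interval
  diag(k) <- 0
  st <- if (K == 3L) c("closed", "open", "scrunched")
        else paste0("state", seq_len(K))
  dimnames(k) <- list(st, st)
  keq <- NA_real_
  if (K >= 3L) {
    if (k[3L, 2L] > 0) keq <- k[2L, 3L] / k[3L, 2L]
    else if (k[2L, 3L] == 0) keq <- NA_real_  # no transitions either way
    else keq <- Inf
  } else if (K == 2L && k[2L, 1L] > 0) keq <- k[1L, 2L] / k[2L, 1L]
  structure(list(k = k, keq_scrunch = keq,
                 frame_interval = frame_interval, method = method,
                 projected = projected),
            class = "rate_estimates")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Gaussian-emission HMM fit:", x$n_states, "states,",
      x$n_traces_used, "traces, logLik", format(x$log_likelihood), "\n")
  cat("  emission means:", paste(round(x$emission_means, 4),
                                 collapse = ", "), "\n")
  cat("  emission sds:  ", paste(round(x$emission_sds, 4),
                                 collapse = ", "), "\n")
  cat("  transition matrix (per frame):\n")
  print(round(x$transition_matrix, 4))
  invisible(x)
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("Rate constants (s^-1,", x$method, "conversion):\n")
  print(signif(x$k, 4))
  cat("  Keq (scrunch) =", format(x$keq_scrunch), "\n")
  if (x$projected)
    cat("  note: negative generator entries floored at 0\n")
  invisible(x)
}
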