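#' Gaussian mixture fit of pooled FRET values with optional fixed means
#'
#' Fits a 1-3 component Gaussian mixture to the pooled window-mean FRET
#' values, the model used to read peak positions, widths and fractional
#' populations off smFRET histograms. Any subset of the component means can
#' be held fixed — the constraint used when a new high-FRET population
#' appears on top of peaks whose positions are already known from a
#' reference condition.
#'
#' The default backend maximizes the pooled likelihood by EM with multiple
#' seeded restarts (quantile-spaced initial means, jittered on restarts;
#' best likelihood kept). The `"histogram"` backend instead least-squares
#' fits the sum-of-Gaussians curve to the binned density; it is provided as
#' an independent route for cross-checks.
#'
#' @param data numeric vector of pooled FRET values, or a
#'   [build_histogram()] result (its pooled values are used for the EM
#'   backend, its binned density for the histogram backend).
#' @param n_components number of Gaussian components (1-3 typical).
#' @param fixed_means optional numeric vector of means to hold fixed; the
#'   remaining `n_components - length(fixed_means)` means are free.
#' @param backend `"em"` (pooled maximum likelihood) or `"histogram"`
#'   (least squares on the binned density).
#' @param n_restarts EM restarts beyond the deterministic quantile start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed for the restart jitter.
#' @return object of class `mixture_fit`: `means`, `sds`, `weights`
#'   (summing to 1), `fixed_mask`, `loglik` (EM) or `rss` (histogram),
#'   `fwhm` (derived, `2 sqrt(2 log 2) * sds`), `n`, `backend`,
#'   `converged`. Components are sorted by mean ascending.
#' @export
fit_gaussian_mixture <- function(data, n_components = 2L,
                                 fixed_means = NULL,
                                 backend = c("em", "histogram"),
                                 n_restarts = 10L, tol = 1e-8,
                                 max_iter = 500L, seed = 1L) {
  backend <- match.arg(backend)
  hist_obj <- NULL
  if (inherits(data, "fret_histogram")) {
    hist_obj <- data
    x <- data$values
  } else x <- as.numeric(data)
  x <- x[is.finite(x)]
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("`n_components` must be >= 1")
  if (length(x) < 10L * n_components)
    stop("need at least 10 data points per component")
  n_fixed <- length(fixed_means)
  if (n_fixed > n_components)
    stop("more fixed means than components")
  if (n_fixed && (min(fixed_means) < min(x) || max(fixed_means) > max(x)))
    warning("some fixed means lie outside the data range")

  if (backend == "histogram") {
    if (is.null(hist_obj)) hist_obj <- build_histogram(list(x), window = 1L)
    return(.fit_mixture_histogram(hist_obj, n_components, fixed_means,
                                  length(x)))
  }
  .fit_mixture_em(x, n_components, fixed_means, n_restarts, tol,
                  max_iter, seed)
}

.mixture_result <- function(means, sds, weights, fixed_mask, n, backend,
                            loglik = NA_real_, rss = NA_real_,
                            converged = TRUE) {
  ord <- order(means)
  structure(list(means = means[ord], sds = sds[ord],
                 weights = weights[ord] / sum(weights),
                 fixed_mask = fixed_mask[ord],
                 fwhm = 2 * sqrt(2 * log(2)) * sds[ord],
                 loglik = loglik, rss = rss, n = n,
                 backend = backend, converged = converged),
            class = "mixture_fit")
}

.fit_mixture_em <- function(x, K, fixed_means, n_restarts, tol, max_iter,
                            seed) {
  n <- length(x)
  n_fixed <- length(fixed_means)
  free_idx <- if (n_fixed < K) (n_fixed + 1L):K else integer(0)
  sd_floor <- 1e-4

  run_em <- function(mu0, sigma0, w0) {
    mu <- mu0; sigma <- pmax(sigma0, sd_floor); w <- w0 / sum(w0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K),
                     function(k) w[k] * dnorm(x, mu[k], sigma[k]),
                     numeric(n))
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d < 1e-300] <- 1e-300
      ll <- sum(log(rowsum_d))
      r <- dens / rowsum_d
      nk <- colSums(r)
      nk[nk < 1e-12] <- 1e-12
      w <- nk / n
      for (k in free_idx) mu[k] <- sum(r[, k] * x) / nk[k]
      if (n_fixed) mu[seq_len(n_fixed)] <- fixed_means
      for (k in seq_len(K))
        sigma[k] <- max(sqrt(sum(r[, k] * (x - mu[k])^2) / nk[k]), sd_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
        return(list(mu = mu, sigma = sigma, w = w, ll = ll,
                    converged = TRUE))
      }
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, w = w, ll = ll_old, converged = FALSE)
  }

  # deterministic quantile start, then seeded jittered restarts
  qs <- quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (n_fixed) qs[seq_len(n_fixed)] <- fixed_means
  sigma0 <- rep(max(sd(x) / K, sd_floor), K)
  starts <- list(list(mu = qs, sigma = sigma0, w = rep(1 / K, K)))
  if (n_restarts > 0L) {
    jitters <- with_seed(seed, matrix(runif(n_restarts * K, -1, 1),
                                      n_restarts, K))
    span <- diff(range(x))
    for (r in seq_len(n_restarts)) {
      mu_r <- qs + 0.25 * span * jitters[r, ]
      if (n_fixed) mu_r[seq_len(n_fixed)] <- fixed_means
      starts[[r + 1L]] <- list(mu = mu_r, sigma = sigma0,
                               w = rep(1 / K, K))
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- run_em(s$mu, s$sigma, s$w)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (!best$converged)
    warning("mixture EM did not converge; returning best likelihood found")
  fixed_mask <- c(rep(TRUE, n_fixed), rep(FALSE, K - n_fixed))
  .mixture_result(best$mu, best$sigma, best$w, fixed_mask, n, "em",
                  loglik = best$ll, converged = best$converged)
}

.fit_mixture_histogram <- function(h, K, fixed_means, n) {
  mids <- (head(h$bin_edges, -1) + tail(h$bin_edges, -1)) / 2
  dens <- h$density
  n_fixed <- length(fixed_means)
  qs <- quantile(h$values, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (n_fixed) qs[seq_len(n_fixed)] <- fixed_means
  s0 <- max(sd(h$values) / K, 1e-3)

  par0 <- c(rep(1 / K, K), qs[setdiff(seq_len(K), seq_len(n_fixed))],
            rep(s0, K))
  unpack <- function(p) {
    w <- abs(p[seq_len(K)])
    mu <- numeric(K)
    if (n_fixed) mu[seq_len(n_fixed)] <- fixed_means
    n_free <- K - n_fixed
    if (n_free) mu[(n_fixed + 1L):K] <- p[K + seq_len(n_free)]
    sigma <- pmax(abs(p[(K + n_free) + seq_len(K)]), 1e-4)
    list(w = w, mu = mu, sigma = sigma)
  }
  resid_fun <- function(p) {
    q <- unpack(p)
    model <- rowSums(vapply(seq_len(K),
      function(k) q$w[k] * dnorm(mids, q$mu[k], q$sigma[k]),
      numeric(length(mids))))
    dens - model
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  q <- unpack(fit$par)
  fixed_mask <- c(rep(TRUE, n_fixed), rep(FALSE, K - n_fixed))
  .mixture_result(q$mu, q$sigma, q$w, fixed_mask, n, "histogram",
                  rss = sum(resid_fun(fit$par)^2),
                  converged = fit$info %in% 1:4)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit (", x$backend, " backend, ",
      length(x$means), " components, n = ", x$n, ")\n", sep = "")
  tab <- data.frame(mean = round(x$means, 4), sd = round(x$sds, 4),
                    weight = round(x$weights, 4), fixed = x$fixed_mask)
  print(tab, row.names = FALSE)
  invisible(x)
}
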