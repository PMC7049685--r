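#' Detection and photophysics parameters of the simulated TIRF recording
#'
#' Bundles everything about the measurement that is not conformational
#' kinetics: detected intensity scale, channel noise, donor -> acceptor
#' spectral leakage, additive backgrounds, single-step photobleaching rates
#' and the direct-excitation check frames recorded at the start and end of
#' each movie to verify acceptor presence.
#'
#' @param total_intensity mean total detected signal per frame (a.u.).
#' @param noise_sd Gaussian detection noise added independently to each
#'   channel (a.u.).
#' @param leakage fraction of donor signal detected in the acceptor
#'   channel; the 0.08 used by the FRET correction.
#' @param background_d,background_a additive channel backgrounds (a.u.).
#' @param bleach_rate_d,bleach_rate_a per-second single-step photobleaching
#'   rates of the donor and acceptor dye (0 disables bleaching).
#' @param frame_interval seconds per frame.
#' @param n_check_frames number of acceptor direct-excitation frames
#'   prepended and appended to each movie.
#' @return an object of class `photophysics` (a validated list).
#' @export
photophysics <- function(total_intensity = 500, noise_sd = 0,
                         leakage = 0.08,
                         background_d = 0, background_a = 0,
                         bleach_rate_d = 0, bleach_rate_a = 0,
                         frame_interval = 0.1, n_check_frames = 5) {
  if (!is.finite(total_intensity) || total_intensity < 0)
    stop("`total_intensity` must be finite and >= 0")
  if (leakage < 0 || leakage >= 1) stop("`leakage` must lie in [0, 1)")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  if (noise_sd < 0 || bleach_rate_d < 0 || bleach_rate_a < 0)
    stop("rates and noise must be >= 0")
  if (n_check_frames < 0) stop("`n_check_frames` must be >= 0")
  structure(
    list(total_intensity = total_intensity, noise_sd = noise_sd,
         leakage = leakage, background_d = background_d,
         background_a = background_a, bleach_rate_d = bleach_rate_d,
         bleach_rate_a = bleach_rate_a, frame_interval = frame_interval,
         n_check_frames = as.integer(n_check_frames)),
    class = "photophysics")
}

#' Simulate a state path by exact-jump (Gillespie) sampling
#'
#' Draws a continuous-time trajectory of the kinetic model and integrates
#' it onto the camera frame grid: each frame records the fraction of the
#' frame interval spent in every state, so transitions faster than the
#' frame time show up as fractional occupancy (motion blur) rather than
#' being snapped to frame boundaries.
#'
#' @param model a [kinetic_model()].
#' @param n_frames number of frames to simulate (>= 1).
#' @param frame_interval seconds per frame.
#' @param start_state starting state label, or `"stationary"` to draw the
#'   initial state from the stationary distribution.
#' @param seed integer seed; the path is reproducible given the seed.
#' @return object of class `state_path`: list with `state` (majority-
#'   occupancy state index per frame), `occupancy` (n_frames x n_states
#'   matrix of fractional occupancies), `frame_interval`, `states`.
#' @export
simulate_state_path <- function(model, n_frames, frame_interval = 0.1,
                                start_state = "stationary", seed = 1L) {
  stopifnot(inherits(model, "kinetic_model"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  n_states <- length(model$states)
  rates <- model$rates
  exit_rate <- rowSums(rates)

  with_seed(seed, {
    if (identical(start_state, "stationary")) {
      p0 <- stationary_distribution(model)
      s <- sample.int(n_states, 1L, prob = p0)
    } else {
      s <- match(start_state, model$states)
      if (is.na(s)) stop("unknown `start_state`: ", start_state)
    }
    t_total <- n_frames * frame_interval
    occ <- matrix(0, n_frames, n_states,
                  dimnames = list(NULL, model$states))
    t_now <- 0
    while (t_now < t_total) {
      dwell <- if (exit_rate[s] > 0) rexp(1L, exit_rate[s]) else Inf
      t_end <- min(t_now + dwell, t_total)
      # spread the dwell [t_now, t_end) over the frames it covers
      f0 <- floor(t_now / frame_interval)
      f1 <- min(ceiling(t_end / frame_interval) - 1, n_frames - 1L)
      for (f in f0:f1) {
        lo <- max(t_now, f * frame_interval)
        hi <- min(t_end, (f + 1) * frame_interval)
        occ[f + 1L, s] <- occ[f + 1L, s] + (hi - lo) / frame_interval
      }
      t_now <- t_end
      if (t_now >= t_total) break
      s <- sample.int(n_states, 1L, prob = rates[s, ])
    }
    state <- max.col(occ, ties.method = "first")
    structure(list(state = state, occupancy = occ,
                   frame_interval = frame_interval, states = model$states),
              class = "state_path")
  })
}

#' Render a state path into detected donor/acceptor intensities
#'
#' Forward model of the detection chain. The ideal per-frame FRET is the
#' occupancy-weighted state mean plus Gaussian conformational noise with
#' the occupancy-weighted state width. Detected channels are
#' `I_D = T (1 - E) / (1 + l)` and `I_A = T (E + l) / (1 + l)` where `l`
#' is the leakage fraction, a parameterization chosen to be the exact
#' algebraic inverse of the standard correction
#' `E = (I_A - l I_D) / (I_D + I_A)`, so that a noiseless, background-free
#' render followed by [compute_fret()] returns the occupancy-weighted
#' state means exactly. Photobleaching is a single exponential step per
#' dye: after acceptor bleach FRET drops to 0 (donor recovers); after
#' donor bleach both channels fall to background. Direct-excitation check
#' frames at the start and end of the movie carry acceptor signal only
#' while the acceptor is alive.
#'
#' @param path a [simulate_state_path()] result.
#' @param model the generating [kinetic_model()].
#' @param phys a [photophysics()] object.
#' @param seed integer seed for noise and bleach times.
#' @return object of class `sm_trace`: data.frame with columns `frame`,
#'   `I_D`, `I_A`, `is_check_frame`; truth parameters in
#'   `attr(, "truth")`.
#' @export
render_trace <- function(path, model, phys, seed = 1L) {
  stopifnot(inherits(path, "state_path"), inherits(model, "kinetic_model"),
            inherits(phys, "photophysics"))
  if (!identical(path$states, model$states))
    stop("state sets of `path` and `model` disagree")
  n <- length(path$state)
  l <- phys$leakage
  Tint <- phys$total_intensity
  dt <- path$frame_interval

  with_seed(seed, {
    t_bleach_d <- if (phys$bleach_rate_d > 0) rexp(1L, phys$bleach_rate_d) else Inf
    t_bleach_a <- if (phys$bleach_rate_a > 0) rexp(1L, phys$bleach_rate_a) else Inf
    frame_start <- (seq_len(n) - 1L) * dt
    donor_alive <- frame_start < t_bleach_d
    acceptor_alive <- frame_start < t_bleach_a

    E_true <- as.numeric(path$occupancy %*% model$fret_means)
    sd_frame <- as.numeric(path$occupancy %*% model$fret_sd)
    E <- E_true + rnorm(n, 0, sd_frame)
    E[!acceptor_alive] <- 0          # no FRET once the acceptor is dark

    I_D <- Tint * (1 - E) / (1 + l)
    I_A <- Tint * (E + l) / (1 + l)
    I_D[!donor_alive] <- 0
    I_A[!donor_alive] <- 0

    nc <- phys$n_check_frames
    mk_check <- function(alive) {
      ia <- ifelse(alive, Tint, 0)
      data.frame(I_D = rep(0, length(alive)), I_A = ia)
    }
    movie_end <- n * dt
    chk_start <- mk_check(rep(t_bleach_a > 0, nc))
    chk_end <- mk_check(rep(t_bleach_a > movie_end, nc))

    df <- rbind(
      cbind(chk_start, is_check_frame = TRUE),
      data.frame(I_D = I_D, I_A = I_A, is_check_frame = FALSE),
      cbind(chk_end, is_check_frame = TRUE))
    m <- nrow(df)
    if (phys$noise_sd > 0) {
      df$I_D <- df$I_D + rnorm(m, 0, phys$noise_sd)
      df$I_A <- df$I_A + rnorm(m, 0, phys$noise_sd)
    }
    df$I_D <- df$I_D + phys$background_d
    df$I_A <- df$I_A + phys$background_a
    out <- data.frame(frame = seq_len(m) - 1L, df, row.names = NULL)
    structure(out, class = c("sm_trace", "data.frame"),
              truth = list(path = path, E_true = E_true,
                           t_bleach_d = t_bleach_d, t_bleach_a = t_bleach_a,
                           phys = phys, seed = seed))
  })
}

#' Simulate a set of independent smFRET traces
#'
#' Stands in for a stalled-complex TIRF movie campaign: each trace gets its
#' own state path and photophysics realization, with per-trace seeds
#' derived deterministically from one master seed.
#'
#' @param model a [kinetic_model()].
#' @param phys a [photophysics()].
#' @param n_traces number of traces.
#' @param n_frames payload frames per trace (check frames are added on top).
#' @param seed master seed.
#' @param start_state passed to [simulate_state_path()].
#' @return object of class `sm_trace_set`: list of `sm_trace` objects with
#'   a `manifest` attribute recording all truth parameters and seeds.
#' @export
simulate_trace_set <- function(model, phys, n_traces, n_frames, seed = 1L,
                               start_state = "stationary") {
  n_traces <- as.integer(n_traces)
  if (n_traces < 1L) stop("`n_traces` must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_traces)
  path_seeds <- seeds[seq_len(n_traces)]
  render_seeds <- seeds[n_traces + seq_len(n_traces)]
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    p <- simulate_state_path(model, n_frames, phys$frame_interval,
                             start_state = start_state,
                             seed = path_seeds[i])
    traces[[i]] <- render_trace(p, model, phys, seed = render_seeds[i])
  }
  manifest <- list(model = model, phys = phys, n_traces = n_traces,
                   n_frames = n_frames, master_seed = seed,
                   path_seeds = path_seeds, render_seeds = render_seeds,
                   start_state = start_state)
  structure(traces, class = "sm_trace_set", manifest = manifest)
}

#' @export
print.sm_trace_set <- function(x, ...) {
  m <- attr(x, "manifest")
  cat("smFRET trace set:", length(x), "traces x",
      m$n_frames, "frames (seed", m$master_seed, ")\n")
  invisible(x)
}
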