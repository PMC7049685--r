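#' Corrected FRET efficiency of a donor/acceptor trace
#'
#' Applies the standard leakage/background correction
#' `E = (I_A - leakage * I_D) / (I_D + I_A)` to the background-subtracted
#' channel intensities. Direct-excitation check frames are excluded, and
#' frames whose total background-subtracted intensity falls at or below
#' `intensity_floor` (e.g. after both dyes have bleached) are dropped.
#'
#' @param trace an `sm_trace` (or any data.frame with columns `frame`,
#'   `I_D`, `I_A` and optionally `is_check_frame`).
#' @param leakage donor -> acceptor leakage fraction, in `[0, 1)`.
#' @param background_d,background_a constant channel backgrounds to
#'   subtract (a.u.).
#' @param intensity_floor minimum total intensity (post subtraction) for a
#'   frame to be retained.
#' @return object of class `fret_series`: list with `E` (corrected FRET per
#'   retained frame), `frames` (their original frame indices) and counts.
#'   Values outside the soft physical band `[-0.2, 1.2]` are kept but
#'   counted in `n_outside_band` (noise can legitimately push corrected E
#'   slightly outside `[0, 1]`).
#' @export
compute_fret <- function(trace, leakage = 0.08,
                         background_d = 0, background_a = 0,
                         intensity_floor = 0) {
  if (!all(c("I_D", "I_A") %in% names(trace)))
    stop("`trace` must have columns I_D and I_A")
  if (leakage < 0 || leakage >= 1) stop("`leakage` must lie in [0, 1)")
  if (!is.finite(background_d) || !is.finite(background_a))
    stop("backgrounds must be finite")
  keep <- if ("is_check_frame" %in% names(trace)) !trace$is_check_frame
          else rep(TRUE, nrow(trace))
  id <- trace$I_D[keep] - background_d
  ia <- trace$I_A[keep] - background_a
  frames <- if ("frame" %in% names(trace)) trace$frame[keep]
            else which(keep) - 1L
  tot <- id + ia
  ok <- is.finite(tot) & tot > intensity_floor
  if (!any(ok))
    stop("all frames fall at or below the intensity floor; empty trace")
  E <- (ia[ok] - leakage * id[ok]) / tot[ok]
  structure(list(E = E, frames = frames[ok],
                 n_dropped = sum(!ok), n_frames = length(E),
                 n_outside_band = sum(E < -0.2 | E > 1.2),
                 leakage = leakage),
            class = "fret_series")
}

#' Count downward photobleaching steps in an intensity series
#'
#' Recursive binary segmentation on a single series (typically
#' `I_D + I_A`): at each level the split point minimizing the two-segment
#' residual sum of squares is accepted when the level drop exceeds
#' `threshold` times the robust noise scale (MAD of first differences /
#' sqrt(2)) and both segments are at least `min_seg` frames long. Only
#' downward steps are counted, matching single-step dye photobleaching.
#'
#' @param x numeric intensity series.
#' @param min_seg minimum segment length (frames).
#' @param threshold step size in units of the noise scale.
#' @return integer count of detected downward steps.
#' @export
detect_bleach_steps <- function(x, min_seg = 10L, threshold = 4) {
  noise <- mad(diff(x)) / sqrt(2)
  if (!is.finite(noise) || noise == 0) noise <- max(sd(x) / 10, 1e-12)
  count_steps <- function(x) {
    n <- length(x)
    if (n < 2L * min_seg) return(0L)
    css <- cumsum(x); css2 <- cumsum(x^2)
    ks <- seq(min_seg, n - min_seg)
    m1 <- css[ks] / ks
    m2 <- (css[n] - css[ks]) / (n - ks)
    sse <- (css2[ks] - ks * m1^2) + ((css2[n] - css2[ks]) - (n - ks) * m2^2)
    k <- ks[which.min(sse)]
    drop <- mean(x[seq_len(k)]) - mean(x[(k + 1L):n])
    if (drop > threshold * noise) {
      1L + count_steps(x[seq_len(k)]) + count_steps(x[(k + 1L):n])
    } else 0L
  }
  count_steps(as.numeric(x))
}

#' Quality-control selection of traces
#'
#' Applies the standard smFRET trace filters and returns the surviving
#' subset with a per-trace rejection log. Filters (each can be disabled):
#' \describe{
#'   \item{acceptor_check}{mean acceptor signal in the leading
#'     direct-excitation check frames must exceed `background_a +
#'     acceptor_min`; traces lacking an acceptor dye are removed.}
#'   \item{single_pair}{at most one photobleaching step on the total
#'     intensity `I_D + I_A` ([detect_bleach_steps()]); multi-dye spots
#'     show multiple steps and are removed.}
#'   \item{mid_band}{when a numeric band `c(lo, hi)` is supplied, the
#'     corrected FRET series must visit it at least once; used to keep
#'     only traces that sampled the open (mid-FRET) state.}
#' }
#'
#' @param traces an `sm_trace_set` or list of `sm_trace` objects.
#' @param acceptor_check,single_pair logical switches.
#' @param mid_band `NULL` (off) or numeric `c(lo, hi)` FRET band.
#' @param acceptor_min minimum above-background acceptor check signal
#'   (a.u.).
#' @param leakage,background_d,background_a passed to [compute_fret()] for
#'   the mid-band filter.
#' @param min_seg,threshold passed to [detect_bleach_steps()].
#' @return the accepted subset (same class as input), with a data.frame of
#'   rejections in `attr(, "rejections")` (columns `trace`, `reason`).
#' @export
select_traces <- function(traces, acceptor_check = TRUE, single_pair = TRUE,
                          mid_band = NULL, acceptor_min = 50,
                          leakage = 0.08, background_d = 0, background_a = 0,
                          min_seg = 10L, threshold = 4) {
  reasons <- character(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    chk <- tr$is_check_frame
    if (acceptor_check) {
      lead <- which(chk & cumsum(!chk) == 0)   # leading check block
      if (length(lead) == 0L ||
          mean(tr$I_A[lead]) - background_a <= acceptor_min) {
        reasons[i] <- "no acceptor"
        next
      }
    }
    if (single_pair) {
      tot <- (tr$I_D + tr$I_A)[!chk]
      if (detect_bleach_steps(tot, min_seg, threshold) >= 2L) {
        reasons[i] <- "multiple bleach steps"
        next
      }
    }
    if (!is.null(mid_band)) {
      fs <- tryCatch(
        compute_fret(tr, leakage, background_d, background_a),
        error = function(e) NULL)
      if (is.null(fs) || !any(fs$E >= mid_band[1] & fs$E <= mid_band[2])) {
        reasons[i] <- "never visited mid-FRET band"
        next
      }
    }
  }
  keep <- reasons == ""
  out <- traces[keep]
  attributes(out) <- c(attributes(out),
                       list(class = class(traces)))
  rej <- data.frame(trace = which(!keep), reason = reasons[!keep])
  attr(out, "rejections") <- rej
  attr(out, "manifest") <- attr(traces, "manifest")
  out
}

#' Non-overlapping window means of a FRET series
#'
#' @param fret a `fret_series` or numeric vector.
#' @param window window length in frames; trailing partial windows are
#'   dropped.
#' @return numeric vector of window means.
#' @export
window_means <- function(fret, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1")
  E <- if (inherits(fret, "fret_series")) fret$E else as.numeric(fret)
  n <- (length(E) %/% window) * window
  if (n == 0L) return(numeric(0))
  colMeans(matrix(E[seq_len(n)], nrow = window))
}

#' Pooled FRET histogram from window-averaged traces
#'
#' Each trace is represented by its non-overlapping `window`-frame mean
#' FRET values; values are pooled across traces and binned into a density
#' histogram (integral 1).
#'
#' @param fret_traces list of `fret_series` (or numeric vectors).
#' @param window averaging window in frames (default 5).
#' @param bins numeric vector of bin edges; default 40 uniform bins on
#'   `[-0.2, 1.2]`.
#' @return object of class `fret_histogram`: list with `bin_edges`,
#'   `density`, `counts`, `n_traces`, `n_points`, `window`, plus the pooled
#'   `values`.
#' @export
build_histogram <- function(fret_traces, window = 5L,
                            bins = seq(-0.2, 1.2, length.out = 41L)) {
  if (inherits(fret_traces, "fret_series") || is.numeric(fret_traces))
    fret_traces <- list(fret_traces)
  if (length(fret_traces) == 0L) stop("at least one trace is required")
  vals <- unlist(lapply(fret_traces, window_means, window = window))
  if (length(vals) == 0L) stop("no complete windows in any trace")
  edges <- sort(bins)
  v <- vals[vals >= edges[1] & vals <= edges[length(edges)]]
  h <- hist(v, breaks = edges, plot = FALSE)
  structure(list(bin_edges = edges, density = h$density, counts = h$counts,
                 n_traces = length(fret_traces), n_points = length(vals),
                 window = window, values = vals),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("FRET histogram:", x$n_points, "window means from", x$n_traces,
      "traces (window", x$window, "frames)\n")
  invisible(x)
}

#' @importFrom graphics hist
NULL
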