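#' Continuous-time kinetic model of initiation-complex conformations
#'
#' Defines the conformational scheme observed by smFRET between the -16/+16
#' promoter labels: a set of states (canonically closed, open, scrunched),
#' one FRET efficiency and emission width per state, and the first-order
#' rate constants connecting them. The model is both the ground truth for
#' the trace simulator and the target of hidden-Markov inference.
#'
#' States are stored sorted by FRET mean ascending, so for the canonical
#' three-state scheme index 1 is closed, 2 open, 3 scrunched. The generator
#' matrix has off-diagonal entries `k[i, j]` = rate (per second) of the
#' i -> j transition and diagonal entries equal to minus the row sums.
#'
#' @param rates square numeric matrix of off-diagonal rate constants
#'   (s^-1); the diagonal is ignored and recomputed. Dimnames, if present,
#'   must match `states`.
#' @param fret_means FRET efficiency of each state, in `[0, 1]`, strictly
#'   increasing once states are sorted.
#' @param fret_sd per-state emission standard deviation of the corrected
#'   FRET signal (recycled to the number of states).
#' @param states character state labels; defaults to
#'   `c("closed", "open", "scrunched")` for three states.
#' @return An object of class `kinetic_model` with elements `states`,
#'   `fret_means`, `fret_sd`, `rates` (off-diagonal rate matrix) and `Q`
#'   (the generator).
#' @examples
#' m <- three_state_model(k_open = 0.2, k_close = 0.4,
#'                        k_scrunch = 0.6, k_unscrunch = 0.1)
#' stationary_distribution(m)
#' @export
kinetic_model <- function(rates, fret_means, fret_sd = 0.06, states = NULL) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (ncol(rates) != n) stop("`rates` must be a square matrix")
  if (length(fret_means) != n)
    stop("`fret_means` must have one entry per state")
  if (is.null(states)) {
    states <- if (n == 3L) c("closed", "open", "scrunched")
              else paste0("state", seq_len(n))
  }
  if (length(states) != n) stop("`states` must have one label per state")
  diag(rates) <- 0
  off <- rates[row(rates) != col(rates)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal rate constants must be finite and >= 0")
  if (any(!is.finite(fret_means)) || any(fret_means < 0 | fret_means > 1))
    stop("`fret_means` must lie in [0, 1]")
  fret_sd <- rep_len(fret_sd, n)
  if (any(fret_sd < 0)) stop("`fret_sd` must be >= 0")

  ord <- order(fret_means)
  fret_means <- fret_means[ord]
  if (any(diff(fret_means) <= 0))
    stop("state FRET means must be distinct (strictly increasing once sorted)")
  states <- states[ord]
  fret_sd <- fret_sd[ord]
  rates <- rates[ord, ord, drop = FALSE]
  dimnames(rates) <- list(states, states)

  Q <- rates
  diag(Q) <- -rowSums(rates)
  structure(
    list(states = states, fret_means = setNames(fret_means, states),
         fret_sd = setNames(fret_sd, states), rates = rates, Q = Q),
    class = "kinetic_model")
}

#' Canonical closed/open/scrunched three-state scheme
#'
#' Convenience constructor for the scheme of the +2 initiation complex:
#' closed <-> open <-> scrunched, with no direct closed <-> scrunched path.
#' Default FRET means are the free-DNA/open/scrunched peak positions
#' (0.14, 0.38, 0.56) observed for the wild-type complex.
#'
#' @param k_open,k_close closed -> open and open -> closed rates (s^-1).
#' @param k_scrunch,k_unscrunch open -> scrunched and scrunched -> open
#'   rates (s^-1); their ratio is the scrunching equilibrium constant.
#' @param fret_means,fret_sd passed to [kinetic_model()].
#' @return a `kinetic_model`.
#' @export
three_state_model <- function(k_open = 0.2, k_close = 0.4,
                              k_scrunch = 0.6, k_unscrunch = 0.1,
                              fret_means = c(0.14, 0.38, 0.56),
                              fret_sd = 0.06) {
  rates <- matrix(0, 3, 3)
  rates[1, 2] <- k_open
  rates[2, 1] <- k_close
  rates[2, 3] <- k_scrunch
  rates[3, 2] <- k_unscrunch
  kinetic_model(rates, fret_means, fret_sd)
}

#' Stationary distribution of a kinetic model
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by replacing one balance equation with
#' the normalization constraint (exact linear solve, no simulation).
#'
#' @param model a [kinetic_model()].
#' @return named numeric vector of stationary state probabilities.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  Q <- model$Q
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi_hat <- solve(A, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  setNames(pi_hat, model$states)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model:", length(x$states), "states\n")
  cat("  FRET means:",
      paste(sprintf("%s=%.3g", x$states, x$fret_means), collapse = ", "),
      "\n")
  cat("  Rate matrix (s^-1, off-diagonal):\n")
  print(signif(x$rates, 4))
  invisible(x)
}
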