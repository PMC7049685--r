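#' Closed-form forward models for the ensemble assays
#'
#' `quadratic_binding()` is the tight-binding anisotropy isotherm: with
#' total protein `P_t` titrated into labeled DNA at fixed total
#' concentration `D_t`, the bound fraction is the closed-form root
#' \deqn{f_b = \frac{(K_d + P_t + D_t) - \sqrt{(K_d + P_t + D_t)^2 -
#'   4 P_t D_t}}{2 D_t}}
#' and the observed anisotropy is `r_f + (r_b - r_f) f_b`. This form is
#' required when `K_d` is comparable to `D_t`, where ligand depletion makes
#' the simple hyperbola invalid.
#'
#' `hyperbola()` is `F0 + dF * x / (K_d + x)`; `michaelis_menten()` is
#' `k_cat * S / (K_m + S)`; `exponential_decay()` is
#' `baseline + amplitude * exp(-k * t)`.
#'
#' @param P_t total titrant (protein) concentration, same units as `K_d`
#'   and `D_t`.
#' @param K_d dissociation constant.
#' @param D_t total labeled-DNA concentration.
#' @param r_f,r_b anisotropy of free and bound DNA.
#' @return numeric response vector.
#' @export
quadratic_binding <- function(P_t, K_d, D_t, r_f, r_b) {
  s <- K_d + P_t + D_t
  disc <- pmax(s^2 - 4 * P_t * D_t, 0)
  fb <- (s - sqrt(disc)) / (2 * D_t)
  r_f + (r_b - r_f) * fb
}

#' @rdname quadratic_binding
#' @param x ligand concentration.
#' @param F0 response at zero ligand.
#' @param dF response amplitude (may be negative).
#' @export
hyperbola <- function(x, F0, dF, K_d) F0 + dF * x / (K_d + x)

#' @rdname quadratic_binding
#' @param S substrate concentration.
#' @param k_cat turnover number (s^-1).
#' @param K_m Michaelis constant.
#' @export
michaelis_menten <- function(S, k_cat, K_m) k_cat * S / (K_m + S)

#' @rdname quadratic_binding
#' @param t time (s).
#' @param baseline asymptotic signal.
#' @param amplitude decaying amplitude.
#' @param k decay rate constant (s^-1).
#' @export
exponential_decay <- function(t, baseline, amplitude, k)
  baseline + amplitude * exp(-k * t)

.titration_models <- list(
  quadratic_binding = list(
    fun = function(x, p) quadratic_binding(x, p[["K_d"]], p[["D_t"]],
                                           p[["r_f"]], p[["r_b"]]),
    pars = c("K_d", "D_t", "r_f", "r_b")),
  hyperbola = list(
    fun = function(x, p) hyperbola(x, p[["F0"]], p[["dF"]], p[["K_d"]]),
    pars = c("F0", "dF", "K_d")),
  michaelis_menten = list(
    fun = function(x, p) michaelis_menten(x, p[["k_cat"]], p[["K_m"]]),
    pars = c("k_cat", "K_m")),
  exponential_decay = list(
    fun = function(x, p) exponential_decay(x, p[["baseline"]],
                                           p[["amplitude"]], p[["k"]]),
    pars = c("baseline", "amplitude", "k")))

#' Generate a titration or time-course dataset from a stated forward model
#'
#' @param kind one of `"quadratic_binding"`, `"hyperbola"`,
#'   `"michaelis_menten"`, `"exponential_decay"`.
#' @param truth named list/vector of the model's true parameters
#'   (see [quadratic_binding()] and friends for names).
#' @param x concentration (or time) grid, nonnegative.
#' @param noise_sd Gaussian noise added to the response; 0 gives the exact
#'   forward curve.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @param x_unit,y_unit unit tags carried on the dataset and checked by the
#'   fitting functions when they are told what to expect.
#' @return a `titration` data.frame with columns `x`, `y` and attributes
#'   `kind`, `truth`, `x_unit`, `y_unit`.
#' @export
generate_titration <- function(kind, truth, x, noise_sd = 0, seed = 1L,
                               x_unit = NA_character_,
                               y_unit = NA_character_) {
  spec <- .titration_models[[kind]]
  if (is.null(spec))
    stop("unsupported model kind: ", kind)
  if (length(x) == 0L || any(!is.finite(x)) || any(x < 0))
    stop("`x` must be nonempty, finite and nonnegative")
  missing_pars <- setdiff(spec$pars, names(truth))
  if (length(missing_pars))
    stop("`truth` is missing parameter(s): ",
         paste(missing_pars, collapse = ", "))
  x <- sort(x)
  y <- spec$fun(x, truth)
  if (noise_sd > 0) y <- y + with_seed(seed, rnorm(length(x), 0, noise_sd))
  structure(data.frame(x = x, y = y),
            class = c("titration", "data.frame"),
            kind = kind, truth = truth, noise_sd = noise_sd,
            x_unit = x_unit, y_unit = y_unit)
}
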