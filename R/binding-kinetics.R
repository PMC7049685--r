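# Ensemble assay fits. All nonlinear fits go through minpack.lm::nlsLM
# (Levenberg-Marquardt), unweighted by default, with asymptotic standard
# errors from the fit covariance.

.check_unit <- function(data, expected, which = "x") {
  if (is.na(expected)) return(invisible())
  got <- attr(data, paste0(which, "_unit"))
  if (!is.null(got) && !is.na(got) && !identical(got, expected))
    stop(sprintf("%s-axis unit mismatch: dataset is tagged '%s', fit expects '%s'",
                 which, got, expected))
  invisible()
}

.kfit <- function(object, params, se, model_name, data, warnings = character(0)) {
  structure(list(params = params, se = se, model = model_name,
                 data = data, warnings = warnings, object = object),
            class = "kfit")
}

#' @export
print.kfit <- function(x, ...) {
  cat("Nonlinear fit:", x$model, "(n =", nrow(x$data), "points)\n")
  tab <- data.frame(estimate = signif(x$params, 6),
                    std_error = signif(x$se, 3))
  print(tab)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.nls_se <- function(fit, pars) {
  se <- rep(NA_real_, length(pars))
  names(se) <- pars
  v <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(v)) {
    d <- sqrt(pmax(diag(v), 0))
    se[names(d)] <- d
  }
  se
}

#' Quadratic tight-binding fit of an anisotropy titration
#'
#' Fits the closed-form tight-binding isotherm (see
#' [quadratic_binding()]) to observed anisotropy versus total protein,
#' with the labeled-DNA concentration `D_t` held at its known value.
#' Estimates `K_d`, `r_f` and `r_b`. Because the probe DNA is at
#' nanomolar concentration comparable to the `K_d`, ligand depletion is
#' substantial and the simple hyperbola would bias `K_d`; the quadratic
#' form accounts for it exactly.
#'
#' @param data a `titration` (or data.frame with `x` = total protein and
#'   `y` = observed anisotropy).
#' @param D_t total labeled-DNA concentration (same units as `x`).
#' @param x_unit optional expected concentration unit; errors on mismatch
#'   with the dataset's tag.
#' @return a `kfit` with parameters `K_d`, `r_f`, `r_b`. A warning flag is
#'   attached if the titration never approaches saturation (maximum
#'   fitted bound fraction < 0.7), which leaves `K_d` ill-constrained.
#' @export
fit_quadratic_binding <- function(data, D_t, x_unit = NA_character_) {
  if (D_t <= 0) stop("`D_t` must be > 0")
  if (nrow(data) < 5L) stop("need at least 5 titration points")
  .check_unit(data, x_unit, "x")
  df <- data.frame(x = data$x, y = data$y)
  # The RSS profile in K_d is flat-then-cliff in the stoichiometric regime
  # (K_d << D_t), so naive starts stall at a bound. The anisotropies enter
  # linearly, so profile them out exactly on a log-spaced K_d grid and
  # start the full fit from the profiled optimum (variable projection).
  profile_rss <- function(kd) {
    fb <- quadratic_binding(df$x, kd, D_t, 0, 1)
    X <- cbind(1 - fb, fb)
    r <- df$y - X %*% qr.solve(X, df$y)
    sum(r^2)
  }
  xpos <- df$x[df$x > 0]
  kd_grid <- 10^seq(log10(min(xpos) / 100), log10(max(xpos) * 100),
                    length.out = 200L)
  kd0 <- kd_grid[which.min(vapply(kd_grid, profile_rss, 0))]
  fb0 <- quadratic_binding(df$x, kd0, D_t, 0, 1)
  ab <- qr.solve(cbind(1 - fb0, fb0), df$y)
  fit <- minpack.lm::nlsLM(
    y ~ quadratic_binding(x, K_d, D_t, r_f, r_b),
    data = df,
    start = list(K_d = kd0, r_f = ab[1], r_b = ab[2]),
    lower = c(K_d = 0, r_f = -Inf, r_b = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- coef(fit)
  warnings <- character(0)
  fb_max <- max((quadratic_binding(df$x, p[["K_d"]], D_t, 0, 1)))
  if (fb_max < 0.7)
    warnings <- "titration never approaches saturation; K_d ill-constrained"
  .kfit(fit, c(p, D_t = D_t), c(.nls_se(fit, names(p)), D_t = NA),
        "quadratic tight-binding (anisotropy)", df, warnings)
}

#' Hyperbolic binding fit
#'
#' Fits `y = F0 + dF * x / (K_d + x)` — the model used for composite
#' initiating-nucleotide Kd estimation from 2-aminopurine fluorescence
#' titrations, valid when the titrant is in large excess over the complex.
#'
#' @inheritParams fit_quadratic_binding
#' @return a `kfit` with parameters `F0`, `dF`, `K_d`; warns when the
#'   fitted `K_d` exceeds the largest concentration titrated.
#' @export
fit_hyperbola <- function(data, x_unit = NA_character_) {
  if (nrow(data) < 5L) stop("need at least 5 titration points")
  .check_unit(data, x_unit, "x")
  df <- data.frame(x = data$x, y = data$y)
  F00 <- df$y[which.min(df$x)]
  dF0 <- df$y[which.max(df$x)] - F00
  if (dF0 == 0) dF0 <- max(abs(df$y)) * 0.1 + 1e-6
  kd0 <- max(df$x[which.min(abs(df$y - (F00 + dF0 / 2)))],
             min(df$x[df$x > 0], na.rm = TRUE))
  fit <- minpack.lm::nlsLM(
    y ~ hyperbola(x, F0, dF, K_d), data = df,
    start = list(F0 = F00, dF = dF0, K_d = kd0),
    lower = c(F0 = -Inf, dF = -Inf, K_d = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- coef(fit)
  warnings <- character(0)
  if (max(df$x) < p[["K_d"]])
    warnings <- "fitted K_d exceeds the titrated range; poorly constrained"
  .kfit(fit, p, .nls_se(fit, names(p)), "hyperbolic binding", df, warnings)
}

#' Michaelis-Menten fit of RNA-synthesis rate constants
#'
#' Fits `v = k_cat * S / (K_m + S)` to rate constants of 2-mer RNA
#' synthesis versus initiating-NTP concentration and reports the
#' catalytic efficiency `k_cat / K_m` with an error propagated from the
#' fit covariance. Rates measured as concentration per time are first
#' divided by the limiting enzyme concentration.
#'
#' @param data titration of rates (`x` = substrate, `y` = rate).
#' @param limiting_enzyme limiting enzyme-DNA complex concentration; set
#'   to 1 (default) when `y` is already a first-order rate constant in
#'   s^-1.
#' @inheritParams fit_quadratic_binding
#' @return a `kfit` with parameters `k_cat`, `K_m`, `efficiency`.
#' @export
fit_michaelis_menten <- function(data, limiting_enzyme = 1,
                                 x_unit = NA_character_) {
  if (nrow(data) < 5L) stop("need at least 5 rate points")
  if (limiting_enzyme <= 0) stop("`limiting_enzyme` must be > 0")
  .check_unit(data, x_unit, "x")
  df <- data.frame(x = data$x, y = data$y / limiting_enzyme)
  kcat0 <- max(df$y)
  km0 <- max(df$x[which.min(abs(df$y - kcat0 / 2))],
             min(df$x[df$x > 0], na.rm = TRUE))
  fit <- minpack.lm::nlsLM(
    y ~ michaelis_menten(x, k_cat, K_m), data = df,
    start = list(k_cat = kcat0, K_m = km0),
    lower = c(k_cat = 0, K_m = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- coef(fit)
  eff <- p[["k_cat"]] / p[["K_m"]]
  v <- tryCatch(vcov(fit), error = function(e) matrix(NA, 2, 2))
  grad <- c(1 / p[["K_m"]], -p[["k_cat"]] / p[["K_m"]]^2)
  eff_se <- sqrt(max(drop(t(grad) %*% v %*% grad), 0))
  warnings <- character(0)
  if (max(df$x) < p[["K_m"]])
    warnings <- "substrate range below fitted K_m; poorly constrained"
  .kfit(fit, c(p, efficiency = eff),
        c(.nls_se(fit, names(p)), efficiency = eff_se),
        "Michaelis-Menten", df, warnings)
}

#' Fold change in 2-aminopurine fluorescence
#'
#' Ratio of background-subtracted complex fluorescence to free-DNA
#' fluorescence — the promoter-melting readout: base unstacking on
#' melting raises 2AP emission, so larger fold changes mean more melting.
#'
#' @param intensity_complex,intensity_free_dna background-subtracted
#'   intensities (a.u.).
#' @param err_complex,err_free optional standard errors; when supplied the
#'   ratio's propagated error is attached as `attr(, "se")`.
#' @return fold change (numeric scalar).
#' @export
fold_change <- function(intensity_complex, intensity_free_dna,
                        err_complex = NULL, err_free = NULL) {
  if (!is.finite(intensity_free_dna) || intensity_free_dna <= 0)
    stop("free-DNA intensity must be finite and > 0")
  fold <- intensity_complex / intensity_free_dna
  if (!is.null(err_complex) && !is.null(err_free)) {
    se <- abs(fold) * sqrt((err_complex / intensity_complex)^2 +
                           (err_free / intensity_free_dna)^2)
    attr(fold, "se") <- se
  }
  fold
}

#' Molar RNA synthesized from gel band intensities
#'
#' `RNA (uM) = R / (R + A) * [ATP]` where `R` and `A` are the band
#' intensities of the RNA product and free ATP in the same lane.
#'
#' @param R RNA product band intensity (a.u., >= 0).
#' @param A free-ATP band intensity (a.u., >= 0).
#' @param atp_total total ATP concentration in the reaction (uM).
#' @return RNA synthesized (uM).
#' @export
quantify_rna <- function(R, A, atp_total) {
  if (any(R < 0) || any(A < 0)) stop("band intensities must be >= 0")
  if (any(R + A == 0)) stop("R + A must be > 0")
  R / (R + A) * atp_total
}

#' Abortive and runoff RNA amounts and their ratio
#'
#' Converts each product band of a gel lane set to a molar amount and
#' summarizes initiation efficiency: the abortive amount is the sum over
#' the 3-7-mer bands (2-mers are genuine initiation events and are
#' excluded by definition), and the abortive:runoff ratio compares it to
#' the full-length product.
#'
#' Multi-band convention (`convention = "shared"`, default): each band is
#' quantified as `R_band / (R_total + A) * [ATP]`, with `R_total` the sum
#' over all product bands, so that band amounts are additive and bounded
#' by `[ATP]`; the single-band formula of [quantify_rna()] is the one-band
#' special case. `convention = "per_band"` applies `R_band / (R_band + A)`
#' to each band independently.
#'
#' @param lanes data.frame with columns `band_label` (e.g. `"runoff"`,
#'   `"2mer"`, ..., `"7mer"`, `"free_ATP"`) and `intensity` (a.u.).
#' @param atp_total total ATP (uM).
#' @param convention `"shared"` or `"per_band"` (see Details).
#' @return list with `runoff_uM`, `abortive_3to7_uM`, `ratio` (NA with a
#'   flag when no runoff product is present), `per_band_uM`.
#' @export
abortive_runoff_ratio <- function(lanes, atp_total,
                                  convention = c("shared", "per_band")) {
  convention <- match.arg(convention)
  if (!all(c("band_label", "intensity") %in% names(lanes)))
    stop("`lanes` needs columns band_label and intensity")
  if (any(lanes$intensity < 0)) stop("band intensities must be >= 0")
  is_atp <- lanes$band_label == "free_ATP"
  if (!any(is_atp)) stop("`lanes` must include a free_ATP band")
  A <- sum(lanes$intensity[is_atp])
  prod <- lanes[!is_atp, , drop = FALSE]
  if (nrow(prod) == 0L) stop("`lanes` must include at least one product band")
  R_tot <- sum(prod$intensity)
  per_band <- if (convention == "shared") {
    prod$intensity / (R_tot + A) * atp_total
  } else {
    prod$intensity / (prod$intensity + A) * atp_total
  }
  names(per_band) <- prod$band_label
  runoff <- sum(per_band[prod$band_label == "runoff"])
  abortive <- sum(per_band[prod$band_label %in%
                             paste0(3:7, "mer")])
  ratio <- if (runoff > 0) abortive / runoff else NA_real_
  list(runoff_uM = runoff, abortive_3to7_uM = abortive, ratio = ratio,
       runoff_undefined = runoff <= 0, per_band_uM = per_band)
}

#' Single-exponential fit of a bubble-collapse time course
#'
#' Fits `y = baseline + amplitude * exp(-k * t)` to a 2AP fluorescence
#' time course. Upstream bubble collapse re-anneals the -4 base and
#' quenches 2AP emission, so a decaying amplitude reports collapse and its
#' rate constant measures collapse speed. When the fitted amplitude is
#' statistically indistinguishable from zero (|amplitude| < 2 standard
#' errors), or the trace is flat, a no-collapse verdict is returned
#' instead of rate estimates.
#'
#' @param timecourse data.frame with `x` = time (s) and `y` = normalized
#'   fluorescence; at least 10 points.
#' @return a `kfit` with parameters `amplitude`, `k_collapse`, `baseline`
#'   and a logical element `no_collapse`.
#' @export
fit_exponential_collapse <- function(timecourse) {
  if (nrow(timecourse) < 10L) stop("need at least 10 time points")
  df <- data.frame(x = timecourse$x, y = timecourse$y)
  span <- diff(range(df$y))
  flat <- span < 1e-12 * max(abs(df$y), 1)
  if (!flat) {
    amp0 <- df$y[which.min(df$x)] - df$y[which.max(df$x)]
    base0 <- df$y[which.max(df$x)]
    k0 <- 1 / max(diff(range(df$x)) / 3, 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ exponential_decay(x, baseline, amplitude, k),
                        data = df,
                        start = list(baseline = base0, amplitude = amp0,
                                     k = k0),
                        lower = c(baseline = -Inf, amplitude = -Inf,
                                  k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  } else fit <- NULL
  if (is.null(fit)) {
    out <- .kfit(NULL,
                 c(amplitude = 0, k_collapse = NA_real_,
                   baseline = mean(df$y)),
                 c(amplitude = NA, k_collapse = NA, baseline = NA),
                 "single-exponential collapse", df,
                 "no measurable collapse")
    out$no_collapse <- TRUE
    return(out)
  }
  p <- coef(fit)
  se <- .nls_se(fit, names(p))
  no_collapse <- is.finite(se[["amplitude"]]) &&
    abs(p[["amplitude"]]) < 2 * se[["amplitude"]]
  out <- .kfit(fit,
               c(amplitude = p[["amplitude"]], k_collapse = p[["k"]],
                 baseline = p[["baseline"]]),
               c(amplitude = se[["amplitude"]], k_collapse = se[["k"]],
                 baseline = se[["baseline"]]),
               "single-exponential collapse", df,
               if (no_collapse) "amplitude indistinguishable from 0"
               else character(0))
  out$no_collapse <- no_collapse
  out
}
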