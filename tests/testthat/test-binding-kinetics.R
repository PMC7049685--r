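test_that("noiseless fits return the generating truth", {
  # randomized truths spanning two orders of magnitude, seeded
  set.seed(71)
  for (i in 1:4) {
    kd <- 10^runif(1, -1, 1) * 0.12
    d <- generate_titration("quadratic_binding",
                            list(K_d = kd, D_t = 5, r_f = 0.15, r_b = 0.3),
                            x = c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 8, 12,
                                  20, 35, 50))
    f <- fit_quadratic_binding(d, D_t = 5)
    expect_equal(f$params[["K_d"]], kd, tolerance = 1e-6)

    kdh <- 10^runif(1, 1, 3)
    dh <- generate_titration("hyperbola", list(F0 = 1, dF = 2, K_d = kdh),
                             x = seq(0, 10 * kdh, length.out = 12))
    fh <- fit_hyperbola(dh)
    expect_equal(fh$params[["K_d"]], kdh, tolerance = 1e-6)

    kcat <- runif(1, 0.1, 2)
    km <- 10^runif(1, 1, 3)
    dm <- generate_titration("michaelis_menten",
                             list(k_cat = kcat, K_m = km),
                             x = seq(0, 10 * km, length.out = 10))
    fm <- fit_michaelis_menten(dm)
    expect_equal(fm$params[["k_cat"]], kcat, tolerance = 1e-6)
    expect_equal(fm$params[["K_m"]], km, tolerance = 1e-6)
    expect_equal(fm$params[["efficiency"]], kcat / km, tolerance = 1e-10)
  }
})

test_that("tight-binding model reduces to the hyperbola when D_t is small", {
  kd <- 10
  x <- seq(0, 200, length.out = 15)[-1]
  shallow <- quadratic_binding(x, kd, D_t = kd / 100, r_f = 0, r_b = 1)
  hyp <- hyperbola(x, 0, 1, kd)
  expect_lt(max(abs(shallow - hyp) / hyp), 0.01)
  # and the two fits agree on K_d in that regime
  d <- generate_titration("quadratic_binding",
                          list(K_d = kd, D_t = kd / 100, r_f = 0.1,
                               r_b = 0.3),
                          x = seq(0.5, 200, length.out = 12))
  f_quad <- fit_quadratic_binding(d, D_t = kd / 100)
  f_hyp <- fit_hyperbola(d)
  expect_equal(f_quad$params[["K_d"]], f_hyp$params[["K_d"]],
               tolerance = 0.01)
})

test_that("saturation model value approaches r_b at large protein", {
  expect_equal(quadratic_binding(1e7, 0.12, 5, 0.15, 0.30), 0.30,
               tolerance = 1e-5)
  # a titration that never saturates is flagged
  d <- generate_titration("quadratic_binding",
                          list(K_d = 500, D_t = 5, r_f = 0.15, r_b = 0.3),
                          x = seq(0.1, 20, length.out = 8))
  f <- fit_quadratic_binding(d, D_t = 5)
  expect_true(length(f$warnings) > 0)
})

test_that("fold change is a background-subtracted ratio with propagation", {
  expect_equal(fold_change(100, 100), 1)
  expect_equal(fold_change(4000, 100), 40)
  # shared background subtracted before the ratio
  expect_equal(fold_change(3 - 0.1, 0.5 - 0.1), 2.9 / 0.4)
  expect_error(fold_change(10, 0), "> 0")
  f <- fold_change(200, 100, err_complex = 10, err_free = 5)
  expect_equal(attr(f, "se"), 2 * sqrt((10 / 200)^2 + (5 / 100)^2))
})

test_that("RNA quantification follows the band-fraction formula", {
  expect_equal(quantify_rna(1, 1, 100), 50)
  expect_equal(quantify_rna(0, 5, 100), 0)
  expect_equal(quantify_rna(1, 3, 400), 100)
  expect_error(quantify_rna(0, 0, 100), "> 0")
  # jointly scale-invariant in (R, A), linear in atp_total
  expect_equal(quantify_rna(2, 6, 400), quantify_rna(20, 60, 400))
  expect_equal(quantify_rna(1, 3, 800), 2 * quantify_rna(1, 3, 400))
})

test_that("abortive/runoff quantification follows the shared convention", {
  lanes <- data.frame(band_label = c("3mer", "free_ATP"),
                      intensity = c(50, 50))
  out <- abortive_runoff_ratio(lanes, atp_total = 100)
  expect_equal(out$abortive_3to7_uM, 50)
  expect_true(out$runoff_undefined)
  expect_true(is.na(out$ratio))

  lanes2 <- data.frame(
    band_label = c("2mer", paste0(3:7, "mer"), "runoff", "free_ATP"),
    intensity = c(10, rep(5, 5), 15, 50))
  out2 <- abortive_runoff_ratio(lanes2, atp_total = 100)
  denom <- 10 + 25 + 15 + 50
  expect_equal(out2$abortive_3to7_uM, 25 / denom * 100)
  expect_equal(out2$runoff_uM, 15 / denom * 100)
  expect_equal(out2$ratio, 25 / 15)
  # the 2-mer band is excluded from the abortive sum but in the total
  expect_equal(sum(out2$per_band_uM), (10 + 25 + 15) / denom * 100)
  # per-band convention reduces to quantify_rna per band
  out3 <- abortive_runoff_ratio(lanes, 100, convention = "per_band")
  expect_equal(out3$abortive_3to7_uM, quantify_rna(50, 50, 100))
})

test_that("bubble-collapse fits recover rates and flag flat traces", {
  d <- generate_titration("exponential_decay",
                          list(baseline = 0.2, amplitude = 0.8, k = 0.01),
                          x = seq(0, 600, by = 5))
  f <- fit_exponential_collapse(d)
  expect_false(f$no_collapse)
  expect_equal(f$params[["k_collapse"]], 0.01, tolerance = 1e-6)
  expect_equal(f$params[["amplitude"]], 0.8, tolerance = 1e-6)
  # flat noiseless trace: no-collapse verdict
  flat <- data.frame(x = seq(0, 100, by = 5), y = rep(1, 21))
  expect_true(fit_exponential_collapse(flat)$no_collapse)
  # ordering of rates is preserved on noiseless data
  slow <- fit_exponential_collapse(
    generate_titration("exponential_decay",
                       list(baseline = 0, amplitude = 1, k = 0.005),
                       x = seq(0, 600, by = 10)))
  fast <- fit_exponential_collapse(
    generate_titration("exponential_decay",
                       list(baseline = 0, amplitude = 1, k = 0.05),
                       x = seq(0, 600, by = 10)))
  expect_lt(slow$params[["k_collapse"]], fast$params[["k_collapse"]])
})

test_that("unit tags are enforced at fit time", {
  d <- generate_titration("hyperbola", list(F0 = 1, dF = 2, K_d = 65),
                          x = seq(0, 2000, length.out = 10),
                          x_unit = "uM")
  expect_error(fit_hyperbola(d, x_unit = "nM"), "unit mismatch")
  expect_silent(fit_hyperbola(d, x_unit = "uM"))
})
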