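test_that("parallel-plate field calibration reproduces the nanogap field", {
  expect_equal(parallel_plate_field(16.5, 55), 0.3)
  expect_equal(parallel_plate_field(3, 10), 0.3)
  expect_equal(parallel_plate_field(0, 55), 0)
  expect_error(parallel_plate_field(5, 0), "thickness")
  expect_warning(field_model(11, 55, f = 2.6), "sharp-tip")
})

test_that("SI and cgs evaluations of the forward model agree", {
  A <- synth_band(pmma_band(), pmma_grid())
  fm <- field_model(16.5, 55, f = 1.3)
  for (args in list(list(dmu = 0.065, chi = 0, zeta = 0),
                    list(dmu = 0.2, chi = 30, zeta = 60))) {
    si <- vse_forward(A, fm, args$dmu, args$chi, args$zeta,
                      a_term = 1e-4, b_term = 2e-4, units = "si")
    cgs <- vse_forward(A, fm, args$dmu, args$chi, args$zeta,
                       a_term = 1e-4, b_term = 2e-4, units = "cgs")
    expect_lt(max(abs(si$delta - cgs$delta)) / max(abs(si$delta)), 1e-9)
  }
})

test_that("forward model scales quadratically in field and dipole change", {
  A <- synth_band(pmma_band(), pmma_grid())
  base <- vse_forward(A, field_model(8.25, 55), 0.065)
  dbl <- vse_forward(A, field_model(16.5, 55), 0.065)
  expect_equal(dbl$delta, 4 * base$delta, tolerance = 1e-12)

  # ||dA||/F^2 constant across a field ladder
  norms <- vapply(c(0.05, 0.1, 0.2, 0.4), function(F) {
    d <- vse_forward(A, field_model(F * 55, 55), 0.065)
    sqrt(sum(d$delta^2)) / F^2
  }, numeric(1))
  expect_lt(diff(range(norms)) / norms[1], 1e-9)

  zero <- vse_forward(A, field_model(10, 55), 0)
  expect_true(all(zero$delta == 0))
  expect_error(vse_forward(A, field_model(10, 55), 0.1, chi = 120),
               "angles")
})

test_that("fit_vse recovers forward coefficients to numerical precision", {
  for (band in list(pmma_band(),
                    band_model(1665, 45, 0.8, "lorentzian"),
                    band_model(1700, 30, 1.2, "pseudo_voigt", eta = 0.3))) {
    A <- synth_band(band, seq(1550, 1850, by = 0.5))
    fm <- field_model(12, 55)
    dA <- vse_forward(A, fm, 0.065, a_term = 5e-5, b_term = -2e-4)
    fit <- fit_vse(dA, A)
    F2 <- fm$F_stat^2
    truth <- c(5e-5 * F2, -2e-4 * F2,
               starkir:::vse_c2(0.065, fm$F_stat))
    expect_equal(unname(fit$coeffs), truth, tolerance = 1e-8)
    expect_lt(fit$residual_rms, 1e-12 * max(abs(dA$delta)))
  }
})

test_that("an in-basis b1 signal projects onto c1 only", {
  A <- synth_band(pmma_band(), pmma_grid())
  db <- derivative_basis(A)
  dA <- difference_spectrum(db$grid, 3e-3 * db$b1, bias = 9)
  fit <- fit_vse(dA, A)
  expect_lt(abs(fit$coeffs[["c2"]]), 1e-8 * abs(fit$coeffs[["c1"]]))
  expect_lt(abs(fit$coeffs[["c0"]]), 1e-8 * abs(fit$coeffs[["c1"]]))
})

test_that("fit_vse rejects a rank-deficient basis", {
  nu <- seq(1000, 2000, by = 5)
  lin <- spectrum_new(nu, 2 * nu)  # A/nu constant: b1 = b2 = 0
  dA <- difference_spectrum(nu, rnorm(length(nu), 0, 1e-3), bias = 5)
  expect_error(fit_vse(dA, lin), "rank-deficient")
})

test_that("reported coefficient standard errors are calibrated", {
  A <- synth_band(pmma_band(), pmma_grid())
  fm <- field_model(12, 55)
  clean <- vse_forward(A, fm, 0.065, a_term = 5e-5, b_term = -2e-4)
  truth <- fit_vse(clean, A)$coeffs
  sigma <- 5e-4
  n_rep <- 10
  set.seed(31)
  unit_w <- rep(1, length(clean$grid))
  hits <- replicate(200, {
    singles <- lapply(seq_len(n_rep), function(i)
      difference_spectrum(clean$grid,
                          clean$delta + rnorm(length(clean$grid), 0, sigma),
                          bias = 12))
    d <- average_differences(singles)
    # sigma is known and homoscedastic: uniform weights
    fit <- fit_vse(d, A, weights = unit_w)
    se <- sqrt(pmax(diag(fit$covariance), 0))
    abs(fit$coeffs - truth) <= 3 * se
  })
  expect_gte(mean(hits), 0.99)
})

test_that("extract_delta_mu recovers the generator value and scales as sqrt(slope)", {
  p <- quiet_preset("pmma55")
  ser <- make_pmma_series(p, n_repeats = 1, seed = 1)
  out <- series_differences(ser)
  fits <- lapply(out$differences, fit_vse, A_ref = out$reference)
  fields <- lapply(out$differences, function(d) field_model(d$bias, 55, 1))
  res <- extract_delta_mu(fits, fields)
  expect_equal(res$delta_mu, 0.065, tolerance = 1e-3)
  expect_gt(res$linearity_r2, 0.99)
  expect_false(res$degenerate)

  # quadrupling the slope doubles the recovered dipole change
  fits4 <- lapply(fits, function(f) {
    f$coeffs <- 4 * f$coeffs
    f
  })
  res4 <- extract_delta_mu(fits4, fields)
  expect_equal(res4$delta_mu, 2 * res$delta_mu, tolerance = 1e-9)

  # nonpositive slope degrades to zero with a flag, not an error
  fits0 <- lapply(fits, function(f) { f$coeffs[] <- c(0, 0, -1e-6); f })
  res0 <- extract_delta_mu(fits0, fields)
  expect_equal(res0$delta_mu, 0)
  expect_true(res0$degenerate)

  expect_error(extract_delta_mu(fits[1], fields[1]), "two distinct")
})

test_that("delta_mu and coefficient ratios are invariant under common rescaling", {
  p <- quiet_preset("pmma55")
  out <- series_differences(make_pmma_series(p, 1, seed = 1))
  k <- 37.5
  ref2 <- spectrum_new(out$reference$wavenumber,
                       k * out$reference$absorbance)
  fits1 <- lapply(out$differences, fit_vse, A_ref = out$reference)
  fits2 <- lapply(out$differences, function(d)
    fit_vse(difference_spectrum(d$grid, k * d$delta, d$bias), ref2))
  fields <- lapply(out$differences, function(d) field_model(d$bias, 55, 1))
  r1 <- extract_delta_mu(fits1, fields)
  r2 <- extract_delta_mu(fits2, fields)
  expect_equal(r2$delta_mu, r1$delta_mu, tolerance = 1e-9)
  expect_equal(fits2[[1]]$coeffs, fits1[[1]]$coeffs, tolerance = 1e-9)
})

test_that("noisy replicates recover the dipole change within the stated band", {
  p <- sample_preset("pmma55")   # default noise on
  set.seed(101)
  dmu <- replicate(30, {
    seed <- sample.int(1e6, 1)
    out <- series_differences(make_pmma_series(p, 10, seed = seed))
    ref <- smooth_spectrum(out$reference, "auto")
    fits <- lapply(out$differences, fit_vse, A_ref = ref)
    fields <- lapply(out$differences, function(d) field_model(d$bias, 55, 1))
    extract_delta_mu(fits, fields)$delta_mu
  })
  expect_gte(mean(abs(dmu - 0.065) <= 0.006), 0.9)
})

test_that("local field factor is recovered from a calibration slope", {
  exp_slope <- starkir:::slope_expected(0.065)
  expect_equal(estimate_local_field_factor(exp_slope, 0.065), 1)
  expect_equal(estimate_local_field_factor(4 * exp_slope, 0.065), 2)
  expect_error(estimate_local_field_factor(1, 0), "reference")

  # sharp-tip synthetic series generated with f = 1.5
  p <- quiet_preset("pmma55")
  p$effects$vse$f <- 1.5
  out <- series_differences(make_pmma_series(p, 1, seed = 1))
  fits <- lapply(out$differences, fit_vse, A_ref = out$reference)
  fields <- lapply(out$differences, function(d)
    field_model(d$bias, 55, 1))     # analyse assuming nominal field
  res <- extract_delta_mu(fits, fields)
  f_hat <- estimate_local_field_factor(res$slope, 0.065)
  expect_equal(f_hat, 1.5, tolerance = 0.01)
})

test_that("linearity r2 degrades monotonically with noise", {
  # fixed standard-normal perturbation scaled by sigma: the c2 errors
  # then grow linearly in sigma and r2 must fall monotonically
  p <- quiet_preset("pmma55")
  out <- series_differences(make_pmma_series(p, 1, seed = 17))
  fields <- lapply(out$differences, function(d) field_model(d$bias, 55, 1))
  set.seed(23)
  eps <- lapply(out$differences, function(d) rnorm(length(d$delta)))
  unit_w <- rep(1, length(out$differences[[1]]$delta))
  r2_at <- function(sigma) {
    fits <- lapply(seq_along(out$differences), function(i) {
      d <- out$differences[[i]]
      fit_vse(difference_spectrum(d$grid, d$delta + sigma * eps[[i]],
                                  d$bias), out$reference,
              weights = unit_w)
    })
    extract_delta_mu(fits, fields)$linearity_r2
  }
  r2 <- vapply(c(0, 0.002, 0.01, 0.05), r2_at, numeric(1))
  expect_gt(r2[1], 0.999999)
  expect_true(all(diff(r2) <= 1e-9))
})
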