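test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum_new(1500:1600, rnorm(101)), "stark_spectrum")
  expect_error(spectrum_new(1500:1506, rep(0, 7)), "at least 8")
  expect_error(spectrum_new(1600:1500, rep(0, 101)), "increasing")
  expect_error(spectrum_new(c(-5, 1:10), rep(0, 11)), "positive")
  expect_error(spectrum_new(1500:1600, c(NA, rnorm(100))), "finite")
  expect_error(spectrum_new(1500:1600, rnorm(100)), "equal length")
})

test_that("synth_band peaks at the amplitude and matches the closed-form area", {
  grid <- seq(1500, 1800, by = 1)
  s <- synth_band(band_model(1665, 40, 1), grid)
  expect_equal(s$absorbance[grid == 1665], 1)
  expect_equal(which.max(s$absorbance), which(grid == 1665))

  s0 <- synth_band(band_model(1665, 40, 0), grid)
  expect_true(all(s0$absorbance == 0))

  # area check on a grid 5x finer than the fwhm
  b <- band_model(1665, 40, 0.7)
  fine <- seq(1200, 2200, by = 40 / 200)
  area <- integrate_window(synth_band(b, fine))
  expect_equal(area, gaussian_area(b), tolerance = 1e-3)

  expect_error(synth_band(band_model(1665, 40), numeric(0)), "empty")
  expect_error(synth_band(band_model(1665, 40), c(-10, 1:20)), "positive")
})

test_that("band shapes are normalized to unit peak at the center", {
  grid <- seq(1600, 1860, by = 0.5)
  for (shape in c("gaussian", "lorentzian", "pseudo_voigt")) {
    s <- synth_band(band_model(1731, 24, 1, shape), grid)
    expect_equal(max(s$absorbance), 1, info = shape)
    # half maximum at center +/- fwhm/2
    at_half <- s$absorbance[abs(grid - (1731 + 12)) < 1e-9]
    expect_equal(at_half, 0.5, tolerance = 1e-9, info = shape)
  }
})

test_that("smoothing spline: identity at 0, near noise floor with GCV", {
  s <- synth_band(pmma_band(), pmma_grid())
  expect_identical(smooth_spectrum(s, 0), s)
  expect_error(smooth_spectrum(s, -1), "nonnegative")

  set.seed(42)
  noisy <- spectrum_new(s$wavenumber, s$absorbance + rnorm(321, 0, 0.01))
  sm <- smooth_spectrum(noisy, "auto")
  # residual vs the noisy input should be at most the injected noise sd
  expect_lte(sd(noisy$absorbance - sm$absorbance), 0.0105)
  # recovered curve close to truth
  expect_lt(sd(sm$absorbance - s$absorbance), 0.01)
  # band area preserved to < 1%
  expect_equal(integrate_window(sm), integrate_window(noisy),
               tolerance = 0.01)
})

test_that("increasing smoothing penalty never increases roughness", {
  set.seed(7)
  s <- spectrum_new(pmma_grid(),
                    synth_band(pmma_band(), pmma_grid())$absorbance +
                      rnorm(321, 0, 0.02))
  rough <- function(y) sum(diff(diff(y))^2)
  lambdas <- 10^seq(-8, -2, by = 1)
  r <- vapply(lambdas, function(l)
    rough(smooth_spectrum(s, l)$absorbance), numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("derivative basis matches the refined finite-difference oracle", {
  s <- synth_band(pmma_band(), pmma_grid())
  db <- derivative_basis(s)

  fine <- pmma_grid(step = 0.05)
  red <- synth_band(pmma_band(), fine)$absorbance / fine
  idx <- match(s$wavenumber, fine)
  b1_o <- fine[idx] * starkir:::grid_derivative(fine, red, 1L)[idx]
  b2_o <- fine[idx] * starkir:::grid_derivative(fine, red, 2L)[idx]

  scale <- max(abs(b2_o))
  expect_lt(max(abs(db$b1 - b1_o)) / scale, 1e-4)
  expect_lt(max(abs(db$b2 - b2_o)) / scale, 1e-4)
  # negative curvature at the band maximum
  expect_lt(db$b2[s$wavenumber == 1731], 0)
})

test_that("derivative basis of A = c*nu has vanishing b1 and b2", {
  nu <- seq(1000, 2000, by = 5)
  db <- derivative_basis(spectrum_new(nu, 3.7 * nu))
  expect_lt(max(abs(db$b1)), 1e-8)
  expect_lt(max(abs(db$b2)), 1e-8)
})

test_that("derivative basis is linear and refuses short grids", {
  nu <- seq(1600, 1800, by = 2)
  a <- synth_band(band_model(1680, 30), nu)
  b <- synth_band(band_model(1720, 50, 0.5, "lorentzian"), nu)
  mix <- spectrum_new(nu, 2 * a$absorbance - 0.3 * b$absorbance)
  dm <- derivative_basis(mix)
  da <- derivative_basis(a); db <- derivative_basis(b)
  for (k in c("b0", "b1", "b2"))
    expect_equal(dm[[k]], 2 * da[[k]] - 0.3 * db[[k]], tolerance = 1e-10)
  expect_error(derivative_basis(
    structure(list(wavenumber = 1:4, absorbance = rnorm(4)),
              class = "stark_spectrum")), "too short")
})

test_that("derivative estimates converge at better than 2nd order", {
  err_at <- function(step) {
    nu <- seq(1650, 1810, by = step)
    red <- synth_band(pmma_band(), nu)$absorbance / nu
    est <- starkir:::grid_derivative(nu, red, 2L)
    truth <- {
      # near-exact second derivative of A(nu)/nu via tiny-step differences
      h <- 1e-3
      g <- function(x) synth_band(pmma_band(), x)$absorbance / x
      (g(nu + h) - 2 * g(nu) + g(nu - h)) / h^2
    }
    max(abs(est - truth))
  }
  e1 <- err_at(1); e2 <- err_at(0.5)
  expect_gte(e1 / e2, 2)
})

test_that("band centroid: symmetry, two-band midpoint, quadrature oracle", {
  grid <- seq(1500, 1830, by = 0.5)
  s <- synth_band(band_model(1665, 40), grid)
  expect_equal(band_centroid(s, c(1600, 1730)), 1665, tolerance = 1e-6)

  two <- spectrum_new(grid,
                      synth_band(band_model(1600, 20), grid)$absorbance +
                        synth_band(band_model(1700, 20), grid)$absorbance)
  expect_equal(band_centroid(two, c(1540, 1760)), 1650, tolerance = 1e-6)

  # asymmetrically truncated Lorentzian vs direct quadrature ratio
  lor <- synth_band(band_model(1731, 24, 1, "lorentzian"), grid)
  win <- c(1700, 1820)
  idx <- grid >= win[1] & grid <= win[2]
  x <- grid[idx]; y <- lor$absorbance[idx]
  trap <- function(v) sum(diff(x) * (v[-1] + v[-length(v)]) / 2)
  expect_equal(band_centroid(lor, win), trap(x * y) / trap(y),
               tolerance = 1e-12)

  zero <- spectrum_new(grid, rep(0, length(grid)))
  expect_error(band_centroid(zero, c(1600, 1700)), "weight")
})

test_that("integrate_window: zero, rectangle, Gaussian closed form", {
  grid <- seq(1000, 2000, by = 1)
  zero <- spectrum_new(grid, rep(0, length(grid)))
  expect_equal(integrate_window(zero, c(1200, 1800)), 0)

  # unit rectangle of width 10: flanks contribute half a step each
  rect <- spectrum_new(grid, as.numeric(grid >= 1495.5 & grid <= 1505.5))
  expect_equal(integrate_window(rect, c(1400, 1600)), 10)

  b <- band_model(1500, 60, 2)
  fine <- seq(1000, 2000, by = 0.25)
  expect_equal(integrate_window(synth_band(b, fine)),
               gaussian_area(b), tolerance = 1e-3)
  expect_error(integrate_window(zero, c(2500, 2600)), "overlap")
})

test_that("CSV and JCAMP round trips preserve a spectrum", {
  s <- synth_band(pmma_band(), pmma_grid(), bias = 9, label = "pmma")
  csv <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, csv)
  expect_equal(readLines(csv, n = 1), "wavenumber_cm-1,absorbance")
  r <- read_spectrum_csv(csv, bias = 9)
  expect_equal(r$wavenumber, s$wavenumber)
  expect_equal(r$absorbance, s$absorbance, tolerance = 1e-6)
  expect_equal(r$bias, 9)

  jdx <- tempfile(fileext = ".jdx")
  write_spectrum_jcamp(s, jdx)
  j <- read_spectrum_jcamp(jdx)
  expect_equal(j$wavenumber, s$wavenumber, tolerance = 1e-8)
  expect_equal(j$absorbance, s$absorbance, tolerance = 1e-6)
})
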