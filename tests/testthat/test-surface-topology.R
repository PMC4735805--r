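test_that("amplification is exact for flat maps and bounded below by 1", {
  flat <- height_map(matrix(5, 30, 30), 20)   # constant offset, still flat
  expect_identical(amplification_factor(flat), 1)
  set.seed(3)
  rough <- height_map(matrix(rnorm(900, sd = 30), 30, 30), 20)
  expect_gte(amplification_factor(rough), 1)
  expect_error(amplification_factor(height_map(matrix(0, 1, 5), 20)),
               "2 x 2")
})

test_that("sinusoid amplification matches the arc-length quadrature", {
  lam <- 500; A <- lam / (2 * pi)
  oracle <- oracle_sinusoid_amplification(A, lam)
  expect_equal(oracle, 1.2160, tolerance = 1e-4)
  s <- gen_height_map("sinusoid", amplitude = A, period = lam,
                      extent = 4000, spacing = 5)
  expect_lt(abs(amplification_factor(s) - oracle) / oracle, 0.01)
})

test_that("amplification converges under mesh refinement", {
  lam <- 500; A <- lam / (2 * pi)
  oracle <- oracle_sinusoid_amplification(A, lam)
  errs <- vapply(c(20, 10, 5), function(sp) {
    s <- gen_height_map("sinusoid", amplitude = A, period = lam,
                        extent = 4000, spacing = sp)
    abs(amplification_factor(s) - oracle)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("amplification is invariant to height offset and diagonal choice", {
  s <- gen_height_map("bump_lattice", amplitude = 120, period = 600,
                      extent = 2400, spacing = 20)
  a1 <- amplification_factor(s)
  s2 <- height_map(s$z + 500, s$spacing_nm)
  expect_equal(amplification_factor(s2), a1)
  a_anti <- amplification_factor(s, diagonal = "anti")
  expect_lt(abs(a1 - a_anti) / a1, 0.005)
})

test_that("peak detection finds constructed extrema only", {
  one <- gen_height_map("bump_lattice", amplitude = 100, period = 1200,
                        extent = 1200, spacing = 20)
  pk <- detect_peaks(one, min_distance_nm = 100, min_prominence_nm = 10)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$z, max(one$z))
  apex <- which(one$z == max(one$z), arr.ind = TRUE)
  expect_equal(pk$x, unname((apex[1, 2] - 1) * 20))
  expect_equal(pk$y, unname((apex[1, 1] - 1) * 20))

  flat <- gen_height_map("flat", extent = 800, spacing = 20)
  expect_equal(nrow(detect_peaks(flat, 100, 10)), 0)

  bl <- gen_height_map("bump_lattice", amplitude = 100, period = 400,
                       extent = 2400, spacing = 20)
  pk2 <- detect_peaks(bl, min_distance_nm = 200, min_prominence_nm = 20)
  expect_equal(nrow(pk2), 36)   # 6 x 6 lattice sites
})

test_that("peak spacing matches hand-computed and brute-force values", {
  two <- tibble::tibble(x = c(0, 300), y = c(0, 400), z = c(0, 0))
  sp <- peak_spacing_stats(two, "3d")
  expect_equal(sp$distance_nm, c(500, 500))    # 3-4-5 triangle
  expect_equal(peak_spacing_stats(two, "projected_2d")$distance_nm,
               c(500, 500))

  zonly <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 100))
  expect_equal(peak_spacing_stats(zonly, "3d")$distance_nm, c(100, 100))
  expect_equal(peak_spacing_stats(zonly, "projected_2d")$distance_nm,
               c(0, 0))

  set.seed(8)
  rnd <- tibble::tibble(x = runif(40, 0, 3000), y = runif(40, 0, 3000),
                        z = runif(40, 0, 300))
  got <- peak_spacing_stats(rnd, "3d")
  d2 <- as.matrix(dist(cbind(rnd$x, rnd$y, rnd$z)))
  diag(d2) <- Inf
  expect_equal(got$distance_nm, unname(apply(d2, 1, min)))
  expect_equal(unname(got$neighbour), unname(apply(d2, 1, which.min)))
  expect_error(peak_spacing_stats(two[1, ], "3d"), "at least 2")
})

test_that("the power spectrum recovers the lattice period", {
  grid <- expand.grid(x = seq(250, 3750, by = 500),
                      y = seq(250, 3750, by = 500))
  pk <- tibble::tibble(x = grid$x, y = grid$y, z = 0)
  spec <- periodicity_spectrum(pk, render_sigma_nm = 50, pixel_nm = 20,
                               extent_nm = 4000)
  expect_false(spec$flagged)
  bin <- 1 / (nrow(spec$power) * 20)
  expect_lte(abs(1 / spec$dominant_period_nm - 1 / 500), bin)

  # doubling the period halves the dominant frequency
  grid2 <- expand.grid(x = seq(500, 7500, by = 1000),
                       y = seq(500, 7500, by = 1000))
  spec2 <- periodicity_spectrum(tibble::tibble(x = grid2$x, y = grid2$y,
                                               z = 0),
                                render_sigma_nm = 50, pixel_nm = 20,
                                extent_nm = 8000)
  expect_equal(1 / spec2$dominant_period_nm, 0.5 / spec$dominant_period_nm,
               tolerance = 0.12)

  single <- periodicity_spectrum(tibble::tibble(x = 500, y = 500, z = 0),
                                 render_sigma_nm = 50, pixel_nm = 20,
                                 extent_nm = 1000)
  expect_true(single$flagged)
  expect_true(is.na(single$dominant_period_nm))
})

test_that("masked samples are excluded from the surface integral", {
  z <- matrix(0, 10, 10)
  z[1, 1] <- 1e6                      # huge spike, masked out
  mask <- matrix(TRUE, 10, 10); mask[1, 1] <- FALSE
  hm <- height_map(z, 20, mask)
  expect_equal(amplification_factor(hm), 1)
})
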