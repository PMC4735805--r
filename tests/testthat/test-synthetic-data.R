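test_that("generators are deterministic under a seed", {
  f1 <- gen_ellipse_field(4000, 3, 10, attraction_f = 1, seed = 7)
  f2 <- gen_ellipse_field(4000, 3, 10, attraction_f = 1, seed = 7)
  expect_identical(f1$ellipses, f2$ellipses)

  tr <- affine2d(matrix(c(1.2, 0.1, -0.1, 0.8), 2, 2), c(5, -3))
  expect_identical(gen_fiducial_pairs(tr, 10, 3, seed = 2),
                   gen_fiducial_pairs(tr, 10, 3, seed = 2))

  s1 <- gen_particle_stack(n = 3, seed = 5)
  s2 <- gen_particle_stack(n = 3, seed = 5)
  expect_identical(s1$stack$particles, s2$stack$particles)
  expect_identical(s1$poses, s2$poses)

  i1 <- render_localization_image(f1, seed = 9)
  i2 <- render_localization_image(f1, seed = 9)
  expect_identical(i1$data, i2$data)
})

test_that("a field with no reference ellipses has no contacts", {
  f <- gen_ellipse_field(6000, 0, 5, attraction_f = 4, seed = 3)
  expect_equal(sum(f$ellipses$channel == "reference"), 0)
  expect_equal(sum(f$ellipses$channel == "query"), 5)
  q <- f$ellipses
  expect_true(all(q$x >= 0 & q$x <= 6000))
  expect_true(all(q$y >= 0 & q$y <= 1000))
})

test_that("attraction raises the mean contact fraction (f = 8 vs f = 1)", {
  contact_frac <- function(field) {
    e <- field$ellipses
    r <- as.matrix(e[e$channel == "reference", c("x", "y", "a", "b", "theta")])
    q <- as.matrix(e[e$channel == "query", c("x", "y", "a", "b", "theta")])
    mean(vapply(seq_len(nrow(q)), function(i) {
      any(vapply(seq_len(nrow(r)), function(j) {
        ellipses_overlap(q[i, ], r[j, ])
      }, logical(1)))
    }, logical(1)))
  }
  n_fields <- 60
  c1 <- vapply(seq_len(n_fields), function(s) {
    contact_frac(gen_ellipse_field(6000, 5, 20, attraction_f = 1,
                                   seed = 100 + s))
  }, numeric(1))
  c8 <- vapply(seq_len(n_fields), function(s) {
    contact_frac(gen_ellipse_field(6000, 5, 20, attraction_f = 8,
                                   seed = 100 + s))
  }, numeric(1))
  expect_gt(mean(c8), mean(c1))
  expect_gt(mean(c8) - mean(c1), 0.1)
})

test_that("rendered image dimensions follow the pixel size", {
  f <- gen_ellipse_field(10000, 0, 1, seed = 1)
  img <- render_localization_image(f, pixel_nm = 20, seed = 1)
  expect_equal(dim(img$data)[2], 500)   # 10,000 nm / 20 nm per px
  expect_equal(dim(img$data)[1], 50)    # 1,000 nm band / 20 nm per px
})

test_that("jitter-free rendering covers exactly the rasterized ellipse", {
  f <- gen_ellipse_field(2000, 0, 1, seed = 12, margin_nm = 350,
                         size_sampler = function(n) {
                           tibble::tibble(a = rep(250, n), b = rep(150, n))
                         })
  img <- render_localization_image(f, pixel_nm = 20, density = 1,
                                   precision_nm = 0, seed = 5)
  e <- as.numeric(f$ellipses[1, c("x", "y", "a", "b", "theta")])
  hot <- which(img$data[, , 2] > 0, arr.ind = TRUE)
  # every nonzero pixel intersects the ellipse (some corner inside)
  corner_in <- function(r, c) {
    xs <- c(c - 1, c, c - 1, c) * 20
    ys <- c(r - 1, r - 1, r, r) * 20
    any(point_in_ellipse(xs, ys, e)) ||
      point_in_ellipse((c - 0.5) * 20, (r - 0.5) * 20, e)
  }
  expect_true(all(vapply(seq_len(nrow(hot)), function(k) {
    corner_in(hot[k, 1], hot[k, 2])
  }, logical(1))))
  # every pixel whose center is inside is hit at this density
  ny <- dim(img$data)[1]; nxp <- dim(img$data)[2]
  centers <- expand.grid(r = seq_len(ny), c = seq_len(nxp))
  inside <- point_in_ellipse((centers$c - 0.5) * 20, (centers$r - 0.5) * 20, e)
  hit <- img$data[, , 2][cbind(centers$r, centers$c)] > 0
  expect_true(all(hit[inside]))
})

# independent re-derivation of the sampled localization count: replays the
# generator's RNG consumption per ellipse
with_seed_count <- function(field, density, precision_nm, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  total <- 0
  for (ch in 1:2) {
    lab <- c("reference", "query")[ch]
    ell <- field$ellipses[field$ellipses$channel == lab, , drop = FALSE]
    for (i in seq_len(nrow(ell))) {
      n_loc <- stats::rpois(1, density * pi * ell$a[i] * ell$b[i])
      total <- total + n_loc
      if (n_loc > 0) {
        runif(n_loc); runif(n_loc)
        if (precision_nm > 0) { rnorm(n_loc); rnorm(n_loc) }
      }
    }
  }
  total
}

test_that("rendering conserves localization counts for interior fields", {
  f <- gen_ellipse_field(3000, 2, 4, seed = 8, margin_nm = 400)
  img <- render_localization_image(f, density = 0.02, precision_nm = 10,
                                   seed = 3)
  # re-sample the same localizations with the same seed to count them
  n_expected <- with_seed_count(f, 0.02, 10, 3)
  expect_equal(sum(img$data), n_expected)
})

test_that("fiducial pairs follow the generating transform", {
  idt <- affine2d()
  p0 <- gen_fiducial_pairs(idt, 8, noise_nm = 0, seed = 4)
  expect_equal(p0$src_x, p0$dst_x)
  expect_equal(p0$src_y, p0$dst_y)

  tr <- affine2d(diag(2), c(10, 5))
  p1 <- gen_fiducial_pairs(tr, 12, noise_nm = 0, seed = 4)
  expect_equal(p1$dst_x - p1$src_x, rep(10, 12))
  expect_equal(p1$dst_y - p1$src_y, rep(5, 12))

  expect_error(gen_fiducial_pairs(idt, 0, seed = 1), "at least one")
})

test_that("shear + scale transform is recovered from noisy fiducials", {
  tr <- affine2d(matrix(c(2.0, 0.15, 0.3, 1.7), 2, 2), c(120, -60))
  pairs <- gen_fiducial_pairs(tr, 20, noise_nm = 5, seed = 31)
  est <- estimate_affine(pairs)
  scale <- max(abs(tr$linear))
  expect_lt(max(abs(est$linear - tr$linear)), 0.02 * scale)
})

test_that("height map kinds match their analytic definitions", {
  flat <- gen_height_map("flat", extent = 1000, spacing = 50)
  expect_true(all(flat$z == 0))
  expect_equal(amplification_factor(flat), 1)

  s <- gen_height_map("sinusoid", amplitude = 80, period = 400,
                      extent = 1200, spacing = 10)
  xs <- seq(0, 1200, by = 10)
  expect_equal(s$z[1, ], 80 * sin(2 * pi * xs / 400))
  expect_equal(s$z[5, ], s$z[1, ])   # constant along y

  expect_error(gen_height_map("sinusoid", period = 30, spacing = 20),
               "Nyquist|exceed")
})

test_that("bump lattice spacing equals the construction period", {
  bl <- gen_height_map("bump_lattice", amplitude = 100, period = 500,
                       extent = 3000, spacing = 20)
  pk <- detect_peaks(bl, min_distance_nm = 250, min_prominence_nm = 20)
  expect_equal(nrow(pk), 36)           # 6 x 6 bumps in 3000 nm
  sp <- peak_spacing_stats(pk, "3d")
  tab <- table(round(sp$distance_nm / 20) * 20)
  modal <- as.numeric(names(tab)[which.max(tab)])
  expect_lte(abs(modal - 500), 20)
})

test_that("particle stacks honour poses, dimensions and parameter bounds", {
  still <- gen_particle_stack(n = 10, max_shift_px = 0, max_rot_deg = 0,
                              noise_level = 0, seed = 2)
  for (i in 1:10) {
    expect_equal(still$stack$particles[, , , i], still$template,
                 tolerance = 1e-12)
  }
  s50 <- gen_particle_stack(n = 50, seed = 3)
  expect_equal(dim(s50$stack$particles), c(100, 100, 2, 50))
  expect_equal(s50$stack$pixel_nm, 20)  # 100 px x 20 nm = 2 um box
  expect_equal(nrow(s50$poses), 50)
  expect_error(gen_particle_stack(n = 2, max_shift_px = 60, seed = 1),
               "half the box")
})
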