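# Synthetic-data generators. Every downstream stage of the package can be
# exercised on data produced here, with the generating ground truth carried
# alongside, so recovery can be tested without any external images.
#
# Coordinate conventions: nm units, origin at the top-left of the field,
# x rightward, y downward; pixel indices are 1-based in R but pixel i covers
# the half-open square [(i-1)*p, i*p) so pixel centers sit at (i - 0.5) * p.

#' Default ellipse size sampler
#'
#' Log-normal semi-major axes (median 120 nm, sdlog 0.35) with axis ratio
#' uniform in `[0.5, 1]`: cluster scales of tens to a few hundred nm,
#' matching the scale of channel/adhesion clusters in reconstructed
#' localization images. Plug in any `function(n) -> data.frame(a, b)` to
#' use a measured size list instead.
#'
#' @param median_a_nm Median semi-major axis (nm).
#' @param sdlog Log-scale standard deviation.
#' @return A sampler `function(n)`.
#' @export
lognormal_size_sampler <- function(median_a_nm = 120, sdlog = 0.35) {
  function(n) {
    a <- rlnorm(n, meanlog = log(median_a_nm), sdlog = sdlog)
    tibble(a = a, b = a * runif(n, 0.5, 1))
  }
}

#' Generate a two-channel ellipse cluster field with known ground truth
#'
#' Reference ellipses are placed uniformly without mutual overlap in a
#' membrane box of `box_length x 2 * halfwidth_nm`; query ellipses are then
#' placed under the attraction model with factor `attraction_f` (`1` =
#' uniform). The same placement code as [run_placement_experiment()] is
#' used, so the generating attraction is known exactly.
#'
#' @param box_length Box length (nm).
#' @param n_ref,n_query Number of reference and query ellipses.
#' @param size_sampler Size source: `function(n) -> data.frame(a, b)` or a
#'   data frame of sizes resampled with replacement. Default
#'   [lognormal_size_sampler()].
#' @param attraction_f Attraction factor `f >= 1`.
#' @param seed Integer seed; same seed, same field.
#' @param halfwidth_nm Box half-width (nm; default 500).
#' @param query_min_edge_nm Optional minimum edge separation among query
#'   ellipses (validation aid; default 0 = model behaviour).
#' @param margin_nm Optional inset keeping ellipse centers at least this
#'   far from every box edge (validation aid so rendered clusters lie
#'   wholly inside the field of view; default 0 = model behaviour).
#' @return An `ellipse_field`: list with `ellipses` (tibble: `id`,
#'   `channel` in `reference`/`query`, `x`, `y`, `a`, `b`, `theta`),
#'   `membrane_line`, `box_length`, `halfwidth_nm`, `attraction_f`, `seed`.
#' @export
gen_ellipse_field <- function(box_length, n_ref, n_query,
                              size_sampler = lognormal_size_sampler(),
                              attraction_f = 1, seed = NULL,
                              halfwidth_nm = 500, query_min_edge_nm = 0,
                              margin_nm = 0) {
  stopifnot(box_length > 0, n_ref >= 0, n_query >= 0, attraction_f >= 1,
            margin_nm >= 0, margin_nm < halfwidth_nm,
            2 * margin_nm < box_length)
  with_seed(seed, {
    inner_len <- box_length - 2 * margin_nm
    inner_half <- halfwidth_nm - margin_nm
    ref <- place_reference(inner_len, sample_sizes(size_sampler, n_ref),
                           inner_half)
    qry <- place_query(inner_len, ref, sample_sizes(size_sampler, n_query),
                       attraction_f, inner_half,
                       min_edge_nm = query_min_edge_nm)
    ref$x <- ref$x + margin_nm; ref$y <- ref$y + margin_nm
    qry$x <- qry$x + margin_nm; qry$y <- qry$y + margin_nm
    ell <- dplyr::bind_rows(
      mutate(ref, channel = "reference"),
      mutate(qry, channel = "query"))
    ell <- ell[, c("id", "channel", "x", "y", "a", "b", "theta")]
    structure(list(
      ellipses = ell,
      membrane_line = tibble(x = c(0, box_length),
                             y = c(halfwidth_nm, halfwidth_nm)),
      box_length = box_length, halfwidth_nm = halfwidth_nm,
      attraction_f = attraction_f, seed = seed),
      class = "ellipse_field")
  })
}

#' @export
print.ellipse_field <- function(x, ...) {
  cat(sprintf(
    "ellipse field: %d reference + %d query ellipses, box %g x %g nm, f = %g\n",
    sum(x$ellipses$channel == "reference"),
    sum(x$ellipses$channel == "query"),
    x$box_length, 2 * x$halfwidth_nm, x$attraction_f))
  invisible(x)
}

#' Two-channel reconstructed image container
#'
#' @param data Numeric array `[y, x, channel]` or `[y, x, channel, z]`.
#' @param pixel_nm Lateral pixel size (nm).
#' @param channels Channel names.
#' @param z_step_nm Axial step (nm) for z-stacks.
#' @return A `recon_image`.
#' @export
recon_image <- function(data, pixel_nm = 20,
                        channels = c("reference", "query"),
                        z_step_nm = NULL) {
  stopifnot(pixel_nm > 0, length(dim(data)) %in% c(3, 4),
            dim(data)[3] == length(channels))
  structure(list(data = data, pixel_nm = pixel_nm, channels = channels,
                 z_step_nm = z_step_nm),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("reconstructed image: %d x %d px at %g nm/px, %d channel(s)%s\n",
              d[2], d[1], x$pixel_nm, d[3],
              if (length(d) == 4) sprintf(", %d z-planes", d[4]) else ""))
  invisible(x)
}

#' Render a localization-style image of an ellipse field
#'
#' For each ellipse, a Poisson number of localizations (mean
#' `density * area`) is sampled uniformly inside the ellipse, jittered with
#' isotropic Gaussian noise of scale `precision_nm` (the localization
#' precision) and binned into pixels. Localizations falling outside the
#' field of view are not recorded (camera convention); for a field whose
#' ellipses lie wholly inside the box, the sum of all pixel counts equals
#' the number of sampled localizations.
#'
#' @param field An `ellipse_field`.
#' @param pixel_nm Pixel size (nm/px; default 20).
#' @param density Localizations per nm^2 of ellipse area.
#' @param precision_nm Gaussian jitter scale (nm); 0 disables jitter.
#' @param seed Integer seed.
#' @return A [recon_image()] with channels `reference` and `query`.
#' @export
render_localization_image <- function(field, pixel_nm = 20, density = 0.01,
                                      precision_nm = 20, seed = NULL) {
  stopifnot(inherits(field, "ellipse_field"), pixel_nm > 0, density > 0)
  nx <- ceiling(field$box_length / pixel_nm)
  ny <- ceiling(2 * field$halfwidth_nm / pixel_nm)
  img <- array(0, c(ny, nx, 2))
  with_seed(seed, {
    for (ch in 1:2) {
      lab <- c("reference", "query")[ch]
      ell <- field$ellipses[field$ellipses$channel == lab, , drop = FALSE]
      for (i in seq_len(nrow(ell))) {
        e <- as.numeric(ell[i, c("x", "y", "a", "b", "theta")])
        n_loc <- stats::rpois(1, density * pi * e[3] * e[4])
        if (n_loc == 0) next
        # uniform in the unit disc, scaled and rotated into the ellipse
        r <- sqrt(runif(n_loc)); t <- runif(n_loc, 0, 2 * pi)
        u <- r * cos(t) * e[3]; v <- r * sin(t) * e[4]
        th <- deg2rad(e[5])
        px <- e[1] + u * cos(th) - v * sin(th)
        py <- e[2] + u * sin(th) + v * cos(th)
        if (precision_nm > 0) {
          px <- px + rnorm(n_loc, 0, precision_nm)
          py <- py + rnorm(n_loc, 0, precision_nm)
        }
        keep <- px >= 0 & px < field$box_length &
          py >= 0 & py < 2 * field$halfwidth_nm
        px <- px[keep]; py <- py[keep]
        if (!length(px)) next
        ix <- floor(px / pixel_nm) + 1
        iy <- floor(py / pixel_nm) + 1
        acc <- table(iy + (ix - 1) * ny)
        idx <- as.integer(names(acc))
        plane <- img[, , ch]
        plane[idx] <- plane[idx] + as.integer(acc)
        img[, , ch] <- plane
      }
    }
  })
  recon_image(img, pixel_nm = pixel_nm)
}

#' Generate matched fiducial coordinate pairs under a known affine map
#'
#' Source points are uniform in a square field of view; targets are the
#' affine image of the sources plus isotropic Gaussian noise.
#'
#' @param transform An [affine2d()] transform.
#' @param n Number of pairs (>= 3 recommended for downstream estimation).
#' @param noise_nm Gaussian noise scale on the targets (nm).
#' @param fov_nm Field-of-view side length (nm).
#' @param seed Integer seed.
#' @return Tibble with `src_x`, `src_y`, `dst_x`, `dst_y` (nm).
#' @export
gen_fiducial_pairs <- function(transform, n, noise_nm = 0, fov_nm = 10000,
                               seed = NULL) {
  if (n < 1) abort("need at least one fiducial pair")
  with_seed(seed, {
    src <- cbind(runif(n, 0, fov_nm), runif(n, 0, fov_nm))
    dst <- transform_points(src, transform)
    if (noise_nm > 0) dst <- dst + matrix(rnorm(2 * n, 0, noise_nm), n, 2)
    tibble(src_x = src[, 1], src_y = src[, 2],
           dst_x = dst[, 1], dst_y = dst[, 2])
  })
}

#' Generate a synthetic surface height map
#'
#' Three surface kinds with analytically known geometry: `flat` (z = 0
#' everywhere, amplification exactly 1), `sinusoid`
#' (`z = A * sin(2 * pi * x / period)`, amplification given by the
#' arc-length integral), and `bump_lattice` (Gaussian bumps of height
#' `amplitude` on a square lattice with the given period — a stand-in for
#' the regularly spaced microfolds of the plicate membrane surface).
#'
#' @param kind `"flat"`, `"sinusoid"` or `"bump_lattice"`.
#' @param amplitude Height amplitude A (nm).
#' @param period Spatial period (nm); must exceed `2 * spacing`.
#' @param extent Field side length (nm).
#' @param spacing Grid spacing (nm).
#' @param bump_sigma_nm Gaussian bump width for `bump_lattice`
#'   (default `period / 8`).
#' @return A [height_map()].
#' @export
gen_height_map <- function(kind = c("flat", "sinusoid", "bump_lattice"),
                           amplitude = 100, period = 500, extent = 4000,
                           spacing = 20, bump_sigma_nm = NULL) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, extent > spacing)
  if (kind != "flat" && period <= 2 * spacing) {
    abort("period must exceed 2 * spacing (sampling below Nyquist)")
  }
  xs <- seq(0, extent, by = spacing)
  n <- length(xs)
  z <- switch(kind,
    flat = matrix(0, n, n),
    sinusoid = matrix(rep(amplitude * sin(2 * pi * xs / period), each = n),
                      n, n),
    bump_lattice = {
      sig <- bump_sigma_nm %||% (period / 8)
      cx <- seq(period / 2, extent - period / 2 + 1e-9, by = period)
      zz <- matrix(0, n, n)
      for (bx in cx) for (by in cx) {
        zz <- zz + amplitude *
          outer(exp(-(xs - by)^2 / (2 * sig^2)),
                exp(-(xs - bx)^2 / (2 * sig^2)))
      }
      zz
    })
  height_map(z, spacing)
}

#' Generate a particle stack with known poses
#'
#' Each particle is the two-channel template transformed by a recorded pose
#' (rotation about the box center followed by a shift) with Gaussian noise
#' added. Poses are stored as ground truth for alignment-recovery tests.
#'
#' @param template Numeric array `[box, box, 2]`, or `NULL` for the
#'   built-in two-blob template ([default_particle_template()]).
#' @param n Number of particles.
#' @param max_shift_px Maximum absolute shift per axis (px); must be below
#'   half the box.
#' @param max_rot_deg Maximum absolute rotation (degrees).
#' @param noise_level Gaussian noise sd as a fraction of the template
#'   intensity range.
#' @param box_px Box side (px; default 100).
#' @param pixel_nm Pixel size (nm/px; default 20, so a 100 px box spans
#'   2 um).
#' @param seed Integer seed.
#' @return A `particle_stack_truth`: list with `stack` (a
#'   [particle_stack()]), `poses` (tibble: `particle`, `dx`, `dy`,
#'   `rot_deg`), `template`, `noise_level`.
#' @export
gen_particle_stack <- function(template = NULL, n = 50, max_shift_px = 10,
                               max_rot_deg = 30, noise_level = 0.1,
                               box_px = 100, pixel_nm = 20, seed = NULL) {
  stopifnot(n >= 1)
  if (is.null(template)) template <- default_particle_template(box_px)
  box <- dim(template)[1]
  if (max_shift_px > box / 2) {
    abort("max_shift_px exceeds half the box size")
  }
  rng <- diff(range(template))
  with_seed(seed, {
    poses <- tibble(particle = seq_len(n),
                    dx = runif(n, -max_shift_px, max_shift_px),
                    dy = runif(n, -max_shift_px, max_shift_px),
                    rot_deg = runif(n, -max_rot_deg, max_rot_deg))
    arr <- array(0, c(box, box, 2, n))
    for (i in seq_len(n)) {
      p <- apply_pose(template, poses$dx[i], poses$dy[i], poses$rot_deg[i],
                      interp = "bilinear")
      if (noise_level > 0) p <- p + array(rnorm(length(p), 0, noise_level * rng),
                                          dim(p))
      arr[, , , i] <- p
    }
    structure(list(stack = particle_stack(arr, pixel_nm = pixel_nm),
                   poses = poses, template = template,
                   noise_level = noise_level),
              class = "particle_stack_truth")
  })
}

#' Built-in two-channel particle template
#'
#' A smooth anisotropic reference blob (channel 1) with a flanking query
#' blob (channel 2), emulating an adhesion cluster with an overlapping
#' channel cluster. Asymmetric by construction so that rotation is
#' identifiable.
#'
#' @param box_px Box side in pixels.
#' @return Array `[box, box, 2]`.
#' @export
default_particle_template <- function(box_px = 100) {
  c0 <- (box_px + 1) / 2
  xs <- seq_len(box_px) - c0
  X <- matrix(rep(xs, each = box_px), box_px, box_px)   # column = x
  Y <- matrix(rep(xs, times = box_px), box_px, box_px)  # row = y
  g <- function(cx, cy, sx, sy, rot = 0) {
    th <- deg2rad(rot)
    u <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    v <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  }
  ref <- g(0, 0, 20, 5, 20) + 0.7 * g(14, 10, 4, 4) + 0.5 * g(-16, -6, 4, 4)
  qry <- 0.9 * g(-8, -10, 10, 4, -35) + 0.6 * g(12, -6, 5, 3, 60)
  array(c(ref, qry), c(box_px, box_px, 2))
}
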