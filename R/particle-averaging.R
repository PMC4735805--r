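# Cross-correlation particle averaging of boxed two-channel cluster images.
# Alignment iterates against the running average: for each particle an
# exhaustive rotation-grid search (with local refinement) finds the
# rotation whose cross-correlation peak with the current average is
# highest; the peak location gives the translation. The summed normalized
# correlation is the alignment score and is kept non-decreasing across
# iterations.

#' Two-channel particle stack
#'
#' @param particles Array `[box, box, 2, n]` (channels: reference,
#'   secondary) or a list of `[box, box, 2]` arrays.
#' @param pixel_nm Pixel size (nm/px; default 20).
#' @param padded Optional logical vector flagging particles whose
#'   extraction box crossed the image edge.
#' @return A `particle_stack`.
#' @export
particle_stack <- function(particles, pixel_nm = 20, padded = NULL) {
  if (is.list(particles)) {
    d <- dim(particles[[1]])
    arr <- array(0, c(d, length(particles)))
    for (i in seq_along(particles)) arr[, , , i] <- particles[[i]]
    particles <- arr
  }
  stopifnot(length(dim(particles)) == 4, dim(particles)[3] == 2,
            dim(particles)[4] >= 1)
  structure(list(particles = particles, pixel_nm = pixel_nm,
                 padded = padded %||% rep(FALSE, dim(particles)[4]),
                 channel_roles = c("reference", "secondary")),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$particles)
  cat(sprintf("particle stack: %d particles, %d x %d px, 2 channels (%g nm/px)\n",
              d[4], d[1], d[2], x$pixel_nm))
  invisible(x)
}

#' Extract particle boxes around co-localized cluster pairs
#'
#' Boxes of `box_px` pixels are cut from a two-channel image, centered on
#' the given centroids (typically midpoints of co-localized
#' reference/query cluster pairs, i.e. pairs with edge-to-edge distance
#' <= 0). Boxes crossing the image edge are zero-padded and flagged.
#'
#' @param image A [recon_image()].
#' @param centroids Data frame with `x`, `y` centroid coordinates (nm).
#' @param box_px Box side (px; default 100).
#' @return A [particle_stack()] with the `padded` flag set per particle.
#' @export
extract_particles <- function(image, centroids, box_px = 100) {
  stopifnot(inherits(image, "recon_image"))
  if (nrow(centroids) == 0) abort("no centroids to extract")
  d <- dim(image$data)
  half <- box_px %/% 2
  n <- nrow(centroids)
  arr <- array(0, c(box_px, box_px, 2, n))
  padded <- logical(n)
  for (i in seq_len(n)) {
    cx <- floor(centroids$x[i] / image$pixel_nm) + 1
    cy <- floor(centroids$y[i] / image$pixel_nm) + 1
    rows <- (cy - half):(cy - half + box_px - 1)
    cols <- (cx - half):(cx - half + box_px - 1)
    rok <- rows >= 1 & rows <= d[1]
    cok <- cols >= 1 & cols <= d[2]
    padded[i] <- !(all(rok) && all(cok))
    arr[which(rok), which(cok), , i] <- image$data[rows[rok], cols[cok], 1:2]
  }
  particle_stack(arr, pixel_nm = image$pixel_nm, padded = padded)
}

#' Apply a pose to an image
#'
#' Rotates by `rot_deg` about the image center, then shifts by
#' `(dx, dy)` pixels (x rightward = columns, y downward = rows). Inverse
#' mapping with nearest-neighbour (binarity-preserving) or bilinear
#' interpolation; samples falling outside come back as 0.
#'
#' @param img Matrix `[y, x]` or array `[y, x, ch]`.
#' @param dx,dy Shift in pixels.
#' @param rot_deg Rotation in degrees.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return Transformed image, same shape.
#' @export
apply_pose <- function(img, dx = 0, dy = 0, rot_deg = 0,
                       interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  d <- dim(img)
  if (length(d) == 3) {
    out <- img
    for (k in seq_len(d[3])) {
      out[, , k] <- apply_pose(img[, , k], dx, dy, rot_deg, interp)
    }
    return(out)
  }
  nr <- d[1]; nc <- d[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- deg2rad(rot_deg)
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  u <- X - cx - dx
  v <- Y - cy - dy
  xs <- cos(th) * u + sin(th) * v + cx
  ys <- -sin(th) * u + cos(th) * v + cy
  out <- matrix(0, nr, nc)
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
    out[ok] <- img[cbind(yi[ok], xi[ok])]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
    idx <- which(ok)
    x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
    g <- function(r, c) img[cbind(r, c)]
    out[idx] <-
      (1 - fx[idx]) * (1 - fy[idx]) * g(y0[idx], x0[idx]) +
      fx[idx] * (1 - fy[idx]) * g(y0[idx], x1[idx]) +
      (1 - fx[idx]) * fy[idx] * g(y1[idx], x0[idx]) +
      fx[idx] * fy[idx] * g(y1[idx], x1[idx])
  }
  out
}

# invert a pose: if particle = S_d R_theta template, the aligned particle is
# S_{-d'} R_{-theta} particle with d' = R_{-theta} d
unapply_pose <- function(img, dx, dy, rot_deg, interp = "nearest") {
  th <- deg2rad(rot_deg)
  dxp <- cos(th) * dx + sin(th) * dy
  dyp <- -sin(th) * dx + cos(th) * dy
  apply_pose(apply_pose(img, 0, 0, -rot_deg, interp), -dxp, -dyp, 0, interp)
}

# circular cross-correlation peak: returns shift (dx, dy) maximizing
# sum(a * shift(b, d)) and the normalized peak value
xcorr_peak <- function(a, b, max_shift = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  sx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  sy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  if (!is.null(max_shift)) {
    bad_r <- abs(sy) > max_shift
    bad_c <- abs(sx) > max_shift
    cc[bad_r, ] <- -Inf
    cc[, bad_c] <- -Inf
  }
  k <- arrayInd(which.max(cc), dim(cc))
  denom <- sqrt(sum(a^2) * sum(b^2))
  list(dx = sx[k[2]], dy = sy[k[1]],
       score = if (denom > 0) max(cc) / denom else 0)
}

# best (rot, shift) of particle against reference over a rotation grid
best_pose <- function(particle, ref_fft_conj, ref_norm, angles, max_shift,
                      interp, rot_cache = NULL) {
  n <- length(particle)
  best <- list(score = -Inf)
  for (ai in seq_along(angles)) {
    th <- angles[ai]
    rot <- if (!is.null(rot_cache)) {
      apply_map(particle, rot_cache[[ai]])
    } else {
      apply_pose(particle, 0, 0, -th, interp)
    }
    cc <- Re(fft(fft(rot) * ref_fft_conj, inverse = TRUE)) / n
    nr <- nrow(particle); nc <- ncol(particle)
    sx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
    sy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
    if (!is.null(max_shift)) {
      cc[abs(sy) > max_shift, ] <- -Inf
      cc[, abs(sx) > max_shift] <- -Inf
    }
    k <- arrayInd(which.max(cc), dim(cc))
    denom <- sqrt(sum(rot^2)) * ref_norm
    sc <- if (denom > 0) cc[k] / denom else 0
    if (sc > best$score) {
      dxp <- sx[k[2]]; dyp <- sy[k[1]]
      if (interp == "bilinear") {
        # quadratic sub-pixel interpolation of the correlation peak
        wrap <- function(i, n) (i - 1) %% n + 1
        cl <- cc[k[1], wrap(k[2] - 1, nc)]; cr <- cc[k[1], wrap(k[2] + 1, nc)]
        cu <- cc[wrap(k[1] - 1, nr), k[2]]; cd <- cc[wrap(k[1] + 1, nr), k[2]]
        c0 <- cc[k]
        if (is.finite(cl) && is.finite(cr) && cl - 2 * c0 + cr < 0) {
          dxp <- dxp + 0.5 * (cl - cr) / (cl - 2 * c0 + cr)
        }
        if (is.finite(cu) && is.finite(cd) && cu - 2 * c0 + cd < 0) {
          dyp <- dyp + 0.5 * (cu - cd) / (cu - 2 * c0 + cd)
        }
      }
      best <- list(score = sc, rot_deg = th, dxp = dxp, dyp = dyp,
                   rotated = rot)
    }
  }
  best
}

# precomputed inverse-rotation index map (nearest neighbour)
rotation_map <- function(nr, nc, rot_deg) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- deg2rad(-rot_deg)
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  u <- X - cx; v <- Y - cy
  xi <- round(cos(th) * u + sin(th) * v + cx)
  yi <- round(-sin(th) * u + cos(th) * v + cy)
  ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
  src <- rep(NA_integer_, nr * nc)
  src[ok] <- (xi[ok] - 1) * nr + yi[ok]
  src
}

apply_map <- function(img, src) {
  out <- numeric(length(img))
  ok <- !is.na(src)
  out[ok] <- img[src[ok]]
  matrix(out, nrow(img), ncol(img))
}

#' Align a particle stack by iterative cross-correlation
#'
#' One channel drives the alignment. Each iteration matches every particle
#' against the running average over a rotation grid (step
#' `rot_step_deg`, range `+/- rot_range_deg`, followed by a local
#' `refine_step_deg` search around the best grid angle); the
#' cross-correlation peak supplies the shift. The score (summed normalized
#' peak correlation) is non-decreasing over the reported trace: an
#' iteration that would lower it is discarded and the previous poses are
#' returned.
#'
#' @param stack A [particle_stack()].
#' @param channel Channel used for matching (1 = reference, 2 = secondary).
#' @param rot_range_deg Half-range of the rotation search (degrees).
#' @param rot_step_deg Rotation grid step (degrees; default 2).
#' @param refine_step_deg Local refinement step (degrees; default 0.5).
#' @param max_shift_px Maximum shift magnitude searched (px; default half
#'   the box).
#' @param max_iter Maximum iterations (default 10).
#' @param tol Convergence tolerance on the mean per-particle score change.
#' @param interp Interpolation for rotations (`"nearest"` preserves
#'   binarity).
#' @return A `pose_set`: tibble with `particle`, `dx`, `dy`, `rot_deg`,
#'   `score`, plus attributes `score_trace`, `converged`, `channel`.
#' @export
align_stack <- function(stack, channel = 1, rot_range_deg = 180,
                        rot_step_deg = 2, refine_step_deg = 0.5,
                        max_shift_px = NULL, max_iter = 10, tol = 1e-4,
                        interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  arr <- stack$particles[, , channel, , drop = FALSE]
  d <- dim(arr)
  nr <- d[1]; nc <- d[2]; n <- d[4]
  max_shift_px <- max_shift_px %||% (min(nr, nc) %/% 2)
  angles <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg)
  rot_cache <- if (interp == "nearest") {
    purrr::map(angles, function(th) rotation_map(nr, nc, th))
  }
  aligned <- array(arr, c(nr, nc, n))
  poses <- tibble(particle = seq_len(n), dx = 0, dy = 0, rot_deg = 0,
                  score = NA_real_)
  score_trace <- numeric(0)
  prev_score <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ref <- apply(aligned, c(1, 2), mean)
    ref_fft_conj <- Conj(fft(ref))
    ref_norm <- sqrt(sum(ref^2))
    new_poses <- poses
    new_aligned <- aligned
    total <- 0
    for (i in seq_len(n)) {
      p <- matrix(arr[, , 1, i], nr, nc)
      b <- best_pose(p, ref_fft_conj, ref_norm, angles, max_shift_px,
                     interp, rot_cache)
      if (refine_step_deg > 0 && refine_step_deg < rot_step_deg) {
        fine <- setdiff(seq(b$rot_deg - rot_step_deg + refine_step_deg,
                            b$rot_deg + rot_step_deg - refine_step_deg,
                            by = refine_step_deg), angles)
        if (length(fine)) {
          b2 <- best_pose(p, ref_fft_conj, ref_norm, fine, max_shift_px,
                          interp, NULL)
          if (b2$score > b$score) b <- b2
        }
      }
      th <- deg2rad(b$rot_deg)
      new_poses$rot_deg[i] <- b$rot_deg
      new_poses$dx[i] <- cos(th) * b$dxp - sin(th) * b$dyp
      new_poses$dy[i] <- sin(th) * b$dxp + cos(th) * b$dyp
      new_poses$score[i] <- b$score
      new_aligned[, , i] <- apply_pose(b$rotated, -b$dxp, -b$dyp, 0, interp)
      total <- total + b$score
    }
    if (total < prev_score - tol) break     # keep previous (monotone) state
    poses <- new_poses
    aligned <- new_aligned
    score_trace <- c(score_trace, total)
    if (total - prev_score < tol && is.finite(prev_score)) {
      converged <- TRUE
      break
    }
    prev_score <- total
  }
  if (!converged && length(score_trace) == max_iter) {
    warn("alignment did not converge within max_iter iterations")
  }
  structure(poses, class = c("pose_set", class(poses)),
            score_trace = score_trace, converged = converged,
            channel = channel)
}

#' Two-stage two-channel alignment
#'
#' Stage 1 aligns on the reference channel; the stage-1 poses are applied
#' to the secondary channel, which is then aligned in a second stage. The
#' composed poses are returned.
#'
#' @inheritParams align_stack
#' @return A `pose_set` of composed poses, with attribute `stages` holding
#'   the two stage pose sets.
#' @export
align_two_stage <- function(stack, rot_range_deg = 180, rot_step_deg = 2,
                            refine_step_deg = 0.5, max_shift_px = NULL,
                            max_iter = 10, tol = 1e-4,
                            interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  p1 <- align_stack(stack, channel = 1, rot_range_deg = rot_range_deg,
                    rot_step_deg = rot_step_deg,
                    refine_step_deg = refine_step_deg,
                    max_shift_px = max_shift_px, max_iter = max_iter,
                    tol = tol, interp = interp)
  d <- dim(stack$particles)
  arr2 <- array(0, c(d[1], d[2], 2, d[4]))
  for (i in seq_len(d[4])) {
    arr2[, , 2, i] <- unapply_pose(stack$particles[, , 2, i],
                                   p1$dx[i], p1$dy[i], p1$rot_deg[i], interp)
    arr2[, , 1, i] <- unapply_pose(stack$particles[, , 1, i],
                                   p1$dx[i], p1$dy[i], p1$rot_deg[i], interp)
  }
  stage2 <- particle_stack(arr2, pixel_nm = stack$pixel_nm)
  p2 <- align_stack(stage2, channel = 2, rot_range_deg = rot_range_deg,
                    rot_step_deg = rot_step_deg,
                    refine_step_deg = refine_step_deg,
                    max_shift_px = max_shift_px, max_iter = max_iter,
                    tol = tol, interp = interp)
  # compose: particle = pose1(pose2(template))
  th1 <- deg2rad(p1$rot_deg)
  out <- tibble(
    particle = p1$particle,
    dx = p1$dx + cos(th1) * p2$dx - sin(th1) * p2$dy,
    dy = p1$dy + sin(th1) * p2$dx + cos(th1) * p2$dy,
    rot_deg = p1$rot_deg + p2$rot_deg,
    score = p2$score)
  structure(out, class = c("pose_set", class(out)),
            score_trace = attr(p2, "score_trace"),
            converged = attr(p2, "converged"),
            stages = list(p1, p2))
}

#' Average a particle stack under given poses
#'
#' Each particle (both channels, the same pose) is brought back to the
#' common frame by the inverse of its pose; the transformed particles are
#' averaged.
#'
#' @param stack A [particle_stack()].
#' @param poses A `pose_set` (or tibble with `dx`, `dy`, `rot_deg`), one
#'   row per particle.
#' @param interp Interpolation used for the inverse transform.
#' @return Array `[box, box, 2]`: the two-channel average.
#' @export
average_stack <- function(stack, poses, interp = "nearest") {
  d <- dim(stack$particles)
  if (nrow(poses) != d[4]) abort("pose count does not match particle count")
  acc <- array(0, c(d[1], d[2], 2))
  for (i in seq_len(d[4])) {
    for (ch in 1:2) {
      acc[, , ch] <- acc[, , ch] +
        unapply_pose(stack$particles[, , ch, i], poses$dx[i], poses$dy[i],
                     poses$rot_deg[i], interp)
    }
  }
  acc / d[4]
}

#' Pose-recovery errors up to the common reference frame
#'
#' Reference-free alignment determines poses only up to one rigid motion
#' shared by all particles (the internal average frame need not coincide
#' with the frame the ground-truth poses are expressed in). This helper
#' estimates that common offset from the pose differences (mean rotation
#' offset; mean shift offset in the internal frame) and returns the
#' per-particle residual errors after removing it, which is the meaningful
#' recovery metric for validation against generated ground truth.
#'
#' @param estimated A `pose_set` (or tibble with `dx`, `dy`, `rot_deg`).
#' @param truth Ground-truth pose tibble (same columns, same order).
#' @return Tibble with `particle`, `shift_err_px`, `rot_err_deg`, plus
#'   attribute `frame_offset` (`gx`, `gy`, `gamma_deg`) and the corrected
#'   poses as attribute `corrected`.
#' @export
pose_recovery_errors <- function(estimated, truth) {
  stopifnot(nrow(estimated) == nrow(truth))
  th <- deg2rad(estimated$rot_deg)
  dxs <- truth$dx - estimated$dx
  dys <- truth$dy - estimated$dy
  rx <- cos(-th) * dxs + sin(-th) * dys
  ry <- -sin(-th) * dxs + cos(-th) * dys
  gamma <- mean(truth$rot_deg - estimated$rot_deg)
  gx <- mean(rx); gy <- mean(ry)
  corrected <- tibble(
    particle = seq_len(nrow(estimated)),
    dx = estimated$dx + cos(th) * gx - sin(th) * gy,
    dy = estimated$dy + sin(th) * gx + cos(th) * gy,
    rot_deg = estimated$rot_deg + gamma)
  out <- tibble(
    particle = corrected$particle,
    shift_err_px = sqrt((corrected$dx - truth$dx)^2 +
                          (corrected$dy - truth$dy)^2),
    rot_err_deg = abs(corrected$rot_deg - truth$rot_deg))
  attr(out, "frame_offset") <- c(gx = gx, gy = gy, gamma_deg = gamma)
  attr(out, "corrected") <- corrected
  out
}
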