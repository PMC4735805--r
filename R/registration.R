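# Fiducial-based affine registration between fluorescence and EM frames.
# The transform y = L x + t (L a 2x2 linear part, t a translation in nm) is
# estimated by least squares on homogeneous coordinates; fiducials are
# assumed hand-picked, so no robust weighting is applied by default.

#' 2D affine transform
#'
#' @param linear 2x2 matrix (dimensionless linear part).
#' @param translation Length-2 numeric (nm).
#' @return An `affine2d` object.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < .Machine$double.eps) {
    abort("linear part is singular")
  }
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d: y = L x + t\n")
  cat(sprintf("  L = [%9.5f %9.5f; %9.5f %9.5f]   t = (%g, %g) nm\n",
              x$linear[1, 1], x$linear[1, 2], x$linear[2, 1], x$linear[2, 2],
              x$translation[1], x$translation[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.affine2d <- function(x, ...) {
  tibble(term = c("a11", "a12", "a21", "a22", "tx", "ty"),
         estimate = c(t(x$linear), x$translation))
}

#' @exportS3Method generics::glance
glance.affine2d <- function(x, ...) {
  tibble(determinant = det(x$linear),
         rmse_nm = attr(x, "rmse_nm") %||% NA_real_,
         n_pairs = attr(x, "n_pairs") %||% NA_integer_)
}

#' Invert an affine transform
#' @param transform An [affine2d()].
#' @return The inverse `affine2d`.
#' @export
affine_invert <- function(transform) {
  Li <- solve(transform$linear)
  affine2d(Li, -Li %*% transform$translation)
}

#' Compose two affine transforms
#' @param t1,t2 [affine2d()] transforms; the result applies `t2` first,
#'   then `t1`.
#' @return The composed `affine2d`.
#' @export
affine_compose <- function(t1, t2) {
  affine2d(t1$linear %*% t2$linear,
           t1$linear %*% t2$translation + t1$translation)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    xc <- points$x %||% points$src_x
    yc <- points$y %||% points$src_y
    cbind(xc, yc)
  } else {
    matrix(points, ncol = 2)
  }
}

#' Apply an affine transform to points
#'
#' Applies `y = L x + t` per point. Note the image convention: y runs
#' downward, so a rotation with positive angle turns (1, 0) toward (0, 1)
#' visually clockwise on screen.
#'
#' @param points Data frame with `x`, `y` columns or an `n x 2` matrix (nm).
#' @param transform An [affine2d()].
#' @return Matrix (or tibble, if a data frame came in) of transformed
#'   points.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "affine2d"))
  p <- as_point_matrix(points)
  out <- p %*% t(transform$linear)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  if (is.data.frame(points)) tibble(x = out[, 1], y = out[, 2]) else out
}

pair_matrices <- function(pairs) {
  stopifnot(all(c("src_x", "src_y", "dst_x", "dst_y") %in% names(pairs)))
  list(src = cbind(pairs$src_x, pairs$src_y),
       dst = cbind(pairs$dst_x, pairs$dst_y))
}

#' Estimate an affine transform from fiducial pairs
#'
#' Least-squares fit of `dst ~ L src + t` by the normal equations on
#' homogeneous coordinates; exact (to numerical tolerance) when the pairs
#' are noiseless and consistent. With `trim_worst > 0`, the fit is repeated
#' after dropping that many pairs with the largest residuals (off by
#' default: fiducials are assumed hand-curated).
#'
#' @param pairs Tibble with `src_x`, `src_y`, `dst_x`, `dst_y` (nm), e.g.
#'   from [gen_fiducial_pairs()] or [read_fiducials_csv()].
#' @param trim_worst Number of worst pairs to drop and refit (default 0).
#' @return An [affine2d()] with attributes `rmse_nm` and `n_pairs`.
#' @export
estimate_affine <- function(pairs, trim_worst = 0) {
  pm <- pair_matrices(pairs)
  n <- nrow(pm$src)
  if (n < 3) abort("need at least 3 fiducial pairs")
  X <- cbind(pm$src, 1)
  if (qr(X)$rank < 3) {
    abort("degenerate configuration: fiducials are collinear")
  }
  beta <- solve(crossprod(X), crossprod(X, pm$dst))  # 3 x 2
  if (trim_worst > 0 && n - trim_worst >= 3) {
    res <- sqrt(rowSums((X %*% beta - pm$dst)^2))
    keep <- order(res, decreasing = TRUE)[-seq_len(trim_worst)]
    return(estimate_affine(pairs[sort(keep), , drop = FALSE], trim_worst = 0))
  }
  tr <- affine2d(t(beta[1:2, ]), beta[3, ])
  attr(tr, "rmse_nm") <- registration_error(pairs, tr)$rmse_nm
  attr(tr, "n_pairs") <- n
  tr
}

#' Registration residual error
#'
#' Root-mean-square residual of the transformed source points against the
#' targets. A QC flag is raised when the RMSE exceeds the threshold
#' (default 20 nm, the mapping error of the super-resolved reconstruction).
#'
#' @param pairs Fiducial pair tibble.
#' @param transform An [affine2d()].
#' @param threshold_nm QC threshold (nm; default 20).
#' @return List with `rmse_nm`, `residuals_nm` (per pair), `flagged`.
#' @export
registration_error <- function(pairs, transform, threshold_nm = 20) {
  pm <- pair_matrices(pairs)
  if (nrow(pm$src) < 1) abort("no fiducial pairs")
  pred <- transform_points(pm$src, transform)
  res <- sqrt(rowSums((pred - pm$dst)^2))
  rmse <- sqrt(mean(res^2))
  list(rmse_nm = rmse, residuals_nm = res, flagged = rmse > threshold_nm)
}
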