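# Membrane surface topology from height maps: surface-area amplification
# (triangulated area over planform area), peak detection with
# persistence-based prominence, nearest-neighbour peak spacing and Fourier
# periodicity of the peak pattern.

#' Height map container
#'
#' @param z Numeric matrix of surface heights (nm); rows index y, columns
#'   x, grid node `(i, j)` sits at `((j - 1) * spacing, (i - 1) * spacing)`.
#' @param spacing_nm Lateral grid spacing (nm).
#' @param mask Logical matrix of valid samples (default all valid).
#' @return A `height_map`.
#' @export
height_map <- function(z, spacing_nm, mask = NULL) {
  stopifnot(is.matrix(z), spacing_nm > 0)
  mask <- mask %||% matrix(TRUE, nrow(z), ncol(z))
  if (any(!is.finite(z[mask]))) abort("non-finite heights on valid samples")
  structure(list(z = z, spacing_nm = spacing_nm, mask = mask),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height map: %d x %d grid at %g nm spacing, z range [%g, %g] nm\n",
              nrow(x$z), ncol(x$z), x$spacing_nm, min(x$z[x$mask]),
              max(x$z[x$mask])))
  invisible(x)
}

#' Surface-area amplification factor
#'
#' Each grid cell with four valid corners is split into two triangles along
#' a fixed diagonal; the summed 3D triangle area is divided by the planform
#' area of the same cells. Always >= 1; a flat map gives exactly 1. The
#' alternate diagonal is available as a discretization cross-check.
#'
#' @param surface A [height_map()].
#' @param diagonal `"main"` (default) or `"anti"` cell split.
#' @return Dimensionless amplification factor.
#' @export
amplification_factor <- function(surface, diagonal = c("main", "anti")) {
  diagonal <- match.arg(diagonal)
  z <- surface$z; s <- surface$spacing_nm; m <- surface$mask
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) abort("need at least a 2 x 2 grid")
  i <- 1:(nr - 1); j <- 1:(nc - 1)
  valid <- m[i, j, drop = FALSE] & m[i + 1, j, drop = FALSE] &
    m[i, j + 1, drop = FALSE] & m[i + 1, j + 1, drop = FALSE]
  if (!any(valid)) abort("no cell has four valid corners")
  z00 <- z[i, j, drop = FALSE];     z10 <- z[i, j + 1, drop = FALSE]
  z01 <- z[i + 1, j, drop = FALSE]; z11 <- z[i + 1, j + 1, drop = FALSE]
  # triangle area over a right triangle with legs s: for vertices with
  # heights (za at corner, zb along x, zc along y),
  # area = s/2 * sqrt(s^2 + (zb - za)^2 + (zc - za)^2)
  tri <- function(za, zb, zc) 0.5 * s * sqrt(s^2 + (zb - za)^2 + (zc - za)^2)
  area <- if (diagonal == "main") {
    # split along the 00-11 diagonal: triangles (00,10,11) and (00,01,11)
    tri(z10, z00, z11) + tri(z01, z00, z11)
  } else {
    tri(z00, z10, z01) + tri(z11, z01, z10)
  }
  sum(area[valid]) / (sum(valid) * s^2)
}

#' Detect surface peaks
#'
#' Local maxima are extracted with topographic prominence computed by the
#' persistence construction: sweeping the level set from the highest sample
#' down with union-find, a maximum's prominence is its height minus the
#' level at which its component merges into a component holding a higher
#' maximum (the global maximum gets the full height range). Peaks below
#' `min_prominence_nm` are discarded; remaining peaks closer than
#' `min_distance_nm` are suppressed, higher peak wins.
#'
#' @param surface A [height_map()].
#' @param min_distance_nm Minimum peak separation (nm).
#' @param min_prominence_nm Minimum prominence (nm); default 10% of the
#'   height range.
#' @return A `peak_set`: tibble with `x`, `y`, `z` (nm) and
#'   `prominence_nm`, plus a `params` attribute.
#' @export
detect_peaks <- function(surface, min_distance_nm = NULL,
                         min_prominence_nm = NULL) {
  z <- surface$z; s <- surface$spacing_nm; m <- surface$mask
  zrange <- diff(range(z[m]))
  min_prominence_nm <- min_prominence_nm %||% (0.1 * zrange)
  min_distance_nm <- min_distance_nm %||% (2 * s)
  stopifnot(min_distance_nm > 0, min_prominence_nm >= 0)
  empty <- tibble(x = numeric(), y = numeric(), z = numeric(),
                  prominence_nm = numeric())
  if (zrange == 0) {
    return(structure(empty, class = c("peak_set", class(empty))))
  }
  nr <- nrow(z); nc <- ncol(z)
  ord <- order(z, decreasing = TRUE)
  ord <- ord[m[ord]]
  parent <- integer(nr * nc)           # 0 = not yet activated
  peak_of <- integer(nr * nc)          # root -> linear index of its maximum
  prominence <- rep(NA_real_, nr * nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (lin in ord) {
    r <- (lin - 1) %% nr + 1; cc <- (lin - 1) %/% nr + 1
    parent[lin] <- lin
    peak_of[lin] <- lin
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccn <- cc + dc
      if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
      nl <- (ccn - 1) * nr + rr
      if (parent[nl] == 0) next
      ra <- find(lin); rb <- find(nl)
      if (ra == rb) next
      pa <- peak_of[ra]; pb <- peak_of[rb]
      # the component whose maximum is lower dies here
      if (z[pa] < z[pb] || (z[pa] == z[pb] && pa > pb)) {
        tmp <- ra; ra <- rb; rb <- tmp
        tmp <- pa; pa <- pb; pb <- tmp
      }
      if (is.na(prominence[pb])) prominence[pb] <- z[pb] - z[lin]
      parent[rb] <- ra
    }
  }
  act <- which(parent != 0)
  roots <- unique(vapply(act, function(i) as.integer(find(i)), integer(1)))
  for (rt in roots) prominence[peak_of[rt]] <- zrange
  cand <- which(!is.na(prominence) & prominence >= min_prominence_nm)
  if (!length(cand)) {
    return(structure(empty, class = c("peak_set", class(empty)),
                     params = list(min_distance_nm = min_distance_nm,
                                   min_prominence_nm = min_prominence_nm)))
  }
  cand <- cand[order(z[cand], decreasing = TRUE)]
  px <- ((cand - 1) %/% nr) * s
  py <- ((cand - 1) %% nr) * s
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (i == 1) { keep[1] <- TRUE; next }
    k <- which(keep[seq_len(i - 1)])
    keep[i] <- all((px[i] - px[k])^2 + (py[i] - py[k])^2 >=
                     min_distance_nm^2)
  }
  out <- tibble(x = px[keep], y = py[keep], z = z[cand[keep]],
                prominence_nm = prominence[cand[keep]])
  structure(out, class = c("peak_set", class(out)),
            params = list(min_distance_nm = min_distance_nm,
                          min_prominence_nm = min_prominence_nm))
}

#' Nearest-neighbour peak spacing
#'
#' Per-peak distance to its closest neighbour, in full 3D or with the
#' coordinates projected onto the xy plane (z dropped).
#'
#' @param peaks A `peak_set` (or tibble with `x`, `y`, `z`).
#' @param mode `"3d"` or `"projected_2d"`.
#' @return Tibble with `peak`, `neighbour`, `distance_nm`.
#' @export
peak_spacing_stats <- function(peaks, mode = c("3d", "projected_2d")) {
  mode <- match.arg(mode)
  n <- nrow(peaks)
  if (n < 2) abort("need at least 2 peaks for spacing statistics")
  zz <- if (mode == "3d") peaks$z else rep(0, n)
  d2 <- outer(peaks$x, peaks$x, "-")^2 + outer(peaks$y, peaks$y, "-")^2 +
    outer(zz, zz, "-")^2
  diag(d2) <- Inf
  nb <- apply(d2, 1, which.min)
  tibble(peak = seq_len(n), neighbour = nb,
         distance_nm = sqrt(d2[cbind(seq_len(n), nb)]))
}

#' Fourier periodicity of a peak pattern
#'
#' The projected peaks are rendered as Gaussian spots on a square raster,
#' the 2D power spectrum is computed, and power is averaged over radial
#' frequency bins. The dominant spatial period is the interior local
#' maximum of the radial profile with the highest power; when no interior
#' maximum exists (e.g. a single spot) the result is flagged and the
#' period is `NA`.
#'
#' @param peaks A `peak_set` (or tibble with `x`, `y`).
#' @param render_sigma_nm Gaussian spot sigma (nm).
#' @param pixel_nm Raster pixel size (nm).
#' @param extent_nm Raster side length (nm); default covers the peaks plus
#'   a margin.
#' @return A `power_spectrum`: list with `power` (matrix),
#'   `radial_profile` (tibble: `freq_per_nm`, `period_nm`, `power`),
#'   `dominant_period_nm`, `flagged`.
#' @export
periodicity_spectrum <- function(peaks, render_sigma_nm = 50, pixel_nm = 20,
                                 extent_nm = NULL) {
  if (nrow(peaks) < 1) abort("no peaks to render")
  extent_nm <- extent_nm %||%
    (max(max(peaks$x), max(peaks$y)) + 6 * render_sigma_nm)
  npx <- max(8, ceiling(extent_nm / pixel_nm))
  ax <- (seq_len(npx) - 0.5) * pixel_nm
  img <- matrix(0, npx, npx)
  for (i in seq_len(nrow(peaks))) {
    gx <- exp(-(ax - peaks$x[i])^2 / (2 * render_sigma_nm^2))
    gy <- exp(-(ax - peaks$y[i])^2 / (2 * render_sigma_nm^2))
    img <- img + outer(gy, gx)
  }
  pw <- Mod(fft(img))^2
  fr <- c(0:(npx %/% 2), -((npx - npx %/% 2 - 1):1)) / (npx * pixel_nm)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  bin_w <- 1 / (npx * pixel_nm)
  bins <- round(rad / bin_w)
  kmax <- npx %/% 2
  prof <- vapply(0:kmax, function(k) mean(pw[bins == k]), numeric(1))
  profile <- tibble(freq_per_nm = (0:kmax) * bin_w,
                    period_nm = c(Inf, 1 / ((1:kmax) * bin_w)),
                    power = prof)
  interior <- which(
    seq_along(prof) > 2 & seq_along(prof) < length(prof) &
      prof > c(Inf, prof[-length(prof)]) & prof > c(prof[-1], Inf))
  flagged <- length(interior) == 0
  dominant <- if (flagged) NA_real_ else {
    k <- interior[which.max(prof[interior])] - 1
    1 / (k * bin_w)
  }
  if (!flagged && extent_nm < 2 * dominant) flagged <- TRUE
  structure(list(power = pw, radial_profile = profile,
                 dominant_period_nm = dominant, flagged = flagged,
                 pixel_nm = pixel_nm, extent_nm = extent_nm),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power spectrum: dominant period %s nm%s\n",
              if (is.na(x$dominant_period_nm)) "NA"
              else sprintf("%.0f", x$dominant_period_nm),
              if (x$flagged) " (flagged)" else ""))
  invisible(x)
}
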