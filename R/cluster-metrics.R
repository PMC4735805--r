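# Cluster detection and distance statistics on reconstructed localization
# images. Images are thresholded to binary masks, connected components are
# extracted (2D or 3D), analysis is restricted to a band around the membrane
# line, and nearest-neighbour distances between a query species and a
# reference species are summarized as contact/bin fractions.

#' Binarize a reconstructed image channel
#'
#' The channel is linearly rescaled to `[0, 1]` (a deterministic stand-in
#' for manual brightness/contrast adjustment), smoothed with a mean filter
#' of the given radius, and thresholded. The threshold is either a fixed
#' intensity in rescaled units or `"otsu"`.
#'
#' @param image A [recon_image()] or a numeric matrix / 3D array.
#' @param channel Channel name or index (ignored for bare arrays).
#' @param smooth_radius_px Mean-filter radius in pixels; `0` disables
#'   smoothing.
#' @param threshold Numeric fixed threshold in `[0, 1]` (applied as
#'   `>= threshold` to the rescaled, smoothed intensities) or `"otsu"`.
#' @param rescale Rescale intensities to `[0, 1]` before thresholding
#'   (default `TRUE`; a constant image maps to all zeros).
#' @return Logical mask with the channel's dimensions.
#' @export
binarize <- function(image, channel = 1, smooth_radius_px = 0,
                     threshold = "otsu", rescale = TRUE) {
  x <- get_channel(image, channel)
  if (rescale) {
    rng <- range(x)
    x <- if (diff(rng) == 0) array(0, dim(x) %||% length(x)) else
      (x - rng[1]) / diff(rng)
  }
  if (smooth_radius_px > 0) {
    w <- 2 * round(smooth_radius_px) + 1
    br <- EBImage::makeBrush(w, shape = "box")
    br <- br / sum(br)
    if (length(dim(x)) == 3) {
      for (k in seq_len(dim(x)[3])) {
        x[, , k] <- EBImage::filter2(x[, , k], br, boundary = "replicate")
      }
    } else {
      x <- EBImage::filter2(x, br, boundary = "replicate")
    }
  }
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu")) {
      abort(sprintf("unknown threshold method '%s'", threshold))
    }
    if (all(x == x[1])) return(array(FALSE, dim(x)))
    thr <- EBImage::otsu(EBImage::Image(as.vector(x), dim = c(length(x), 1)))
    mask <- x > thr
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    mask <- x >= threshold
  }
  array(mask, dim(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_channel <- function(image, channel) {
  if (inherits(image, "recon_image")) {
    ch <- if (is.character(channel)) match(channel, image$channels) else channel
    if (is.na(ch) || ch < 1 || ch > length(image$channels)) {
      abort(sprintf("channel '%s' not found", as.character(channel)))
    }
    d <- dim(image$data)
    if (length(d) == 4) image$data[, , ch, ] else image$data[, , ch]
  } else {
    image
  }
}

#' Detect clusters as connected components of a binary mask
#'
#' Components with at least `min_size` pixels (voxels) are reported with
#' centroid (nm), area (nm^2) or volume (nm^3), and, in 2D, circularity
#' `4 * pi * area / perimeter^2` clamped to `[0, 1]` (perimeter from the
#' object's boundary-pixel count).
#'
#' @param mask Logical/0-1 matrix (2D) or 3D array.
#' @param pixel_nm Lateral pixel size (nm; default 20).
#' @param min_size Minimum component size in pixels/voxels.
#' @param connectivity `8` or `4` in 2D; `26` or `6` in 3D. Defaults to 8
#'   and 26 respectively.
#' @param z_step_nm Axial step (nm); required for 3D masks.
#' @return Tibble with one row per cluster: `id`, `centroid_x`,
#'   `centroid_y` (and `centroid_z`), `n_px`, `area_nm2` (or `volume_nm3`),
#'   `circularity` (2D), plus list-columns `pixels` and `boundary` of pixel
#'   index matrices. The pixel size is attached as attribute `pixel_nm`.
#' @export
detect_clusters <- function(mask, pixel_nm = 20, min_size = 1,
                            connectivity = NULL, z_step_nm = NULL) {
  d <- dim(mask)
  is3d <- length(d) == 3
  if (is3d && is.null(z_step_nm)) abort("z_step_nm required for 3D masks")
  connectivity <- connectivity %||% if (is3d) 26L else 8L
  if (is3d) stopifnot(connectivity %in% c(6L, 26L))
  else stopifnot(connectivity %in% c(4L, 8L))
  m <- array(as.integer(mask != 0), d)
  labels <- label_components_cpp(m, as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0) return(empty_clusters(is3d, pixel_nm))
  sizes <- tabulate(labels[labels > 0], nbins = nlab)
  keep <- which(sizes >= min_size)
  if (!length(keep)) return(empty_clusters(is3d, pixel_nm))
  bnd <- boundary_mask(labels)
  out <- purrr::map(seq_along(keep), function(k) {
    lab <- keep[k]
    idx <- which(labels == lab, arr.ind = TRUE)
    bidx <- which(labels == lab & bnd, arr.ind = TRUE)
    cx <- mean(idx[, 2] - 0.5) * pixel_nm
    cy <- mean(idx[, 1] - 0.5) * pixel_nm
    base <- tibble(id = k, centroid_x = cx, centroid_y = cy)
    if (is3d) {
      base$centroid_z <- mean(idx[, 3] - 0.5) * z_step_nm
      base$n_px <- nrow(idx)
      base$volume_nm3 <- nrow(idx) * pixel_nm^2 * z_step_nm
    } else {
      base$n_px <- nrow(idx)
      base$area_nm2 <- nrow(idx) * pixel_nm^2
      base$circularity <- min(1, 4 * pi * nrow(idx) / nrow(bidx)^2)
    }
    base$pixels <- list(idx)
    base$boundary <- list(bidx)
    base
  })
  res <- dplyr::bind_rows(out)
  attr(res, "pixel_nm") <- pixel_nm
  attr(res, "z_step_nm") <- z_step_nm
  res
}

empty_clusters <- function(is3d, pixel_nm) {
  res <- if (is3d) {
    tibble(id = integer(), centroid_x = numeric(), centroid_y = numeric(),
           centroid_z = numeric(), n_px = integer(), volume_nm3 = numeric(),
           pixels = list(), boundary = list())
  } else {
    tibble(id = integer(), centroid_x = numeric(), centroid_y = numeric(),
           n_px = integer(), area_nm2 = numeric(), circularity = numeric(),
           pixels = list(), boundary = list())
  }
  attr(res, "pixel_nm") <- pixel_nm
  res
}

# foreground pixels with an axial neighbour of a different label (or the
# image border): the rasterized object boundary
boundary_mask <- function(labels) {
  d <- dim(labels)
  pad <- array(0L, d + 2)
  if (length(d) == 2) {
    pad[2:(d[1] + 1), 2:(d[2] + 1)] <- labels
    ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
    out <- (pad[1:d[1], 2:(d[2] + 1)] != ctr) |
      (pad[3:(d[1] + 2), 2:(d[2] + 1)] != ctr) |
      (pad[2:(d[1] + 1), 1:d[2]] != ctr) |
      (pad[2:(d[1] + 1), 3:(d[2] + 2)] != ctr)
  } else {
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- labels
    ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    out <- (pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] != ctr) |
      (pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] != ctr) |
      (pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] != ctr) |
      (pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] != ctr) |
      (pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] != ctr) |
      (pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)] != ctr)
  }
  out & labels > 0
}

#' Binarize and detect clusters in every channel of an image
#'
#' Convenience wrapper: runs [binarize()] and [detect_clusters()] per
#' channel and stacks the results with a `channel` column.
#'
#' @inheritParams binarize
#' @inheritParams detect_clusters
#' @return Tibble of clusters with a `channel` column.
#' @export
analyze_image <- function(image, smooth_radius_px = 0, threshold = "otsu",
                          min_size = 1, connectivity = NULL) {
  stopifnot(inherits(image, "recon_image"))
  out <- purrr::map(image$channels, function(ch) {
    m <- binarize(image, ch, smooth_radius_px, threshold)
    cl <- detect_clusters(m, pixel_nm = image$pixel_nm, min_size = min_size,
                          connectivity = connectivity,
                          z_step_nm = image$z_step_nm)
    if (nrow(cl)) cl$channel <- ch
    cl
  })
  res <- dplyr::bind_rows(out)
  attr(res, "pixel_nm") <- image$pixel_nm
  res
}

#' Keep clusters within a band around the membrane line
#'
#' @param clusters Cluster tibble (detected or parametric) with centroid
#'   columns `centroid_x`/`centroid_y` or `x`/`y`.
#' @param membrane_line Data frame of polyline vertices (`x`, `y`, nm).
#' @param halfwidth_nm Band half-width (nm; default 500).
#' @return The subset of clusters whose centroid lies within
#'   `halfwidth_nm` of the polyline.
#' @export
filter_by_membrane <- function(clusters, membrane_line, halfwidth_nm = 500) {
  stopifnot(halfwidth_nm > 0)
  if (is.null(membrane_line) || nrow(membrane_line) < 2) {
    abort("membrane line must have at least 2 vertices")
  }
  cx <- clusters[["centroid_x"]] %||% clusters[["x"]]
  cy <- clusters[["centroid_y"]] %||% clusters[["y"]]
  d <- point_polyline_distance(cx, cy, membrane_line)
  clusters[d <= halfwidth_nm, , drop = FALSE]
}

# ---- nearest-neighbour distances ------------------------------------------

is_parametric <- function(cl) all(c("a", "b", "theta") %in% names(cl))

cluster_centroids <- function(cl) {
  cbind(cl[["centroid_x"]] %||% cl[["x"]], cl[["centroid_y"]] %||% cl[["y"]])
}

# max centroid-to-boundary radius per cluster, used for search pruning
cluster_radii <- function(cl, pixel_nm = NULL) {
  if (is_parametric(cl)) return(pmax(cl$a, cl$b))
  ctr <- cluster_centroids(cl)
  vapply(seq_len(nrow(cl)), function(i) {
    b <- (cl$boundary[[i]] - 0.5) * pixel_nm
    sqrt(max((b[, 2] - ctr[i, 1])^2 + (b[, 1] - ctr[i, 2])^2))
  }, numeric(1))
}

# signed edge distance between two detected (pixel) clusters, in nm
pixel_edge_distance <- function(ci, cj, pixel_nm) {
  key_i <- ci$pixels[[1]][, 1] * 1e6 + ci$pixels[[1]][, 2]
  key_j <- cj$pixels[[1]][, 1] * 1e6 + cj$pixels[[1]][, 2]
  shared <- intersect(key_i, key_j)
  bi <- ci$boundary[[1]]; bj <- cj$boundary[[1]]
  if (length(shared)) {
    sr <- shared %/% 1e6; sc <- shared %% 1e6
    di <- sqrt(outer(sr, bi[, 1], "-")^2 + outer(sc, bi[, 2], "-")^2)
    dj <- sqrt(outer(sr, bj[, 1], "-")^2 + outer(sc, bj[, 2], "-")^2)
    pen <- max(pmin(apply(di, 1, min), apply(dj, 1, min)))
    return(-pen * pixel_nm)
  }
  dmin <- min_pointset_distance(bi, bj)
  (dmin - sqrt(2)) * pixel_nm
}

#' Nearest reference cluster for each query cluster
#'
#' For every query cluster the nearest reference cluster by edge-to-edge
#' distance is found. Both the centroid-to-centroid and the signed
#' edge-to-edge distance are reported; `edge_nm <= 0` marks contact
#' (touching or overlapping boundaries). Detected clusters use rasterized
#' boundaries (minimum boundary pixel-center distance minus one pixel
#' diagonal; overlap gives the negative of the maximal mutual penetration);
#' parametric ellipse tables (columns `a`, `b`, `theta`) use the exact
#' ellipse geometry. Ties are broken by the lowest reference id.
#'
#' @param query,reference Cluster tibbles (from [detect_clusters()]) or
#'   parametric ellipse tibbles (`id`, `x`, `y`, `a`, `b`, `theta`).
#' @return Tibble with `query_id`, `reference_id`, `centroid_nm`,
#'   `edge_nm`, `contact`.
#' @export
nn_distances <- function(query, reference) {
  if (nrow(reference) == 0) abort("reference cluster set is empty")
  if (nrow(query) == 0) {
    return(tibble(query_id = integer(), reference_id = integer(),
                  centroid_nm = numeric(), edge_nm = numeric(),
                  contact = logical()))
  }
  param <- is_parametric(query) && is_parametric(reference)
  pixel_nm <- attr(query, "pixel_nm") %||% attr(reference, "pixel_nm")
  if (!param && is.null(pixel_nm)) {
    abort("pixel_nm attribute required for detected-cluster distances")
  }
  qc <- cluster_centroids(query); rc <- cluster_centroids(reference)
  qr <- cluster_radii(query, pixel_nm); rr <- cluster_radii(reference, pixel_nm)
  edge_fun <- if (param) {
    qm <- as.matrix(query[, c("x", "y", "a", "b", "theta")])
    rm_ <- as.matrix(reference[, c("x", "y", "a", "b", "theta")])
    function(i, j) ellipse_edge_distance(qm[i, ], rm_[j, ])
  } else {
    function(i, j) pixel_edge_distance(query[i, ], reference[j, ], pixel_nm)
  }
  qid <- query[["id"]] %||% seq_len(nrow(query))
  rid <- reference[["id"]] %||% seq_len(nrow(reference))
  out <- purrr::map(seq_len(nrow(query)), function(i) {
    dc <- sqrt((rc[, 1] - qc[i, 1])^2 + (rc[, 2] - qc[i, 2])^2)
    lower <- dc - rr - qr[i]          # edge distance can not be smaller
    ord <- order(lower, rid)
    best <- Inf; best_j <- NA_integer_; best_dc <- NA_real_
    for (j in ord) {
      if (lower[j] >= best) break
      e <- edge_fun(i, j)
      if (e < best || (e == best && rid[j] < rid[best_j])) {
        best <- e; best_j <- j; best_dc <- dc[j]
      }
    }
    tibble(query_id = qid[i], reference_id = rid[best_j],
           centroid_nm = best_dc, edge_nm = best, contact = best <= 0)
  })
  dplyr::bind_rows(out)
}

# ---- distance summaries ----------------------------------------------------

distance_breaks <- function(bin_nm, bin_max_nm) {
  c(seq(0, bin_max_nm, by = bin_nm), Inf)
}

edge_histogram <- function(edges, breaks) {
  lo <- head(breaks, -1)
  hi <- breaks[-1]
  labels <- c("contact",
              sprintf("(%g,%s]", lo,
                      vapply(hi, function(v)
                        if (is.finite(v)) sprintf("%g", v) else "Inf",
                        character(1))))
  n_bins <- length(breaks) - 1
  counts <- integer(n_bins + 1)
  counts[1] <- sum(edges <= 0)
  pos <- edges[edges > 0]
  if (length(pos)) {
    # findInterval with left.open: value in (breaks[i], breaks[i+1]] -> i
    idx <- findInterval(pos, breaks, left.open = TRUE)
    counts[-1] <- tabulate(idx, nbins = n_bins)
  }
  tot <- length(edges)
  tibble(bin = labels, count = counts,
         fraction = if (tot) counts / tot else rep(0, n_bins + 1))
}

#' Summarize nearest-neighbour distance records
#'
#' Fractions of query clusters in contact (edge distance `<= 0`) and per
#' distance bin of width `bin_nm` on the edge distance. Fractions sum to 1
#' over contact plus all bins.
#'
#' @param records Tibble from [nn_distances()].
#' @param bin_nm Bin width (nm; default 100).
#' @param bin_max_nm Upper edge of the last finite bin (nm); distances
#'   beyond it fall into an overflow bin.
#' @return A `distance_summary`: tibble (`bin`, `count`, `fraction`) with
#'   attributes `contact_fraction` and `n`.
#' @export
distance_summary <- function(records, bin_nm = 100, bin_max_nm = 1000) {
  stopifnot(bin_nm > 0)
  if (nrow(records) == 0) abort("no distance records to summarize")
  h <- edge_histogram(records$edge_nm, distance_breaks(bin_nm, bin_max_nm))
  structure(h, class = c("distance_summary", class(h)),
            contact_fraction = h$fraction[1], n = nrow(records),
            bin_nm = bin_nm)
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance summary over %d records (contact fraction %.3f)\n",
              attr(x, "n"), attr(x, "contact_fraction")))
  NextMethod()
}
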