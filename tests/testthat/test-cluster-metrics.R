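make_disc_mask <- function(nr, nc, cy, cx, r) {
  m <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  }
  m
}

test_that("binarize handles trivial and degenerate inputs", {
  z <- matrix(0, 10, 10)
  expect_false(any(binarize(z, threshold = 0.5)))
  expect_false(any(binarize(z, threshold = "otsu")))

  b <- matrix(0, 8, 8); b[3:5, 3:5] <- 1
  expect_equal(array(binarize(b, smooth_radius_px = 0, threshold = 0.5),
                     dim(b)),
               array(b == 1, dim(b)))
  expect_error(binarize(b, threshold = "quantile"), "unknown threshold")
})

test_that("smoothing uses a mean filter of the given radius", {
  z <- matrix(0, 9, 9); z[5, 5] <- 9
  sm <- binarize(z, smooth_radius_px = 1, threshold = 0.999, rescale = FALSE)
  # 3x3 mean of a unit spike of 9 = 1 on the 3x3 neighbourhood
  expect_equal(sum(sm), 9)
  expect_true(all(which(sm, arr.ind = TRUE)[, 1] %in% 4:6))
})

test_that("a rasterized disc yields one near-circular cluster", {
  m <- make_disc_mask(21, 21, 11, 11, 5)
  cl <- detect_clusters(m, pixel_nm = 20)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_px, sum(m))
  expect_lt(abs(cl$n_px - pi * 25) / (pi * 25), 0.10)
  expect_equal(cl$area_nm2, sum(m) * 400)
  expect_gt(cl$circularity, 0.85)
  expect_equal(cl$centroid_x, (11 - 0.5) * 20, tolerance = 1e-9)
  expect_equal(cl$centroid_y, (11 - 0.5) * 20, tolerance = 1e-9)
})

test_that("separated discs are reported as distinct clusters", {
  m <- make_disc_mask(40, 40, 10, 10, 4) + make_disc_mask(40, 40, 30, 30, 4)
  cl <- detect_clusters(m, pixel_nm = 20)
  expect_equal(nrow(cl), 2)
  expect_equal(detect_clusters(matrix(0L, 5, 5), pixel_nm = 20) |> nrow(), 0)
})

test_that("component labelling matches the BFS oracle in 2D and 3D", {
  set.seed(33)
  for (conn in c(4L, 8L)) {
    m <- matrix(rbinom(40 * 30, 1, 0.35), 40, 30)
    got <- idnodes:::label_components_cpp(array(m, dim(m)), conn)
    want <- oracle_label_components(m, conn)
    expect_true(same_partition(got, want))
  }
  for (conn in c(6L, 26L)) {
    a <- array(rbinom(12 * 10 * 6, 1, 0.3), c(12, 10, 6))
    got <- idnodes:::label_components_cpp(array(as.integer(a), dim(a)), conn)
    want <- oracle_label_components(a, conn)
    expect_true(same_partition(got, want))
  }
})

test_that("cluster pixel counts account for all foreground above min_size", {
  set.seed(44)
  m <- matrix(rbinom(50 * 50, 1, 0.3), 50, 50)
  lab <- oracle_label_components(m, 8)
  sizes <- table(lab[lab > 0])
  for (ms in c(1, 3, 8)) {
    cl <- detect_clusters(m, pixel_nm = 20, min_size = ms)
    expect_equal(sum(cl$n_px), sum(sizes[sizes >= ms]))
  }
})

test_that("detection is invariant to whole-pixel translation", {
  set.seed(7)
  m <- matrix(0L, 60, 60)
  m[10:14, 10:16] <- 1L; m[30:38, 40:44] <- 1L
  m2 <- matrix(0L, 60, 60)
  m2[13:17, 15:21] <- 1L; m2[33:41, 45:49] <- 1L   # shifted by (3, 5)
  c1 <- detect_clusters(m, pixel_nm = 20)
  c2 <- detect_clusters(m2, pixel_nm = 20)
  expect_equal(c2$centroid_x - c1$centroid_x, rep(5 * 20, 2))
  expect_equal(c2$centroid_y - c1$centroid_y, rep(3 * 20, 2))
  expect_equal(c1$n_px, c2$n_px)
  expect_equal(c1$circularity, c2$circularity)
})

test_that("3D detection reports volumes and centroids in nm", {
  a <- array(0L, c(20, 20, 10))
  a[3:6, 3:6, 2:4] <- 1L
  cl <- detect_clusters(a, pixel_nm = 20, min_size = 1, z_step_nm = 50)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$volume_nm3, 48 * 20^2 * 50)
  expect_equal(cl$centroid_z, (3 - 0.5) * 50)
  expect_error(detect_clusters(a, pixel_nm = 20), "z_step_nm")
})

test_that("membrane filtering keeps centroids within the halfwidth", {
  line <- data.frame(x = c(0, 2000), y = c(500, 500))
  cl <- tibble::tibble(id = 1:3,
                       centroid_x = c(100, 1000, 1500),
                       centroid_y = c(900, 1100, 499))
  kept <- filter_by_membrane(cl, line, halfwidth_nm = 500)
  expect_equal(kept$id, c(1L, 3L))
  expect_error(filter_by_membrane(cl, line[1, , drop = FALSE]), "2 vertices")

  set.seed(15)
  rnd <- tibble::tibble(id = 1:50, centroid_x = runif(50, -100, 2100),
                        centroid_y = runif(50, 0, 2000))
  kept2 <- filter_by_membrane(rnd, line, 500)
  want <- rnd$id[point_polyline_distance(rnd$centroid_x, rnd$centroid_y,
                                         line) <= 500]
  expect_equal(kept2$id, want)
})

test_that("parametric nearest-neighbour search matches the O(n^2) oracle", {
  set.seed(61)
  qry <- tibble::tibble(id = 1:50, x = runif(50, 0, 5000),
                        y = runif(50, 0, 1000), a = runif(50, 40, 200),
                        b = runif(50, 30, 150), theta = runif(50, 0, 180))
  ref <- tibble::tibble(id = 1:20, x = runif(20, 0, 5000),
                        y = runif(20, 0, 1000), a = runif(20, 50, 250),
                        b = runif(20, 40, 180), theta = runif(20, 0, 180))
  got <- nn_distances(qry, ref)
  want <- oracle_nn_param(qry, ref)
  expect_equal(got$reference_id, want$reference_id)
  expect_equal(got$edge_nm, want$edge_nm)
  expect_true(all(got$centroid_nm >= got$edge_nm))
  expect_error(nn_distances(qry, ref[0, ]), "empty")
})

test_that("pixel-cluster distances follow the rasterized convention", {
  # two discs radius 5 px, centers 15 px apart at 20 nm/px:
  # centroid 300 nm, boundary gap 5 px -> edge (5 - sqrt(2)) * 20
  m <- make_disc_mask(40, 40, 20, 10, 5)
  m2 <- make_disc_mask(40, 40, 20, 25, 5)
  c1 <- detect_clusters(m, pixel_nm = 20)
  c2 <- detect_clusters(m2, pixel_nm = 20)
  rec <- nn_distances(c1, c2)
  expect_equal(rec$centroid_nm, 300)
  expect_equal(rec$edge_nm, (5 - sqrt(2)) * 20, tolerance = 1e-9)
  expect_false(rec$contact)
  # identical overlapping cluster: shared pixels -> negative edge, contact
  rec2 <- nn_distances(c1, c1)
  expect_lte(rec2$edge_nm, 0)
  expect_true(rec2$contact)
})

test_that("distance summaries count contact and bins directly", {
  rec <- tibble::tibble(query_id = 1:6, reference_id = 1L,
                        centroid_nm = 1:6 * 100,
                        edge_nm = c(-10, -5, 40, 150, 250, 600),
                        contact = c(-10, -5, 40, 150, 250, 600) <= 0)
  s <- distance_summary(rec, bin_nm = 100)
  expect_equal(attr(s, "contact_fraction"), 2 / 6)
  expect_equal(s$fraction[s$bin == "(0,100]"], 1 / 6)
  expect_equal(s$fraction[s$bin == "(100,200]"], 1 / 6)
  expect_equal(s$fraction[s$bin == "(200,300]"], 1 / 6)
  expect_equal(s$fraction[s$bin == "(500,600]"], 1 / 6)
  expect_equal(sum(s$fraction), 1)

  all_contact <- dplyr::mutate(rec, edge_nm = -1, contact = TRUE)
  expect_equal(attr(distance_summary(all_contact), "contact_fraction"), 1)
  expect_error(distance_summary(rec[0, ]), "no distance records")
})

test_that("synthesize -> render -> detect round-trip recovers clusters", {
  for (s in 1:6) {
    f <- gen_ellipse_field(5000, 0, 6, attraction_f = 1, seed = 400 + s,
                           query_min_edge_nm = 100, margin_nm = 350)
    img <- render_localization_image(f, pixel_nm = 20, density = 0.05,
                                     precision_nm = 10, seed = 500 + s)
    mask <- binarize(img, "query",
                     threshold = 0.5 / max(img$data[, , 2]))
    cl <- detect_clusters(mask, pixel_nm = 20, min_size = 4)
    expect_equal(nrow(cl), 6)
    truth <- f$ellipses[f$ellipses$channel == "query", ]
    for (i in seq_len(nrow(cl))) {
      d <- sqrt((truth$x - cl$centroid_x[i])^2 +
                  (truth$y - cl$centroid_y[i])^2)
      expect_lt(min(d), 20)   # within one pixel
    }
  }
})
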