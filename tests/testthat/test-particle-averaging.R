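test_that("apply_pose identities and inverses hold", {
  tmpl <- default_particle_template(60)[, , 1]
  expect_equal(apply_pose(tmpl, 0, 0, 0, "bilinear"), tmpl)
  expect_equal(apply_pose(tmpl, 0, 0, 0, "nearest"), tmpl)
  shifted <- apply_pose(tmpl, 5, -3, 0, "nearest")
  back <- apply_pose(shifted, -5, 3, 0, "nearest")
  ctr <- 15:45
  expect_equal(back[ctr, ctr], tmpl[ctr, ctr])
})

test_that("identical particles align with identity poses", {
  tmpl <- default_particle_template(60)
  arr <- array(0, c(60, 60, 2, 6))
  for (i in 1:6) arr[, , , i] <- tmpl
  st <- particle_stack(arr)
  poses <- align_stack(st, channel = 1, rot_range_deg = 10,
                       rot_step_deg = 2, max_shift_px = 10)
  expect_equal(poses$dx, rep(0, 6))
  expect_equal(poses$dy, rep(0, 6))
  expect_equal(poses$rot_deg, rep(0, 6))
  expect_true(all(poses$score > 0.999))
  avg <- average_stack(st, poses)
  expect_equal(avg[, , 1], tmpl[, , 1], tolerance = 1e-9)
})

test_that("a single particle gets the identity pose", {
  tmpl <- default_particle_template(40)
  st <- particle_stack(array(tmpl, c(40, 40, 2, 1)))
  poses <- align_stack(st, rot_range_deg = 6, rot_step_deg = 2)
  expect_equal(as.numeric(poses[1, c("dx", "dy", "rot_deg")]), c(0, 0, 0))
})

test_that("averaging is linear and permutation-invariant", {
  tmpl <- default_particle_template(40)
  zero <- array(0, dim(tmpl))
  st <- particle_stack(list(tmpl, zero))
  poses <- tibble::tibble(particle = 1:2, dx = 0, dy = 0, rot_deg = 0)
  avg <- average_stack(st, poses)
  expect_equal(avg, tmpl / 2)

  set.seed(2)
  parts <- lapply(1:5, function(i) tmpl + array(rnorm(length(tmpl), 0, 0.05),
                                                dim(tmpl)))
  p5 <- tibble::tibble(particle = 1:5, dx = c(1, -2, 0, 3, -1),
                       dy = c(0, 1, -2, 2, 0), rot_deg = c(4, -6, 0, 8, -2))
  perm <- c(3, 5, 1, 4, 2)
  a1 <- average_stack(particle_stack(parts), p5)
  a2 <- average_stack(particle_stack(parts[perm]), p5[perm, ])
  expect_equal(a1, a2)
  expect_error(average_stack(particle_stack(parts), p5[1:3, ]),
               "does not match")
})

test_that("the alignment score trace is monotone non-decreasing", {
  truth <- gen_particle_stack(n = 10, max_shift_px = 6, max_rot_deg = 15,
                              noise_level = 0.15, box_px = 64, seed = 41)
  poses <- align_stack(truth$stack, rot_range_deg = 20, rot_step_deg = 2,
                       max_shift_px = 10, interp = "bilinear")
  trace <- attr(poses, "score_trace")
  expect_gte(length(trace), 1)
  expect_true(all(diff(trace) >= -1e-9))
})

test_that("known poses are recovered up to the common frame", {
  truth <- gen_particle_stack(n = 16, max_shift_px = 8, max_rot_deg = 25,
                              noise_level = 0.1, box_px = 80, seed = 51)
  poses <- align_stack(truth$stack, channel = 1, rot_range_deg = 30,
                       rot_step_deg = 2, max_shift_px = 12,
                       interp = "bilinear")
  errs <- pose_recovery_errors(poses, truth$poses)
  expect_gte(mean(errs$shift_err_px <= 1 & errs$rot_err_deg <= 2), 0.85)
  # frame-corrected average resembles the template
  avg <- average_stack(truth$stack, poses, interp = "bilinear")
  off <- attr(errs, "frame_offset")
  fixed <- idnodes:::unapply_pose(avg[, , 1], off["gx"], off["gy"],
                                  off["gamma_deg"], "bilinear")
  expect_gt(cor(as.vector(fixed), as.vector(truth$template[, , 1])), 0.95)
})

test_that("a common rigid motion of the inputs moves the average, not the poses", {
  truth <- gen_particle_stack(n = 6, max_shift_px = 4, max_rot_deg = 10,
                              noise_level = 0, box_px = 64, seed = 61)
  shifted <- truth$stack
  for (i in 1:6) {
    shifted$particles[, , , i] <- apply_pose(truth$stack$particles[, , , i],
                                             4, 2, 0, "bilinear")
  }
  p0 <- align_stack(truth$stack, rot_range_deg = 14, rot_step_deg = 2,
                    max_shift_px = 10, interp = "bilinear")
  p1 <- align_stack(shifted, rot_range_deg = 14, rot_step_deg = 2,
                    max_shift_px = 10, interp = "bilinear")
  # relative poses are unchanged up to the search grid resolution (edge
  # zero-fill perturbs the optima slightly)
  expect_lte(max(abs(p1$dx - p0$dx)), 1.5)
  expect_lte(max(abs(p1$dy - p0$dy)), 1.5)
  expect_lte(max(abs(p1$rot_deg - p0$rot_deg)), 0.5)
  # and the averages differ by exactly that motion
  a0 <- average_stack(truth$stack, p0, interp = "bilinear")
  a1 <- average_stack(shifted, p1, interp = "bilinear")
  moved <- apply_pose(a0[, , 1], 4, 2, 0, "bilinear")
  ctr <- 10:54
  expect_gt(cor(as.vector(moved[ctr, ctr]), as.vector(a1[ctr, ctr, 1])),
            0.99)
})

test_that("extract_particles crops, pads and flags correctly", {
  set.seed(3)
  img_arr <- array(runif(200 * 300 * 2), c(200, 300, 2))
  img <- recon_image(img_arr, pixel_nm = 20)
  ctr <- tibble::tibble(x = 150 * 20, y = 100 * 20)   # center
  st <- extract_particles(img, ctr, box_px = 100)
  expect_false(st$padded[1])
  expect_equal(st$particles[, , 1, 1], img_arr[51:150, 101:200, 1])
  corner <- tibble::tibble(x = 40, y = 40)
  st2 <- extract_particles(img, corner, box_px = 100)
  expect_true(st2$padded[1])
  expect_equal(dim(st2$particles)[1:2], c(100, 100))
  expect_error(extract_particles(img, ctr[0, ]), "no centroids")
})
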