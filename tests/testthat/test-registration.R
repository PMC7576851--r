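test_that("affine helpers compose, invert and validate", {
  t1 <- make_affine(rotation_deg = 7, tx = 3, ty = -2, center = c(10, 10))
  t2 <- make_affine(rotation_deg = -7, tx = 1, ty = 5)
  pts <- matrix(runif(20, 0, 50), 10, 2)
  expect_equal(affine_apply_points(affine_compose(t1, t2), pts),
               affine_apply_points(t1, affine_apply_points(t2, pts)))
  expect_equal(affine_apply_points(affine_compose(t1, affine_invert(t1)), pts),
               pts, tolerance = 1e-10)
  expect_error(affine_transform(matrix(c(1, 2, 2, 4, 0, 0), 2, 3)), "invertible")
})

test_that("nuclei preprocessing removes flat background and keeps small spots", {
  flat <- channel_image(matrix(37, 40, 40), 0.5, "nuclei")
  expect_true(all(preprocess_nuclei(flat, 5, 2)$pixels == 0))

  # isolated bright spot smaller than the rolling ball survives subtraction
  px <- matrix(0, 48, 48)
  px[21:25, 21:25] <- 100
  img <- channel_image(px, 0.5, "nuclei")
  out <- preprocess_nuclei(img, 10, 2)
  expect_true(all(out$pixels >= 0))
  expect_gt(max(out$pixels), 0)

  # oracle: brute-force grey-scale opening (erosion then dilation with an
  # inclusive disk) subtracted, then a brute-force median filter
  r <- 10L; mr <- 2L
  off <- -r:r
  in_disk <- outer(off, off, function(a, b) a * a + b * b <= r * r)
  nr <- nrow(px); nc <- ncol(px)
  morph <- function(m, f) {
    out <- m
    for (i in 1:nr) for (j in 1:nc) {
      ii <- pmax(pmin(i + off, nr), 1); jj <- pmax(pmin(j + off, nc), 1)
      w <- m[ii, jj]
      # replicate-pad edges by clamping indices, mark out-of-disk as NA
      w[!in_disk] <- NA
      out[i, j] <- f(w, na.rm = TRUE)
    }
    out
  }
  opened <- morph(morph(px, min), max)
  sub <- pmax(px - opened, 0)
  med <- sub
  for (i in 1:nr) for (j in 1:nc) {
    ii <- pmax(pmin(i + (-mr:mr), nr), 1); jj <- pmax(pmin(j + (-mr:mr), nc), 1)
    med[i, j] <- stats::median(sub[ii, jj])
  }
  # interior comparison (boundary handling differs by padding convention);
  # tolerance covers the 16-bit quantisation of the fast median filter
  int <- (r + mr + 1):(nr - r - mr)
  expect_equal(out$pixels[int, int], med[int, int], tolerance = 0.01)
})

test_that("preprocessing rejects oversized radii", {
  img <- channel_image(matrix(1, 30, 30), 0.5, "nuclei")
  expect_error(preprocess_nuclei(img, 40, 2), "exceeds")
  expect_error(preprocess_nuclei(img, 0, 2), ">= 1")
})

test_that("identical images register to the identity", {
  cfg <- simulation_config(image_size_px = c(256L, 256L), n_cells = 60L,
                           cell_radius_um = c(2, 4), n_plaques = 0L, seed = 5)
  fx <- preprocess_nuclei(generate_case(cfg)$images$nuclei, 20, 2)
  t <- estimate_affine(fx, fx, seed = 1)
  m <- unclass(t)
  expect_lt(max(abs(m[, 1:2] - diag(2))), 1e-3)
  expect_lt(max(abs(m[, 3])), 0.01)
})

test_that("known translations and rotations are recovered to sub-pixel accuracy", {
  cfg <- simulation_config(image_size_px = c(384L, 384L), n_cells = 100L,
                           cell_radius_um = c(2, 4), n_plaques = 0L, seed = 6)
  # translation (10, -4)
  tr <- make_affine(tx = 10, ty = -4)
  pair <- generate_registration_pair(cfg, tr)
  est <- estimate_affine(preprocess_nuclei(pair$fixed, 20, 2),
                         preprocess_nuclei(pair$moving, 20, 2), seed = 1)
  expect_lt(max(abs(unclass(est)[, 3] - c(10, -4))), 0.5)

  # rotation + translation: corner displacement of est o truth^-1 under 1 px
  tr2 <- make_affine(rotation_deg = 5, tx = 6, ty = -9, center = c(191.5, 191.5))
  pair2 <- generate_registration_pair(cfg, tr2)
  est2 <- estimate_affine(preprocess_nuclei(pair2$fixed, 20, 2),
                          preprocess_nuclei(pair2$moving, 20, 2), seed = 1)
  comp <- affine_compose(est2, affine_invert(tr2))
  corners <- rbind(c(0, 0), c(0, 383), c(383, 0), c(383, 383))
  disp <- sqrt(rowSums((affine_apply_points(comp, corners) - corners)^2))
  expect_lt(max(disp), 1)
})

test_that("registration is deterministic for a fixed seed", {
  cfg <- simulation_config(image_size_px = c(256L, 256L), n_cells = 70L,
                           cell_radius_um = c(2, 4), n_plaques = 0L, seed = 7)
  pair <- generate_registration_pair(cfg, make_affine(rotation_deg = -4, tx = 12, ty = 3,
                                                      center = c(127.5, 127.5)))
  fx <- preprocess_nuclei(pair$fixed, 20, 2)
  mv <- preprocess_nuclei(pair$moving, 20, 2)
  e1 <- estimate_affine(fx, mv, seed = 99)
  e2 <- estimate_affine(fx, mv, seed = 99)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
})

test_that("the matched-keypoint residual strictly decreases after registration", {
  cfg <- simulation_config(image_size_px = c(256L, 256L), n_cells = 70L,
                           cell_radius_um = c(2, 4), n_plaques = 0L, seed = 8)
  pair <- generate_registration_pair(cfg, make_affine(tx = 15, ty = -8))
  fx <- preprocess_nuclei(pair$fixed, 20, 2)
  mv <- preprocess_nuclei(pair$moving, 20, 2)
  t <- estimate_affine(fx, mv, seed = 1)
  res <- registration_residual(fx, mv, t)
  expect_lt(res[["after"]], res[["before"]])
})

test_that("too few landmarks is a registration failure with diagnostics", {
  blank <- channel_image(matrix(0, 64, 64), 0.5, "nuclei")
  expect_error(estimate_affine(blank, blank, seed = 1), "too few keypoints")
})

test_that("apply_transform shifts exactly, round-trips, and preserves mask binarity", {
  case <- generate_case(small_case_config(seed = 9, n_cells = 20, noise_sd = 0))
  img <- case$images$iba1
  # identity leaves images untouched
  same <- apply_transform(affine_identity(), img)
  expect_identical(same$pixels, img$pixels)
  # integer translation: bilinear degenerates to an exact copy.
  # The transform maps moving->fixed; resampling into the fixed frame places
  # moving pixel p at position t(p).
  t <- make_affine(tx = 7, ty = 3)
  sh <- apply_transform(t, img)
  expect_identical(sh$pixels[8:256, 4:256], img$pixels[1:249, 1:253])
  expect_true(all(sh$pixels[1:7, ] == 0))
  # round-trip on a smooth image is bounded by interpolation error
  smooth <- channel_image(EBImage::gblur(img$pixels, 3) + 1, 0.5, "smooth")
  t2 <- make_affine(rotation_deg = 3, tx = 2.3, ty = -1.7, center = c(127.5, 127.5))
  fwd <- apply_transform(t2, smooth)
  back <- apply_transform(affine_invert(t2), fwd)
  int <- 40:216
  d2r <- diff(smooth$pixels, differences = 2)
  d2c <- t(diff(t(smooth$pixels), differences = 2))
  bound <- 2 * (1 / 8) * max(abs(d2r), abs(d2c)) * 4  # two passes, safety factor
  expect_lt(max(abs(back$pixels[int, int] - smooth$pixels[int, int])), bound)
  # nearest-neighbour keeps masks binary
  mask_img <- channel_image((img$pixels > 50) * 1, 0.5, "mask")
  warped <- apply_transform(t2, mask_img, interpolation = "nearest")
  expect_true(all(warped$pixels %in% c(0, 1)))
})
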