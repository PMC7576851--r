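#' Affine transform between image coordinate frames
#'
#' A 2x3 matrix `[A | t]` mapping 0-based moving `(row, col)` pixel
#' coordinates to fixed coordinates: `q = A %*% p + t`. The linear part must
#' be invertible.
#'
#' @param m 2x3 numeric matrix.
#' @return An `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- unname(as.matrix(m))
  if (!identical(dim(m), c(2L, 3L)) || !is.numeric(m) || anyNA(m)) {
    stop_histoflow("an affine transform is a 2 x 3 numeric matrix")
  }
  if (abs(det(m[, 1:2])) <= 1e-12) {
    stop_histoflow("affine transform is not invertible (|det| <= 1e-12)")
  }
  structure(m, class = c("affine_transform", "matrix"))
}

as_affine_transform <- function(x) {
  if (inherits(x, "affine_transform")) x else affine_transform(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> (row, col) moving -> fixed\n")
  print(unclass(x))
  if (!is.null(attr(x, "n_inliers"))) {
    cat(sprintf("  estimated from %d inliers of %d matches, rms residual %.3f px\n",
                attr(x, "n_inliers"), attr(x, "n_matches"), attr(x, "rms_px")))
  }
  invisible(x)
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' Build an affine from rotation, translation and scale
#'
#' @param rotation_deg Rotation in degrees (about `center`).
#' @param tx,ty Translation in pixels along row and col.
#' @param center Length-2 rotation centre `(row, col)`, 0-based.
#' @param scale Isotropic scale factor.
#' @return An [affine_transform()].
#' @export
make_affine <- function(rotation_deg = 0, tx = 0, ty = 0, center = c(0, 0), scale = 1) {
  th <- rotation_deg * pi / 180
  rot <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  off <- c(tx, ty) + center - rot %*% center
  affine_transform(cbind(rot, off))
}

#' Apply an affine transform to point coordinates
#' @param t An [affine_transform()].
#' @param pts n x 2 matrix of 0-based `(row, col)` points.
#' @return n x 2 matrix of transformed points.
#' @export
affine_apply_points <- function(t, pts) {
  t <- as_affine_transform(t)
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(unclass(t)[, 1:2]), 2, unclass(t)[, 3], `+`)
}

#' Invert / compose affine transforms
#' @param t,a,b [affine_transform()]s.
#' @export
affine_invert <- function(t) {
  t <- unclass(as_affine_transform(t))
  ai <- solve(t[, 1:2])
  affine_transform(cbind(ai, -ai %*% t[, 3]))
}

#' @rdname affine_invert
#' @return `affine_compose(a, b)` is the transform applying `b` first, then
#'   `a`.
#' @export
affine_compose <- function(a, b) {
  a <- unclass(as_affine_transform(a)); b <- unclass(as_affine_transform(b))
  affine_transform(cbind(a[, 1:2] %*% b[, 1:2], a[, 1:2] %*% b[, 3] + a[, 3]))
}

# Pull-back resampling: out(p) = img(t(p)) for every output pixel p,
# bilinear or nearest-neighbour, out-of-frame filled with `fill`.
warp_image <- function(image, t, fill = 0, interpolation = c("bilinear", "nearest"),
                       output_dim = NULL) {
  stopifnot(inherits(image, "channel_image"))
  interpolation <- match.arg(interpolation)
  t <- unclass(as_affine_transform(t))
  px <- image$pixels
  if (is.null(output_dim)) output_dim <- dim(px)
  nr <- output_dim[1]; nc <- output_dim[2]
  # 0-based output grid
  rows <- rep(seq_len(nr) - 1, times = nc)
  cols <- rep(seq_len(nc) - 1, each = nr)
  src_r <- t[1, 1] * rows + t[1, 2] * cols + t[1, 3]
  src_c <- t[2, 1] * rows + t[2, 2] * cols + t[2, 3]
  out <- rep(as.numeric(fill), nr * nc)
  if (interpolation == "nearest") {
    ir <- round(src_r); ic <- round(src_c)
    ok <- ir >= 0 & ir <= nrow(px) - 1 & ic >= 0 & ic <= ncol(px) - 1
    out[ok] <- px[cbind(ir[ok] + 1, ic[ok] + 1)]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    ok <- r0 >= 0 & r0 <= nrow(px) - 2 | (r0 == nrow(px) - 1 & fr == 0)
    ok <- ok & (c0 >= 0 & c0 <= ncol(px) - 2 | (c0 == ncol(px) - 1 & fc == 0))
    ok <- ok & r0 >= 0 & c0 >= 0
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    r1k <- pmin(r0k + 1, nrow(px) - 1); c1k <- pmin(c0k + 1, ncol(px) - 1)
    v00 <- px[cbind(r0k + 1, c0k + 1)]; v10 <- px[cbind(r1k + 1, c0k + 1)]
    v01 <- px[cbind(r0k + 1, c1k + 1)]; v11 <- px[cbind(r1k + 1, c1k + 1)]
    out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  channel_image(matrix(out, nr, nc), image$pixel_size_um, image$channel_label)
}

#' Preprocess a nuclei channel for registration
#'
#' Rolling-ball background subtraction (grey-scale opening with a disk
#' structuring element of the given radius, subtracted and clipped at zero)
#' followed by a median filter --- the standard smoothing applied to
#' Hoechst-stained nuclei images before landmark extraction.
#'
#' @param image Nuclei [channel_image()].
#' @param rolling_radius_px Rolling-ball radius in pixels.
#' @param median_radius_px Median-filter radius in pixels (window
#'   `2r+1` x `2r+1`).
#' @return Preprocessed [channel_image()] (nonnegative).
#' @export
preprocess_nuclei <- function(image, rolling_radius_px = 50L, median_radius_px = 5L) {
  stopifnot(inherits(image, "channel_image"))
  if (rolling_radius_px < 1L || median_radius_px < 1L) {
    stop_histoflow("filter radii must be >= 1 pixel")
  }
  if (2L * rolling_radius_px + 1L > min(dim(image$pixels)) ||
      2L * median_radius_px + 1L > min(dim(image$pixels))) {
    stop_histoflow("filter radius exceeds image size")
  }
  px <- image$pixels
  mx0 <- max(px)
  # EBImage grey-scale morphology operates on [0, 1]; rescale around it
  bg <- if (mx0 > 0) {
    EBImage::opening(px / mx0, disk_brush(rolling_radius_px)) * mx0
  } else {
    px
  }
  sub <- pmax(px - bg, 0)
  mx <- max(sub)
  if (mx > 0) {
    # EBImage's constant-time median filter works on [0, 1]; rescale around it
    sub <- EBImage::medianFilter(sub / mx, median_radius_px) * mx
  }
  channel_image(pmax(matrix(as.numeric(sub), nrow(px), ncol(px)), 0),
                image$pixel_size_um, image$channel_label)
}

#' Detect nuclei landmark keypoints
#'
#' Thresholds the (preprocessed) nuclei image, labels 8-connected blobs and
#' returns their intensity-weighted centroids --- the intrinsic landmarks
#' used to register sequential staining rounds.
#'
#' @param image Preprocessed nuclei [channel_image()].
#' @param threshold Absolute intensity threshold; default
#'   `median + 0.2 * (max - median)`.
#' @param min_area_px Minimum blob area kept.
#' @return n x 2 matrix of 0-based `(row, col)` keypoint coordinates.
#' @export
detect_keypoints <- function(image, threshold = NULL, min_area_px = 4L) {
  stopifnot(inherits(image, "channel_image"))
  px <- image$pixels
  if (is.null(threshold)) {
    med <- stats::median(px)
    threshold <- med + 0.2 * (max(px) - med)
  }
  mask <- binary_mask(px > threshold, image$pixel_size_um, "nuclei")
  cells <- label_cells(mask, min_area_um2 = min_area_px * image$pixel_size_um^2)
  k <- n_cells(cells)
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  idx <- which(cells$labels > 0L)
  l <- cells$labels[idx]
  w <- px[idx]
  rows <- (idx - 1L) %% nrow(px)
  cols <- (idx - 1L) %/% nrow(px)
  wsum <- as.numeric(tapply(w, l, sum))
  cbind(as.numeric(tapply(w * rows, l, sum)) / wsum,
        as.numeric(tapply(w * cols, l, sum)) / wsum)
}

# Rotation/translation-invariant descriptor: sorted distances to the k
# nearest neighbouring keypoints.
keypoint_descriptors <- function(pts, k = 8L) {
  n <- nrow(pts)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pts))
  t(vapply(seq_len(n), function(i) sort(d[i, -i])[seq_len(k)], numeric(k)))
}

fit_affine_ls <- function(src, dst) {
  # least squares q = A p + t over matched pairs
  X <- cbind(src, 1)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, dst)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  m <- cbind(t(beta[1:2, ]), beta[3, ])
  if (abs(det(m[, 1:2])) <= 1e-12) return(NULL)
  m
}

#' Estimate the affine transform between two staining rounds
#'
#' Feature-based affine registration on nuclei landmarks: blob keypoints are
#' detected on both (preprocessed) images, described by their sorted
#' distances to the `n_neighbors` nearest keypoints (rotation- and
#' translation-invariant), matched by nearest-descriptor with a ratio test
#' and mutual cross-check, and the affine is fitted by RANSAC with a fixed
#' seed followed by least-squares refinement and one guided re-matching
#' pass. Returns the moving-to-fixed transform with `n_inliers`,
#' `n_matches` and `rms_px` attributes.
#'
#' @param fixed,moving Preprocessed nuclei [channel_image()]s with the same
#'   pixel size.
#' @param seed Integer seed for the RANSAC draws (fixed seed gives an
#'   identical matrix across runs).
#' @param ratio Descriptor ratio-test threshold.
#' @param ransac_tol_px RANSAC inlier reprojection tolerance in pixels.
#' @param max_iter RANSAC iterations.
#' @param n_neighbors Neighbours per keypoint descriptor.
#' @param model `"affine"` (6 dof) or `"similarity"` (4 dof fallback for
#'   degenerate keypoint geometry).
#' @param keypoint_threshold Passed to [detect_keypoints()].
#' @return An [affine_transform()].
#' @export
estimate_affine <- function(fixed, moving, seed = 1L, ratio = 0.75,
                            ransac_tol_px = 3, max_iter = 1000L,
                            n_neighbors = 8L,
                            model = c("affine", "similarity"),
                            keypoint_threshold = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(fixed, "channel_image"), inherits(moving, "channel_image"))
  if (abs(fixed$pixel_size_um - moving$pixel_size_um) > 1e-12) {
    stop_histoflow("fixed and moving images must share a pixel size")
  }
  kf <- detect_keypoints(fixed, threshold = keypoint_threshold)
  km <- detect_keypoints(moving, threshold = keypoint_threshold)
  if (nrow(kf) < 3L || nrow(km) < 3L) {
    stop_histoflow(sprintf(
      "registration failure: too few keypoints (fixed %d, moving %d)",
      nrow(kf), nrow(km)
    ))
  }
  df <- keypoint_descriptors(kf, n_neighbors)
  dm <- keypoint_descriptors(km, n_neighbors)
  kd <- min(ncol(df), ncol(dm))
  df <- df[, seq_len(kd), drop = FALSE]; dm <- dm[, seq_len(kd), drop = FALSE]
  # descriptor distances moving -> fixed
  dd <- outer(rowSums(dm^2), rowSums(df^2), `+`) - 2 * dm %*% t(df)
  dd[dd < 0] <- 0
  best <- apply(dd, 1, which.min)
  bestd <- sqrt(dd[cbind(seq_len(nrow(dd)), best)])
  second <- apply(dd, 1, function(r) sort(r)[2])
  pass_ratio <- bestd <= ratio * sqrt(second)
  # mutual cross-check
  back <- apply(dd, 2, which.min)
  mutual <- back[best] == seq_len(nrow(dd))
  sel <- which(pass_ratio & mutual)
  if (length(sel) < 3L) {
    stop_histoflow(sprintf(
      "registration failure: %d candidate matches after ratio test (need >= 3; %d keypoints fixed, %d moving)",
      length(sel), nrow(kf), nrow(km)
    ))
  }
  src <- km[sel, , drop = FALSE]
  dst <- kf[best[sel], , drop = FALSE]
  n <- nrow(src)

  fit3 <- function(i) {
    if (model == "similarity") fit_similarity(src[i, ], dst[i, ]) else {
      s <- cbind(src[i, ], 1)
      if (abs(det(s)) < 1e-9) return(NULL)
      beta <- solve(s, dst[i, ])
      m <- cbind(t(beta[1:2, ]), beta[3, ])
      if (abs(det(m[, 1:2])) <= 1e-12) return(NULL)
      m
    }
  }
  residuals <- function(m) {
    pred <- sweep(src %*% t(m[, 1:2]), 2, m[, 3], `+`)
    sqrt(rowSums((pred - dst)^2))
  }
  best_m <- NULL; best_inl <- 0L
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      i <- sample.int(n, 3L)
      m <- fit3(i)
      if (is.null(m)) next
      inl <- sum(residuals(m) <= ransac_tol_px)
      if (inl > best_inl) {
        best_inl <- inl; best_m <- m
        if (inl == n) break
      }
    }
  })
  if (is.null(best_m) || best_inl < 3L) {
    stop_histoflow(sprintf(
      "registration failure: RANSAC found %d inliers of %d matches (need >= 3)",
      best_inl, n
    ))
  }
  inl <- residuals(best_m) <= ransac_tol_px
  m <- fit_affine_ls(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  if (is.null(m)) m <- best_m
  # guided re-match: transform every moving keypoint, pair with the nearest
  # fixed keypoint within tolerance, refit on the enlarged consensus set
  for (pass in 1:2) {
    pred <- sweep(km %*% t(m[, 1:2]), 2, m[, 3], `+`)
    d2 <- outer(rowSums(pred^2), rowSums(kf^2), `+`) - 2 * pred %*% t(kf)
    nn <- apply(d2, 1, which.min)
    nnd <- sqrt(pmax(d2[cbind(seq_len(nrow(km)), nn)], 0))
    ok <- nnd <= ransac_tol_px
    if (sum(ok) >= 3L) {
      m2 <- fit_affine_ls(km[ok, , drop = FALSE], kf[nn[ok], , drop = FALSE])
      if (!is.null(m2)) m <- m2
    }
  }
  pred <- sweep(km %*% t(m[, 1:2]), 2, m[, 3], `+`)
  d2 <- outer(rowSums(pred^2), rowSums(kf^2), `+`) - 2 * pred %*% t(kf)
  nnd <- sqrt(pmax(apply(d2, 1, min), 0))
  final_inl <- sum(nnd <= ransac_tol_px)
  out <- affine_transform(m)
  attr(out, "n_inliers") <- final_inl
  attr(out, "n_matches") <- n
  attr(out, "rms_px") <- sqrt(mean(nnd[nnd <= ransac_tol_px]^2))
  out
}

fit_similarity <- function(src, dst) {
  # 4-dof (scale, rotation, translation) via Umeyama/Procrustes
  ms <- colMeans(src); md <- colMeans(dst)
  sc <- sweep(src, 2, ms); dc <- sweep(dst, 2, md)
  S <- t(dc) %*% sc
  sv <- svd(S)
  R <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  s <- sum(diag(t(R) %*% S)) / sum(sc^2)
  if (!is.finite(s) || s <= 0) return(NULL)
  cbind(s * R, md - s * R %*% ms)
}

#' Apply one transform to every channel of a staining round
#'
#' Resamples each image into the fixed frame with the identical matrix,
#' bilinear interpolation for intensity channels (or nearest-neighbour for
#' masks, which must stay binary) and zero fill outside the frame.
#'
#' @param t Moving-to-fixed [affine_transform()].
#' @param images A [channel_image()] or list of them.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return List of transformed [channel_image()]s (or a single image if a
#'   single image was given).
#' @export
apply_transform <- function(t, images, interpolation = "bilinear") {
  t <- as_affine_transform(t)
  single <- inherits(images, "channel_image")
  if (single) images <- list(images)
  inv <- affine_invert(t)
  out <- lapply(images, warp_image, t = inv, fill = 0, interpolation = interpolation)
  if (single) out[[1]] else out
}

#' Mean matched-keypoint distance before and after a transform
#'
#' Diagnostic registration residual: for each moving keypoint, the distance
#' to its nearest fixed keypoint, before and after applying the transform.
#'
#' @param fixed,moving Preprocessed nuclei [channel_image()]s.
#' @param t Moving-to-fixed [affine_transform()].
#' @return Named numeric vector `c(before, after)` of mean distances in px.
#' @export
registration_residual <- function(fixed, moving, t) {
  kf <- detect_keypoints(fixed)
  km <- detect_keypoints(moving)
  nnmean <- function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(kf^2), `+`) - 2 * pts %*% t(kf)
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  c(before = nnmean(km), after = nnmean(affine_apply_points(t, km)))
}
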