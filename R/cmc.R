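#' Camera-motion-compensation parameters
#'
#' Controls the per-frame background-motion pipeline: horizon detection,
#' static-region masking, FAST/BRIEF keypoint matching and RANSAC affine
#' estimation, and how the estimate is applied to Kalman states.
#'
#' @param fast_threshold FAST corner intensity threshold (grey levels).
#' @param max_keypoints Keypoints retained per frame (strongest first).
#' @param lowe_ratio 2-NN descriptor-distance ratio filter.
#' @param max_shift_frac Spatial match filter: pairs farther apart than
#'   this fraction of the frame diagonal are discarded.
#' @param ransac_threshold Inlier reprojection threshold, pixels.
#' @param ransac_conf Target confidence of the RANSAC loop.
#' @param ransac_max_iter Maximum RANSAC iterations.
#' @param min_pairs Minimum matched pairs before estimation is attempted;
#'   below it the identity fallback is returned.
#' @param mask_margin Detection boxes are dilated by this fraction of
#'   their size before masking.
#' @param mask_above_horizon Mask out rows strictly above the detected
#'   horizon (sky / far terrain excluded from keypoints).
#' @param apply `"position_only"` (default) transforms positions and
#'   velocities by the affine's 2x2 block and leaves the box shape
#'   `(gamma, h)` untouched: axis-aligned boxes do not change shape
#'   under camera roll, and because gamma is unitless while h is in
#'   pixels, rotating the pair corrupts the aspect ratio by
#'   `sin(theta) * h` — enough to throw correct matches past the
#'   association gate at a degree of roll. `"full"` applies the
#'   rotation to every state pair (the literal block-diagonal
#'   extension), kept for comparison.
#' @param add_qn Add process noise again at compensation time (the
#'   module's stated covariance update; disable to compensate covariance
#'   by the similarity transform alone).
#' @return A list of class `cmc_params`.
#' @export
cmc_params <- function(fast_threshold = 20, max_keypoints = 500,
                       lowe_ratio = 0.75, max_shift_frac = 0.10,
                       ransac_threshold = 3, ransac_conf = 0.995,
                       ransac_max_iter = 500, min_pairs = 8,
                       mask_margin = 0.1, mask_above_horizon = TRUE,
                       apply = c("position_only", "full"),
                       add_qn = TRUE) {
  apply <- match.arg(apply)
  structure(as.list(environment()), class = "cmc_params")
}

#' Convert an RGB array to a grey-level matrix
#'
#' ITU-R BT.601 luma weights; input values in `[0, 1]` (as read by
#' [png::readPNG()]) are rescaled to `[0, 255]`.
#'
#' @param img Matrix (already grey) or H x W x 3(4) array.
#' @return Numeric matrix, values in `[0, 255]`.
#' @export
as_gray_frame <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (length(dim(img)) == 3) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    stop("unsupported image format", call. = FALSE)
  }
  if (max(g) <= 1) g <- g * 255
  g
}

#' Detect the horizon row of a frame
#'
#' The horizon is taken as the image row with the highest mean absolute
#' vertical gradient: `argmax_y (1/W) sum_x |G_y(x, y)|`, with `G_y`
#' computed by central differences (one-sided at the first and last
#' rows). Ties are broken towards the smallest row index.
#'
#' @param frame Grey-level matrix (rows = y).
#' @return 1-based row index of the horizon.
#' @export
detect_horizon <- function(frame) {
  h <- nrow(frame)
  if (h < 2 || ncol(frame) < 2) stop("frame too small", call. = FALSE)
  gy <- matrix(0, h, ncol(frame))
  if (h > 2) gy[2:(h - 1), ] <- (frame[3:h, ] - frame[1:(h - 2), ]) / 2
  gy[1, ] <- frame[2, ] - frame[1, ]
  gy[h, ] <- frame[h, ] - frame[h - 1, ]
  which.max(rowMeans(abs(gy)))
}

#' Build the static-background keypoint mask
#'
#' TRUE marks pixels usable for background keypoints. Every detection box
#' (a moving target) is dilated by `margin` of its size and masked out;
#' rows strictly above the horizon are masked out too, so only stable
#' below-horizon ground texture anchors the motion estimate.
#'
#' @param shape `c(height, width)` of the frame.
#' @param boxes Matrix/data frame of detection boxes
#'   `(left, top, width, height)` in 0-based pixel coordinates, or NULL.
#' @param horizon 1-based horizon row (1 = nothing masked above).
#' @param margin Fractional box dilation. Default 0.1.
#' @param mask_above_horizon Mask rows above the horizon.
#' @return Logical matrix of the frame shape.
#' @export
build_static_mask <- function(shape, boxes = NULL, horizon = 1,
                              margin = 0.1, mask_above_horizon = TRUE) {
  m <- matrix(TRUE, shape[1], shape[2])
  if (mask_above_horizon && horizon > 1) m[seq_len(horizon - 1), ] <- FALSE
  if (!is.null(boxes) && NROW(boxes) > 0) {
    boxes <- as.matrix(boxes[, 1:4, drop = FALSE])
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      dx <- b[3] * margin
      dy <- b[4] * margin
      x0 <- max(1, floor(b[1] - dx) + 1)
      x1 <- min(shape[2], ceiling(b[1] + b[3] + dx))
      y0 <- max(1, floor(b[2] - dy) + 1)
      y1 <- min(shape[1], ceiling(b[2] + b[4] + dy))
      if (x0 <= x1 && y0 <= y1) m[y0:y1, x0:x1] <- FALSE
    }
  }
  m
}

#' Match background keypoints between two frames
#'
#' FAST-9 corners restricted to the static masks, BRIEF-256 descriptors
#' on a box-smoothed image, 2-nearest-neighbour Hamming matching with
#' Lowe's ratio test, and a spatial filter dropping pairs that moved more
#' than `max_shift_frac` of the frame diagonal.
#'
#' @param prev,curr Grey-level matrices of equal shape.
#' @param prev_mask,curr_mask Logical masks ([build_static_mask()]);
#'   NULL = everything usable.
#' @param params [cmc_params()].
#' @return Numeric matrix with columns `x1, y1, x2, y2` (0-based pixel
#'   coordinates), zero rows if nothing matched.
#' @export
match_keypoints <- function(prev, curr, prev_mask = NULL, curr_mask = NULL,
                            params = cmc_params()) {
  if (!all(dim(prev) == dim(curr))) stop("frames must have equal shape",
                                         call. = FALSE)
  empty <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  if (is.null(prev_mask)) prev_mask <- matrix(TRUE, nrow(prev), ncol(prev))
  if (is.null(curr_mask)) curr_mask <- matrix(TRUE, nrow(curr), ncol(curr))
  k1 <- fast_corners_cpp(prev, prev_mask, params$fast_threshold,
                         params$max_keypoints)
  k2 <- fast_corners_cpp(curr, curr_mask, params$fast_threshold,
                         params$max_keypoints)
  if (nrow(k1) == 0 || nrow(k2) == 0) return(empty)
  b1 <- brief_descriptors_cpp(box_blur5_cpp(prev), k1)
  b2 <- brief_descriptors_cpp(box_blur5_cpp(curr), k2)
  if (nrow(b1$points) == 0 || nrow(b2$points) == 0) return(empty)
  mm <- match_knn_cpp(b1$descriptors, b2$descriptors, params$lowe_ratio)
  if (nrow(mm) == 0) return(empty)
  p1 <- b1$points[mm[, 1], , drop = FALSE]
  p2 <- b2$points[mm[, 2], , drop = FALSE]
  shift <- sqrt(rowSums((p2 - p1)^2))
  max_shift <- params$max_shift_frac * sqrt(sum(dim(prev)^2))
  keep <- shift <= max_shift
  out <- cbind(p1, p2)[keep, , drop = FALSE]
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Construct an affine background-motion estimate
#'
#' @param M 2x2 rotation/scale block.
#' @param T_ 2-vector translation, pixels.
#' @param inlier_count Supporting keypoint pairs.
#' @param source `"estimated"` or `"identity_fallback"`.
#' @return A list of class `affine_motion`.
#' @export
affine_motion <- function(M = diag(2), T_ = c(0, 0), inlier_count = 0L,
                          source = "estimated") {
  structure(list(M = M, T = as.numeric(T_),
                 inlier_count = as.integer(inlier_count), source = source),
            class = "affine_motion")
}

#' @rdname affine_motion
#' @export
identity_affine <- function() affine_motion(source = "identity_fallback")

#' Extend an affine to the 8-dimensional state space
#'
#' `M_ext = diag(M, M, M, M)` applies the 2x2 block to each state pair;
#' `T_ext = (T, 0, ..., 0)` translates positions only. With
#' `apply = "position_only"` the `(gamma, h)` and `(vgamma, vh)` blocks
#' stay identity.
#'
#' @param motion An [affine_motion()].
#' @param apply `"full"` or `"position_only"`.
#' @return List with `M_ext` (8x8) and `T_ext` (length 8).
#' @export
affine_extend <- function(motion, apply = "full") {
  m8 <- diag(8)
  blocks <- if (apply == "full") list(1:2, 3:4, 5:6, 7:8) else list(1:2, 5:6)
  for (b in blocks) m8[b, b] <- motion$M
  list(M_ext = m8, T_ext = c(motion$T, rep(0, 6)))
}

#' @rdname affine_motion
#' @param a,b Two [affine_motion()] estimates; `compose_affine(b, a)` is
#'   the motion "a then b".
#' @export
compose_affine <- function(b, a) {
  affine_motion(b$M %*% a$M, as.numeric(b$M %*% a$T) + b$T,
                min(a$inlier_count, b$inlier_count),
                if (a$source == "estimated" && b$source == "estimated")
                  "estimated" else a$source)
}

#' @rdname affine_motion
#' @export
invert_affine <- function(a) {
  mi <- solve(a$M)
  affine_motion(mi, -as.numeric(mi %*% a$T), a$inlier_count, a$source)
}

#' @rdname affine_motion
#' @param points n x 2 matrix of `(x, y)` points.
#' @export
apply_affine <- function(a, points) {
  points <- matrix(points, ncol = 2)
  t(a$M %*% t(points) + a$T)
}

# exact affine through 3 point pairs; NULL if degenerate
affine_from_3 <- function(p1, p2) {
  A <- cbind(p1, 1)
  qr_A <- qr(A)
  if (qr_A$rank < 3) return(NULL)
  coef <- qr.coef(qr_A, p2)          # 3 x 2: rows (a, b, t) per output dim
  affine_motion(t(coef[1:2, ]), coef[3, ])
}

affine_lsq <- function(p1, p2) {
  A <- cbind(p1, 1)
  coef <- qr.coef(qr(A), p2)
  affine_motion(t(coef[1:2, ]), coef[3, ])
}

#' Estimate the background affine from matched point pairs by RANSAC
#'
#' Repeated 3-point minimal fits; the hypothesis with the largest inlier
#' consensus (reprojection error below `ransac_threshold`) is refined by
#' least squares over its inliers. With fewer than `min_pairs` matches,
#' a degenerate configuration, or a reflecting estimate
#' (`det(M) <= 0`), the identity fallback is returned so tracking
#' degrades gracefully instead of failing.
#'
#' @param pairs Matrix with columns `x1, y1, x2, y2` from
#'   [match_keypoints()] (or any correspondence source).
#' @param params [cmc_params()].
#' @return An [affine_motion()].
#' @export
estimate_affine <- function(pairs, params = cmc_params()) {
  if (is.null(pairs) || nrow(pairs) < max(3, params$min_pairs)) {
    return(identity_affine())
  }
  p1 <- as.matrix(pairs[, 1:2, drop = FALSE])
  p2 <- as.matrix(pairs[, 3:4, drop = FALSE])
  n <- nrow(p1)
  thr2 <- params$ransac_threshold^2
  best_inl <- NULL
  best_count <- 0L
  max_iter <- params$ransac_max_iter
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    idx <- sample.int(n, 3)
    cand <- affine_from_3(p1[idx, , drop = FALSE], p2[idx, , drop = FALSE])
    if (is.null(cand)) next
    resid <- apply_affine(cand, p1) - p2
    inl <- rowSums(resid^2) < thr2
    cnt <- sum(inl)
    if (cnt > best_count) {
      best_count <- cnt
      best_inl <- inl
      # adaptive iteration bound from current inlier ratio
      w <- cnt / n
      if (w > 0 && w < 1) {
        need <- log(1 - params$ransac_conf) / log(1 - w^3)
        max_iter <- min(params$ransac_max_iter, ceiling(need))
      } else if (w >= 1) break
    }
  }
  if (is.null(best_inl) || best_count < 3) return(identity_affine())
  fit <- affine_lsq(p1[best_inl, , drop = FALSE], p2[best_inl, , drop = FALSE])
  if (!all(is.finite(fit$M)) || !all(is.finite(fit$T)) || det(fit$M) <= 0) {
    return(identity_affine())
  }
  fit$inlier_count <- best_count
  fit
}

#' Compensate a predicted Kalman state for camera motion
#'
#' Warps the predicted (prior) state and covariance by the estimated
#' background affine: `mean' = M_ext mean + T_ext`,
#' `P' = M_ext P M_ext^T + Qn`. With the identity motion and `Qn = 0` the
#' state is unchanged.
#'
#' @param state A predicted track state.
#' @param motion An [affine_motion()].
#' @param qn 8x8 process-noise matrix added at compensation time, or NULL
#'   for none.
#' @param apply `"full"` or `"position_only"`; see [cmc_params()].
#' @return The compensated track state.
#' @export
compensate_track <- function(state, motion, qn = NULL, apply = "full") {
  ext <- affine_extend(motion, apply)
  mean_c <- as.numeric(ext$M_ext %*% state$mean + ext$T_ext)
  cov_c <- ext$M_ext %*% state$cov %*% t(ext$M_ext)
  if (!is.null(qn)) cov_c <- cov_c + qn
  new_track_state(mean_c, cov_c)
}

#' Full camera-motion estimate between two frames
#'
#' Runs the whole pipeline: horizon detection on each frame, static
#' masking of the frame's own detections, keypoint matching, RANSAC.
#'
#' @param prev,curr Grey-level matrices.
#' @param prev_boxes,curr_boxes Detection boxes per frame (masked out).
#' @param params [cmc_params()].
#' @return An [affine_motion()].
#' @export
estimate_cmc <- function(prev, curr, prev_boxes = NULL, curr_boxes = NULL,
                         params = cmc_params()) {
  shape <- dim(prev)
  hp <- if (params$mask_above_horizon) detect_horizon(prev) else 1
  hc <- if (params$mask_above_horizon) detect_horizon(curr) else 1
  mp <- build_static_mask(shape, prev_boxes, hp, params$mask_margin,
                          params$mask_above_horizon)
  mc <- build_static_mask(shape, curr_boxes, hc, params$mask_margin,
                          params$mask_above_horizon)
  pairs <- match_keypoints(prev, curr, mp, mc, params)
  estimate_affine(pairs, params)
}
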