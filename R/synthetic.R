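#' Configuration of a synthetic UAV tracking scenario
#'
#' The generator emulates the structure of drone footage of a herd of
#' ungulates: smoothly curving correlated-random-walk trajectories on
#' the ground plane, global frame-to-frame camera motion (translation,
#' rotation and zoom jitter about the frame centre), scheduled occlusion
#' episodes that depress detection confidence, per-identity appearance
#' descriptors with noise, and optionally rendered grey-level frames
#' with a textured ground plane below a horizon.
#'
#' Rates are per frame; lengths are pixels.
#'
#' @param n_targets Number of targets.
#' @param n_frames Sequence length (>= 2).
#' @param frame_size `c(width, height)` in pixels.
#' @param speed_range Per-target ground speed range, px/frame.
#' @param turn_sd Std of the per-frame heading change, rad.
#' @param target_height Range of box heights, px.
#' @param target_aspect Range of box aspect ratios (w/h).
#' @param cam_trans_sd Std of per-frame camera translation, px.
#' @param cam_rot_sd Std of per-frame camera rotation, degrees.
#' @param cam_zoom_sd Std of per-frame log zoom.
#' @param cam_drift Constant per-frame camera translation `c(dx, dy)`.
#' @param occl_rate Probability per target per frame of starting an
#'   occlusion episode.
#' @param occl_duration Episode length range, frames.
#' @param occl_conf_floor Mean detection confidence while occluded.
#' @param miss_rate Probability a target yields no detection in a frame.
#' @param jitter_sd Std of box corner/size jitter, px.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param conf_sd Std of confidence noise.
#' @param descriptor_dim Appearance descriptor dimension (>= 8).
#' @param descriptor_noise_sd Descriptor noise std (visible targets).
#' @param descriptor_occl_noise_sd Descriptor noise std while occluded
#'   (occluded crops are appearance-corrupted).
#' @param horizon_frac Horizon row as a fraction of frame height.
#' @param seed Integer seed; the generator is fully reproducible, with
#'   independent substreams per component (trajectories, camera,
#'   occlusion, detection noise, descriptors, rendering) so switching
#'   one noise source off does not perturb the others.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_targets = 8, n_frames = 60,
                            frame_size = c(320, 240),
                            speed_range = c(1, 4), turn_sd = 0.15,
                            target_height = c(16, 24),
                            target_aspect = c(1.4, 1.9),
                            cam_trans_sd = 3, cam_rot_sd = 0.8,
                            cam_zoom_sd = 0.004, cam_drift = c(0, 0),
                            occl_rate = 0.02, occl_duration = c(5, 15),
                            occl_conf_floor = 0.15,
                            miss_rate = 0.05, jitter_sd = 1,
                            fp_rate = 0.5, conf_sd = 0.05,
                            descriptor_dim = 128,
                            descriptor_noise_sd = 0.025,
                            descriptor_occl_noise_sd = 0.15,
                            horizon_frac = 0.25, seed = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  rates <- c(occl_rate, miss_rate, conf_sd)
  if (any(rates < 0) || occl_rate > 1 || miss_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (descriptor_dim < 8) stop("descriptor_dim must be >= 8", call. = FALSE)
  if (max(target_height) > frame_size[2] ||
      max(target_height) * max(target_aspect) > frame_size[1]) {
    stop("infeasible config: targets larger than the frame", call. = FALSE)
  }
  structure(mget(names(formals(scenario_config))),
            class = "scenario_config")
}

with_stream <- function(seed, offset, expr) {
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

sample_camera_affine <- function(cfg) {
  theta <- stats::rnorm(1, 0, cfg$cam_rot_sd) * pi / 180
  s <- exp(stats::rnorm(1, 0, cfg$cam_zoom_sd))
  tr <- cfg$cam_drift + stats::rnorm(2, 0, cfg$cam_trans_sd)
  ctr <- cfg$frame_size / 2
  M <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  affine_motion(M, ctr - as.numeric(M %*% ctr) + tr)
}

#' Simulate a synthetic UAV tracking scenario
#'
#' @param cfg A [scenario_config()].
#' @return Object of class `mot_scenario`: list with
#'   `gt_world` / `gt` (tibbles `frame, id, left, top, width, height` in
#'   world and camera coordinates), `affines` (per-frame frame-to-frame
#'   [affine_motion()]; entry 1 is the identity), `cum_affines`
#'   (world-to-camera chain per frame), `occluded` (tibble
#'   `frame, id, occluded`), `detections` (tibble
#'   `frame, left, top, width, height, conf, src_id, occluded`;
#'   `src_id = NA` marks a false positive), `descriptors` (tibble
#'   `frame, det_index, v1..vD`), `horizon_world` (world horizon row)
#'   and `config`.
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  W <- cfg$frame_size[1]
  H <- cfg$frame_size[2]
  nf <- cfg$n_frames
  nt <- cfg$n_targets
  horizon_px <- round(cfg$horizon_frac * H)

  # -- trajectories (world coordinates) --------------------------------
  traj <- with_stream(cfg$seed, 1L, {
    h <- stats::runif(nt, cfg$target_height[1], cfg$target_height[2])
    a <- stats::runif(nt, cfg$target_aspect[1], cfg$target_aspect[2])
    w <- h * a
    speed <- stats::runif(nt, cfg$speed_range[1], cfg$speed_range[2])
    heading <- stats::runif(nt, 0, 2 * pi)
    y_lo <- horizon_px + max(h) / 2 + 2
    x <- stats::runif(nt, 0.1 * W, 0.9 * W)
    y <- stats::runif(nt, min(y_lo + 1, 0.95 * H - 1), 0.95 * H)
    cx <- matrix(0, nf, nt)
    cy <- matrix(0, nf, nt)
    for (f in seq_len(nf)) {
      cx[f, ] <- x
      cy[f, ] <- y
      heading <- heading + stats::rnorm(nt, 0, cfg$turn_sd)
      x_new <- x + speed * cos(heading)
      y_new <- y + speed * sin(heading)
      # reflect off the walkable region (below horizon, inside frame)
      for (i in seq_len(nt)) {
        if (x_new[i] < w[i] / 2 + 1 || x_new[i] > W - w[i] / 2 - 1) {
          heading[i] <- pi - heading[i]
          x_new[i] <- x[i]
        }
        if (y_new[i] < y_lo || y_new[i] > H - h[i] / 2 - 1) {
          heading[i] <- -heading[i]
          y_new[i] <- y[i]
        }
      }
      x <- x_new
      y <- y_new
    }
    list(cx = cx, cy = cy, w = w, h = h)
  })

  # -- camera motion ---------------------------------------------------
  affines <- with_stream(cfg$seed, 2L, {
    c(list(identity_affine()),
      lapply(seq_len(nf - 1), function(f) sample_camera_affine(cfg)))
  })
  cum <- vector("list", nf)
  cum[[1]] <- identity_affine()
  for (f in 2:nf) cum[[f]] <- compose_affine(affines[[f]], cum[[f - 1]])

  # -- occlusion schedule ---------------------------------------------
  occl <- with_stream(cfg$seed, 3L, {
    m <- matrix(FALSE, nf, nt)
    for (i in seq_len(nt)) {
      left <- 0L
      for (f in seq_len(nf)) {
        if (left > 0L) {
          m[f, i] <- TRUE
          left <- left - 1L
        } else if (stats::runif(1) < cfg$occl_rate) {
          left <- sample(seq(cfg$occl_duration[1], cfg$occl_duration[2]), 1)
          m[f, i] <- TRUE
          left <- left - 1L
        }
      }
    }
    m
  })

  # -- ground truth tables ---------------------------------------------
  gt_world <- tibble::tibble(
    frame = rep(seq_len(nf), each = nt),
    id = rep(seq_len(nt), nf),
    left = as.numeric(t(traj$cx)) - rep(traj$w, nf) / 2,
    top = as.numeric(t(traj$cy)) - rep(traj$h, nf) / 2,
    width = rep(traj$w, nf),
    height = rep(traj$h, nf))

  cam_rows <- lapply(seq_len(nf), function(f) {
    A <- cum[[f]]
    sc <- sqrt(det(A$M))
    ctr <- apply_affine(A, cbind(traj$cx[f, ], traj$cy[f, ]))
    tibble::tibble(frame = f, id = seq_len(nt),
                   left = ctr[, 1] - traj$w * sc / 2,
                   top = ctr[, 2] - traj$h * sc / 2,
                   width = traj$w * sc, height = traj$h * sc)
  })
  gt <- dplyr::bind_rows(cam_rows)

  scen <- structure(list(
    gt_world = gt_world, gt = gt, affines = affines, cum_affines = cum,
    occluded = tibble::tibble(frame = rep(seq_len(nf), each = nt),
                              id = rep(seq_len(nt), nf),
                              occluded = as.logical(t(occl))),
    horizon_world = horizon_px, config = cfg), class = "mot_scenario")

  scen$detections <- corrupt_detections(scen, cfg)
  scen$descriptors <- scenario_descriptors(scen, cfg)
  scen
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Corrupt ground truth into realistic detections
#'
#' Visible targets get confidence near 1 minus noise; occluded frames
#' get confidence near the configured floor (landing them in the low
#' tier of the default [tier_config()]); boxes are jittered, targets are
#' dropped at the miss rate and Poisson false positives are added. With
#' all noise at zero, detections equal camera-coordinate ground truth
#' with confidence 1.
#'
#' @param scenario A `mot_scenario` (its camera-coordinate `gt` and
#'   occlusion schedule are used).
#' @param cfg The [scenario_config()].
#' @return Tibble `frame, left, top, width, height, conf, src_id,
#'   occluded`, ordered by frame.
#' @export
corrupt_detections <- function(scenario, cfg = scenario$config) {
  gt <- dplyr::left_join(scenario$gt, scenario$occluded,
                         by = c("frame", "id"))
  with_stream(cfg$seed, 4L, {
    keep <- stats::runif(nrow(gt)) >= cfg$miss_rate
    det <- gt[keep, , drop = FALSE]
    n <- nrow(det)
    conf <- ifelse(det$occluded,
                   stats::rnorm(n, cfg$occl_conf_floor, cfg$conf_sd),
                   1 - abs(stats::rnorm(n, 0, cfg$conf_sd)))
    out <- tibble::tibble(
      frame = det$frame,
      left = det$left + stats::rnorm(n, 0, cfg$jitter_sd),
      top = det$top + stats::rnorm(n, 0, cfg$jitter_sd),
      width = pmax(2, det$width + stats::rnorm(n, 0, cfg$jitter_sd / 2)),
      height = pmax(2, det$height + stats::rnorm(n, 0, cfg$jitter_sd / 2)),
      conf = clip01(conf),
      src_id = det$id,
      occluded = det$occluded)
    nfp <- stats::rpois(cfg$n_frames, cfg$fp_rate)
    if (sum(nfp) > 0) {
      W <- cfg$frame_size[1]
      H <- cfg$frame_size[2]
      fr <- rep(seq_len(cfg$n_frames), nfp)
      m <- length(fr)
      fh <- stats::runif(m, cfg$target_height[1], cfg$target_height[2])
      fw <- fh * stats::runif(m, cfg$target_aspect[1], cfg$target_aspect[2])
      fp <- tibble::tibble(
        frame = fr,
        left = stats::runif(m, 0, W - fw), top = stats::runif(m, 0, H - fh),
        width = fw, height = fh,
        conf = clip01(stats::runif(m, cfg$occl_conf_floor, 0.75)),
        src_id = NA_integer_, occluded = FALSE)
      out <- dplyr::bind_rows(out, fp)
    }
    dplyr::arrange(out, .data$frame)
  })
}

#' Per-identity appearance anchors and noisy observed descriptors
#'
#' Each identity owns a fixed random unit anchor in `descriptor_dim`
#' dimensions; an observed descriptor is the anchor plus isotropic
#' Gaussian noise, re-normalized, so within-identity cosine distances
#' stay well below cross-identity ones. False positives get fresh random
#' unit vectors.
#'
#' @param identities Integer vector of identity labels (NA = false
#'   positive).
#' @param cfg A [scenario_config()].
#' @param occluded Logical vector; occluded observations use the larger
#'   occlusion noise std.
#' @return Matrix of unit row vectors, one per observation.
#' @export
synthesize_descriptors <- function(identities, cfg, occluded = NULL) {
  if (is.null(occluded)) occluded <- rep(FALSE, length(identities))
  anchors <- descriptor_anchors(cfg)
  n <- length(identities)
  out <- matrix(0, n, cfg$descriptor_dim)
  for (k in seq_len(n)) {
    sd_k <- if (occluded[k]) cfg$descriptor_occl_noise_sd else
      cfg$descriptor_noise_sd
    v <- if (is.na(identities[k])) {
      stats::rnorm(cfg$descriptor_dim)
    } else {
      anchors[identities[k], ] + stats::rnorm(cfg$descriptor_dim, 0, sd_k)
    }
    out[k, ] <- v / sqrt(sum(v^2))
  }
  out
}

descriptor_anchors <- function(cfg) {
  with_stream(cfg$seed, 5L, {
    a <- matrix(stats::rnorm(cfg$n_targets * cfg$descriptor_dim),
                cfg$n_targets)
    a / sqrt(rowSums(a^2))
  })
}

scenario_descriptors <- function(scenario, cfg) {
  det <- scenario$detections
  d <- with_stream(cfg$seed, 7L,
                   synthesize_descriptors(det$src_id, cfg, det$occluded))
  idx <- stats::ave(det$frame, det$frame, FUN = seq_along)
  colnames(d) <- paste0("v", seq_len(ncol(d)))
  dplyr::bind_cols(tibble::tibble(frame = det$frame, det_index = idx),
                   tibble::as_tibble(d))
}

# bilinear texture sampling with border clamping; x, y are 1-based
# continuous coordinates
sample_bilinear <- function(tex, x, y) {
  nr <- nrow(tex)
  nc <- ncol(tex)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1)
  y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0
  fy <- y - y0
  i00 <- cbind(y0, x0)
  tex[i00] * (1 - fx) * (1 - fy) +
    tex[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    tex[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    tex[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# seeded value-noise texture in [0, 1]: coarse bilinear octave + fine octave
value_noise <- function(nr, nc, cell = 16, octaves = 2) {
  out <- matrix(0, nr, nc)
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    gr <- ceiling(nr / cell) + 2
    gc <- ceiling(nc / cell) + 2
    g <- matrix(stats::runif(gr * gc), gr, gc)
    xs <- (seq_len(nc) - 1) / cell + 1
    ys <- (seq_len(nr) - 1) / cell + 1
    grid <- cbind(rep(xs, each = nr), rep(ys, nc))
    out <- out + amp * matrix(sample_bilinear(g, grid[, 1], grid[, 2]),
                              nr, nc)
    total <- total + amp
    amp <- amp / 2
    cell <- max(2, cell / 4)
  }
  out / total
}

#' Render grey-level frames for a scenario
#'
#' A seeded value-noise ground texture below the horizon (dark,
#' low-texture sky above) is warped by each frame's cumulative camera
#' affine; targets are drawn as filled ellipses with per-identity
#' intensity. The per-frame horizon row (camera coordinates) is attached
#' as an attribute `horizon`.
#'
#' @param scenario A `mot_scenario`.
#' @param cfg Its [scenario_config()].
#' @return List of `H x W` matrices (values 0-255), one per frame, with
#'   attribute `horizon` (integer vector of 1-based horizon rows).
#' @export
render_frames <- function(scenario, cfg = scenario$config) {
  W <- cfg$frame_size[1]
  H <- cfg$frame_size[2]
  pad <- 60
  h0 <- scenario$horizon_world
  tex <- with_stream(cfg$seed, 6L, {
    t_ground <- 40 + 180 * value_noise(H + 2 * pad, W + 2 * pad)
    sky_rows <- seq_len(h0 + pad)
    grad <- matrix(rep(seq(15, 50, length.out = length(sky_rows)),
                       W + 2 * pad), length(sky_rows))
    t_ground[sky_rows, ] <- grad +
      4 * value_noise(length(sky_rows), W + 2 * pad, cell = 32, octaves = 1)
    t_ground
  })
  ids_int <- seq(70, 235, length.out = cfg$n_targets)
  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), W)
  frames <- vector("list", cfg$n_frames)
  horizon <- integer(cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    Ainv <- invert_affine(scenario$cum_affines[[f]])
    q <- apply_affine(Ainv, cbind(xs, ys))
    img <- matrix(sample_bilinear(tex, q[, 1] + pad, q[, 2] + pad), H, W)
    gtf <- scenario$gt[scenario$gt$frame == f, , drop = FALSE]
    for (k in seq_len(nrow(gtf))) {
      b <- gtf[k, ]
      cx <- b$left + b$width / 2
      cy <- b$top + b$height / 2
      rx <- max(b$width / 2, 1)
      ry <- max(b$height / 2, 1)
      x0 <- max(1, floor(cx - rx))
      x1 <- min(W, ceiling(cx + rx))
      y0 <- max(1, floor(cy - ry))
      y1 <- min(H, ceiling(cy + ry))
      if (x0 > x1 || y0 > y1) next
      xv <- x0:x1
      yv <- y0:y1
      ell <- outer((yv - cy)^2 / ry^2, (xv - cx)^2 / rx^2, `+`) <= 1
      sub <- img[yv, xv, drop = FALSE]
      sub[ell] <- ids_int[b$id]
      img[yv, xv] <- sub
    }
    horizon[f] <- as.integer(round(
      apply_affine(scenario$cum_affines[[f]], cbind(W / 2, h0))[2]))
    frames[[f]] <- img
  }
  attr(frames, "horizon") <- horizon
  frames
}

#' @export
print.mot_scenario <- function(x, ...) {
  cat("<mot_scenario>", x$config$n_targets, "targets,",
      x$config$n_frames, "frames,", nrow(x$detections), "detections\n")
  invisible(x)
}
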