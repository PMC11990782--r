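test_that("the generator is exactly reproducible under a fixed seed", {
  a <- simulate_scenario(scenario_config(n_targets = 3, n_frames = 10,
                                         seed = 51))
  b <- simulate_scenario(scenario_config(n_targets = 3, n_frames = 10,
                                         seed = 51))
  expect_identical(a$gt, b$gt)
  expect_identical(a$detections, b$detections)
  expect_identical(a$descriptors, b$descriptors)
  expect_identical(lapply(a$affines, unclass), lapply(b$affines, unclass))
})

test_that("switching one noise source off leaves the others untouched", {
  base <- scenario_config(n_targets = 3, n_frames = 10, seed = 53)
  quiet_cam <- scenario_config(n_targets = 3, n_frames = 10, seed = 53,
                               cam_trans_sd = 0, cam_rot_sd = 0,
                               cam_zoom_sd = 0)
  a <- simulate_scenario(base)
  b <- simulate_scenario(quiet_cam)
  expect_identical(a$gt_world, b$gt_world)   # trajectories share their stream
})

test_that("zero jitter and zero speed degenerate cleanly", {
  still <- simulate_scenario(scenario_config(
    n_targets = 2, n_frames = 8, seed = 55, cam_trans_sd = 0, cam_rot_sd = 0,
    cam_zoom_sd = 0, speed_range = c(0, 0)))
  for (a in still$affines) {
    expect_equal(a$M, diag(2))
    expect_equal(a$T, c(0, 0))
  }
  w <- still$gt_world
  expect_equal(dplyr::n_distinct(w[w$id == 1, c("left", "top")]), 1)
  expect_identical(still$gt, still$gt_world)

  noiseless <- simulate_scenario(scenario_config(
    n_targets = 2, n_frames = 8, seed = 55, cam_trans_sd = 0, cam_rot_sd = 0,
    cam_zoom_sd = 0, occl_rate = 0, miss_rate = 0, jitter_sd = 0,
    fp_rate = 0, conf_sd = 0))
  expect_equal(noiseless$detections$conf, rep(1, nrow(noiseless$detections)))
  expect_equal(noiseless$detections[, c("left", "top", "width", "height")],
               noiseless$gt[, c("left", "top", "width", "height")],
               ignore_attr = TRUE)
})

test_that("the inverse cumulative affine recovers world coordinates", {
  sc <- simulate_scenario(scenario_config(n_targets = 3, n_frames = 12,
                                          seed = 57))
  for (f in c(2, 7, 12)) {
    g <- sc$gt[sc$gt$frame == f, ]
    w <- sc$gt_world[sc$gt_world$frame == f, ]
    inv <- invert_affine(sc$cum_affines[[f]])
    ctr_cam <- cbind(g$left + g$width / 2, g$top + g$height / 2)
    ctr_back <- apply_affine(inv, ctr_cam)
    expect_equal(ctr_back, cbind(w$left + w$width / 2, w$top + w$height / 2),
                 tolerance = 1e-6, ignore_attr = TRUE)
    sc_f <- sqrt(det(sc$cum_affines[[f]]$M))
    expect_equal(g$height / sc_f, w$height, tolerance = 1e-6)
  }
})

test_that("the realized miss rate honours its binomial contract", {
  cfg <- scenario_config(n_targets = 10, n_frames = 120, seed = 59,
                         miss_rate = 0.08, fp_rate = 0, occl_rate = 0)
  sc <- simulate_scenario(cfg)
  n_opp <- 10 * 120
  n_detected <- nrow(sc$detections)
  rate <- 1 - n_detected / n_opp
  se <- sqrt(0.08 * 0.92 / n_opp)
  expect_lt(abs(rate - 0.08), 3 * se)
})

test_that("occluded detections land in the low tier", {
  cfg <- scenario_config(n_targets = 6, n_frames = 40, seed = 61,
                         occl_rate = 0.08, occl_conf_floor = 0.2,
                         conf_sd = 0.02)
  sc <- simulate_scenario(cfg)
  occluded <- sc$detections[which(sc$detections$occluded), ]
  expect_gt(nrow(occluded), 20)
  tiers <- stratify_detections(occluded$conf, tier_config(tau_low = 0.3))
  expect_gt(mean(tiers == "low"), 0.9)
})

test_that("descriptors are unit anchors plus noise with identity structure", {
  cfg <- scenario_config(n_targets = 2, n_frames = 5, seed = 63,
                         descriptor_noise_sd = 0)
  clean <- synthesize_descriptors(c(1L, 1L, 2L), cfg)
  expect_equal(sqrt(rowSums(clean^2)), rep(1, 3), tolerance = 1e-6)
  expect_equal(clean[1, ], clean[2, ])            # zero noise: the anchor

  cfg2 <- scenario_config(n_targets = 2, n_frames = 5, seed = 63,
                          descriptor_noise_sd = 0.1)
  set.seed(63)
  ids <- rep(1:2, each = 100)
  d <- synthesize_descriptors(ids, cfg2)
  sims <- d %*% t(d)
  within <- c(sims[ids == 1, ids == 1][upper.tri(diag(100))],
              sims[ids == 2, ids == 2][upper.tri(diag(100))])
  cross <- sims[ids == 1, ids == 2]
  expect_lt(mean(1 - within), mean(1 - cross))
})

test_that("rendered frames carry the scene the other modules expect", {
  cfg <- scenario_config(n_targets = 3, n_frames = 6, seed = 65,
                         cam_trans_sd = 0, cam_rot_sd = 0, cam_zoom_sd = 0,
                         cam_drift = c(8, 0))
  sc <- simulate_scenario(cfg)
  fr <- render_frames(sc)
  expect_length(fr, 6)
  expect_equal(dim(fr[[1]]), c(240, 320))

  # horizon of the rendered frame sits at the recorded row
  expect_lt(abs(detect_horizon(fr[[1]]) - attr(fr, "horizon")[1]), 2)

  # constant drift (8, 0) is recovered from consecutive frames
  est <- estimate_cmc(fr[[2]], fr[[3]],
                      as.matrix(sc$gt[sc$gt$frame == 2, 3:6]),
                      as.matrix(sc$gt[sc$gt$frame == 3, 3:6]))
  expect_equal(est$source, "estimated")
  expect_lt(max(abs(est$T - c(8, 0))), 1)

  # identity camera: static background pixels agree between frames
  cfg0 <- scenario_config(n_targets = 2, n_frames = 3, seed = 67,
                          cam_trans_sd = 0, cam_rot_sd = 0, cam_zoom_sd = 0)
  sc0 <- simulate_scenario(cfg0)
  fr0 <- render_frames(sc0)
  mask <- build_static_mask(c(240, 320),
                            rbind(as.matrix(sc0$gt[sc0$gt$frame == 1, 3:6]),
                                  as.matrix(sc0$gt[sc0$gt$frame == 2, 3:6])),
                            horizon = 1, margin = 0.5)
  expect_equal(fr0[[1]][mask], fr0[[2]][mask])
})

test_that("scenario plots render", {
  sc <- simulate_scenario(scenario_config(n_targets = 2, n_frames = 6,
                                          seed = 69))
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
  expect_output(print(sc), "mot_scenario")
})
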