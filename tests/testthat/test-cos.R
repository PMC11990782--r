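test_that("detections are stratified by the tier boundaries", {
  cfg <- tier_config(tau_high = 0.6, tau_low = 0.3, tau_discard = 0.1)
  expect_equal(stratify_detections(c(0.9, 0.5, 0.2), cfg),
               c("high", "medium", "low"))
  expect_equal(stratify_detections(0.6, cfg), "high")   # closed lower bound
  expect_equal(stratify_detections(0.3, cfg), "medium")
  expect_equal(stratify_detections(0.05, cfg), "discarded")
  df <- stratify_detections(tibble::tibble(conf = c(0.7, 0.05)), cfg)
  expect_equal(df$tier, c("high", "discarded"))
  expect_error(tier_config(tau_high = 0.2, tau_low = 0.3),
               "tau_discard < tau_low < tau_high")
  expect_error(tier_config(thr_high = 0.5, thr_medium = 0.3), "thr_high")
  expect_error(stratify_detections(c(0.5, 1.2), cfg), "\\[0, 1\\]")
})

test_that("stratification loses nothing but the discarded", {
  set.seed(3)
  conf <- runif(200)
  cfg <- tier_config()
  tier <- stratify_detections(conf, cfg)
  expect_equal(sort(c(which(tier == "high"), which(tier == "medium"),
                      which(tier == "low"), which(tier == "discarded"))),
               seq_along(conf))
  expect_true(all(conf[tier == "high"] >= cfg$tau_high))
  expect_true(all(conf[tier == "discarded"] < cfg$tau_discard))
})

make_track <- function(x, y, desc = NULL, age = 0L, h = 20) {
  st <- kf_predict(kf_initiate(c(x, y, 1.5, h)))
  g <- gallery_new(10)
  if (!is.null(desc)) g <- gallery_append(g, desc)
  list(proj = kf_project(st), gallery = g, age = age,
       box = measurement_to_box(st$mean[1:4]))
}

make_dets <- function(boxes, conf, descriptors = NULL, cfg = tier_config()) {
  list(boxes = boxes, conf = conf, descriptors = descriptors,
       measurements = lapply(seq_len(nrow(boxes)),
                             function(i) box_to_measurement(boxes[i, ])),
       tier = stratify_detections(conf, cfg))
}

unit3 <- function(i) {
  v <- numeric(8)
  v[i] <- 1
  v
}

test_that("a lone high tier behaves like the plain cascade", {
  tr <- list(make_track(50, 50, unit3(1)), make_track(150, 60, unit3(2)))
  boxes <- rbind(c(35, 40, 30, 20), c(135, 50, 30, 20))
  dets <- make_dets(boxes, c(0.9, 0.95),
                    rbind(unit3(1), unit3(2)))
  out <- tiered_associate(tr, dets)
  expect_equal(out$matches[order(out$matches[, 1]), ],
               rbind(c(1L, 1L), c(2L, 2L)))
  expect_length(out$unmatched_tracks, 0)
})

test_that("a high-confidence box outranks a nearby low-confidence one", {
  tr <- list(make_track(50, 50, unit3(1)))
  boxes <- rbind(c(36, 41, 30, 20), c(35, 40, 30, 20))
  dets <- make_dets(boxes, c(0.9, 0.2), rbind(unit3(1), unit3(1)))
  out <- tiered_associate(tr, dets)
  expect_equal(out$matches, cbind(1L, 1L))
  expect_equal(out$tier, "high")
})

test_that("a scripted three-tier scene matches its hand trace", {
  # t1 near d1(high); t2 near d2(medium, matching descriptor);
  # t3 near d3(low) and matched by overlap only
  tr <- list(make_track(50, 50, unit3(1)),
             make_track(150, 50, unit3(2)),
             make_track(250, 50, unit3(3)))
  boxes <- rbind(c(36, 41, 30, 20),    # over t1
                 c(136, 41, 30, 20),   # over t2
                 c(236, 41, 30, 20))   # over t3
  dets <- make_dets(boxes, c(0.9, 0.45, 0.2),
                    rbind(unit3(1), unit3(2), unit3(7)))
  out <- tiered_associate(tr, dets)
  ord <- order(out$matches[, 1])
  expect_equal(out$matches[ord, ], rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  expect_equal(out$tier[ord], c("high", "medium", "low"))
})

test_that("tier association is one-to-one with priority to higher tiers", {
  set.seed(17)
  for (rep in 1:10) {
    nt <- sample(2:4, 1)
    tr <- lapply(seq_len(nt), function(i) {
      make_track(60 * i, 50, unit3(i))
    })
    nd <- sample(2:5, 1)
    boxes <- cbind(runif(nd, 0, 300), runif(nd, 30, 70), 30, 20)
    dets <- make_dets(boxes, runif(nd),
                      do.call(rbind, lapply(sample(1:8, nd, TRUE), unit3)))
    out <- tiered_associate(tr, dets)
    if (nrow(out$matches)) {
      expect_false(any(duplicated(out$matches[, 1])))
      expect_false(any(duplicated(out$matches[, 2])))
      expect_true(all(dets$tier[out$matches[, 2]] != "discarded"))
    }
  }
})

test_that("collapsed tiers reduce to the single-stage baseline tracker", {
  sc <- simulate_scenario(scenario_config(n_targets = 4, n_frames = 15,
                                          seed = 77))
  collapsed <- herdtrack:::tier_config_unchecked(
    tau_high = 0.6, tau_low = 0.6, tau_discard = 0.6,
    thr_high = 0.2, thr_medium = 0.2, thr_low = 0.2)
  cfg_cos <- tracker_config(use_cmc = FALSE, tier = collapsed)
  cfg_base <- tracker_config(use_cmc = FALSE, use_cos = FALSE)
  r1 <- track(sc$detections, cfg_cos, descriptors = sc$descriptors)
  r2 <- track(sc$detections, cfg_base, descriptors = sc$descriptors)
  expect_equal(r1$results, r2$results)
})

test_that("pairwise IoU matches a reference formula", {
  set.seed(23)
  a <- cbind(runif(5, 0, 50), runif(5, 0, 50), runif(5, 5, 30), runif(5, 5, 30))
  b <- cbind(runif(4, 0, 50), runif(4, 0, 50), runif(4, 5, 30), runif(4, 5, 30))
  got <- iou_matrix(a, b)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(got[i, j], ref_iou(a[i, ], b[j, ]), tolerance = 1e-12)
  }
  expect_equal(iou_matrix(a[1, , drop = FALSE], a[1, , drop = FALSE])[1, 1], 1)
})
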