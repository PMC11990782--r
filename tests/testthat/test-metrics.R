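boxes_at <- function(x) cbind(x, 50, 20, 20)

frame_tbl <- function(frame, id, x) {
  tibble::tibble(frame = frame, id = id, left = x, top = 50,
                 width = 20, height = 20)
}

test_that("frame matching counts FP, FN and identity switches", {
  gt <- list(id = 1:2, boxes = boxes_at(c(0, 100)))
  same <- match_frame(gt, gt)
  expect_equal(nrow(same$pairs), 2)
  expect_equal(c(same$fp, same$fn, same$idsw), c(0, 0, 0))

  none <- match_frame(gt, list(id = integer(0),
                               boxes = matrix(numeric(0), 0, 4)))
  expect_equal(none$fn, 2)
  expect_equal(none$fp, 0)

  # scripted swap: both predictions trade places between frames
  pred1 <- list(id = c(11L, 12L), boxes = boxes_at(c(0, 100)))
  m1 <- match_frame(gt, pred1, NULL)
  pred2 <- list(id = c(12L, 11L), boxes = boxes_at(c(0, 100)))
  m2 <- match_frame(gt, pred2, m1$mapping)
  expect_equal(m2$idsw, 2)
})

test_that("CLEAR totals follow the accounting identities", {
  gt <- dplyr::bind_rows(lapply(1:5, function(f) frame_tbl(f, 1:2, c(0, 100))))
  perfect <- dplyr::mutate(gt, id = id + 10)
  m <- compute_clear(gt, perfect)
  expect_equal(m$mota, 1)
  expect_equal(m$motp, 1)
  expect_equal(m$n_matches + m$fn, m$n_gt)

  expect_error(compute_clear(gt[0, ], perfect), "no ground-truth")
})

test_that("the CLEAR worked example gives MOTA 0.7", {
  # 5 frames x 2 targets = 10 gt boxes; one FN, one FP, one switch
  gt <- dplyr::bind_rows(lapply(1:5, function(f) frame_tbl(f, 1:2, c(0, 200))))
  pred <- dplyr::bind_rows(
    frame_tbl(1, c(1L, 2L), c(0, 200)),
    frame_tbl(2, c(1L, 2L), c(0, 200)),
    frame_tbl(3, 1L, 0),                      # target 2 missed: FN
    frame_tbl(4, c(1L, 2L, 9L), c(0, 200, 400)),  # spurious box: FP
    frame_tbl(5, c(1L, 3L), c(0, 200)))       # target 2 under new id: IDSW
  m <- compute_clear(gt, pred)
  expect_equal(c(m$fn, m$fp, m$idsw, m$n_gt), c(1, 1, 1, 10))
  expect_equal(m$mota, 0.7)
})

test_that("MOTP averages matched-pair IoU", {
  # two matched pairs with IoU exactly 0.8 and 0.6 -> MOTP 0.7
  # width-10 boxes shifted by dx give IoU (10-dx)/(10+dx)
  gt <- tibble::tibble(frame = c(1, 1), id = 1:2, left = c(0, 100),
                       top = 0, width = 10, height = 10)
  pred <- tibble::tibble(frame = c(1, 1), id = 1:2,
                         left = c(10 / 9, 100 + 2.5),
                         top = 0, width = 10, height = 10)
  expect_equal(ref_iou(c(0, 0, 10, 10), c(10 / 9, 0, 10, 10)), 0.8)
  m <- compute_clear(gt, pred)
  expect_equal(m$motp, 0.7, tolerance = 1e-9)
})

test_that("MOTA is invariant to relabelling that preserves switches", {
  sc <- simulate_scenario(scenario_config(n_targets = 4, n_frames = 15,
                                          seed = 37))
  res <- track(sc$detections, tracker_config(use_cmc = FALSE),
               descriptors = sc$descriptors)
  base <- compute_clear(sc$gt, res$results)
  relab <- dplyr::mutate(res$results, id = id * 7 + 1000)
  again <- compute_clear(sc$gt, relab)
  expect_equal(base$mota, again$mota)
  expect_equal(base$idsw, again$idsw)
})

test_that("IDF1 arithmetic and global pairing are correct", {
  gt <- dplyr::bind_rows(lapply(1:10, function(f) frame_tbl(f, 1L, 0)))
  # pred covers frames 1-8 correctly, then wanders off: IDTP 8, IDFP 2, IDFN 2
  pred <- dplyr::bind_rows(
    lapply(1:8, function(f) frame_tbl(f, 5L, 0)),
    lapply(9:10, function(f) frame_tbl(f, 5L, 500)))
  r <- compute_idf1(gt, pred)
  expect_equal(c(r$idtp, r$idfp, r$idfn), c(8, 2, 2))
  expect_equal(r$idf1, 0.8)

  perfect <- dplyr::bind_rows(lapply(1:10, function(f) frame_tbl(f, 9L, 0)))
  expect_equal(compute_idf1(gt, perfect)$idf1, 1)
  expect_error(compute_idf1(gt[0, ], pred), "empty")
})

test_that("IDF1 pairing equals exhaustive enumeration on small scenes", {
  set.seed(43)
  for (rep in 1:5) {
    ng <- sample(2:3, 1)
    np <- sample(2:4, 1)
    nf <- 6
    gt <- dplyr::bind_rows(lapply(1:nf, function(f) {
      frame_tbl(f, seq_len(ng), 100 * seq_len(ng))
    }))
    # predictions jump between target slots mid-sequence
    pred <- dplyr::bind_rows(lapply(1:nf, function(f) {
      slots <- sample(seq_len(ng), min(np, ng))
      frame_tbl(f, seq_along(slots) + 20L, 100 * slots)
    }))
    r <- compute_idf1(gt, pred)
    gids <- sort(unique(gt$id))
    pids <- sort(unique(pred$id))
    overlap <- matrix(0L, length(gids), length(pids))
    for (f in 1:nf) {
      g <- gt[gt$frame == f, ]
      p <- pred[pred$frame == f, ]
      for (a in seq_len(nrow(g))) for (b in seq_len(nrow(p))) {
        if (ref_iou(as.numeric(g[a, 3:6]), as.numeric(p[b, 3:6])) >= 0.5) {
          overlap[match(g$id[a], gids), match(p$id[b], pids)] <-
            overlap[match(g$id[a], gids), match(p$id[b], pids)] + 1L
        }
      }
    }
    idtp_bf <- brute_force_idtp(overlap)
    expect_equal(r$idtp, idtp_bf)
    expect_equal(r$idf1,
                 2 * idtp_bf / (2 * idtp_bf + (nrow(pred) - idtp_bf) +
                                  (nrow(gt) - idtp_bf)))
  }
})

test_that("average precision integrates the all-point PR curve", {
  gt <- frame_tbl(1, 1:4, c(0, 100, 200, 300))
  all_good <- tibble::tibble(frame = 1, left = c(0, 100, 200, 300), top = 50,
                             width = 20, height = 20, conf = c(.9, .8, .7, .6))
  expect_equal(average_precision(all_good, gt), 1)

  # ranks TP, FP, TP, TP, FP on 4 gt: hand-integrated area 0.625
  toy <- tibble::tibble(frame = 1,
                        left = c(0, 500, 100, 200, 600), top = 50,
                        width = 20, height = 20,
                        conf = c(.95, .9, .85, .8, .75))
  expect_equal(average_precision(toy, gt), 0.625)

  expect_equal(mean_ap(c(0.5)), 0.5)  # single class: mAP = AP
  expect_warning(m <- mean_ap(c(0.4, NA)), "excluded")
  expect_equal(m, 0.4)
  expect_warning(ap_na <- average_precision(toy, gt[0, ]), "no ground truth")
  expect_true(is.na(ap_na))
})

test_that("evaluation ties the suite together with tidy output", {
  sc <- simulate_scenario(scenario_config(n_targets = 3, n_frames = 12,
                                          seed = 47))
  res <- track(sc$detections, tracker_config(use_cmc = FALSE),
               descriptors = sc$descriptors)
  ev <- evaluate_tracking(sc$gt, res)
  gl <- glance(ev)
  expect_true(gl$mota <= 1)
  expect_true(gl$idf1 >= 0 && gl$idf1 <= 1)
  td <- tidy(ev)
  expect_equal(td$metric[1:3], c("MOTA", "MOTP", "IDF1"))
  expect_output(print(ev), "MOTA")
})
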