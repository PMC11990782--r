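#' Tracker configuration
#'
#' Bundles every knob of the per-frame pipeline: Kalman noise, association
#' weights and gates, confidence tiers, lifecycle counters, and camera
#' motion compensation.
#'
#' @param n_init Consecutive hits before a tentative track is confirmed.
#' @param max_age Frames a missing track is retained before deletion.
#' @param lambda Motion weight in the combined association cost
#'   (`lambda * mahalanobis + (1 - lambda) * cosine`). Default 0:
#'   appearance-driven cost with the Mahalanobis acting as a gate only,
#'   the usual choice under camera motion.
#' @param motion_gate Chi-square gate on the Mahalanobis distance;
#'   default the 0.95 quantile at 4 dof.
#' @param gallery_budget Descriptors retained per track.
#' @param tier A [tier_config()].
#' @param noise A [kf_noise()].
#' @param cmc A [cmc_params()].
#' @param use_cmc Apply camera motion compensation when frames (or
#'   externally estimated affines) are available.
#' @param use_cos Use the confidence-tiered association; `FALSE` keeps
#'   only detections at or above `tier$tau_high` and runs the plain
#'   single-stage cascade (the high-tier-only baseline).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(n_init = 3, max_age = 30, lambda = 0,
                           motion_gate = chi2_gate(), gallery_budget = 100,
                           tier = tier_config(), noise = kf_noise(),
                           cmc = cmc_params(), use_cmc = TRUE,
                           use_cos = TRUE) {
  if (n_init < 1 || max_age < 1) stop("n_init and max_age must be >= 1",
                                      call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]",
                                     call. = FALSE)
  structure(as.list(environment()), class = "tracker_config")
}

new_track <- function(id, measurement, descriptor, config) {
  g <- gallery_new(config$gallery_budget)
  if (!is.null(descriptor)) g <- gallery_append(g, descriptor)
  list(id = id,
       state = kf_initiate(measurement, config$noise),
       gallery = g,
       status = if (config$n_init <= 1) "confirmed" else "tentative",
       hits = 1L,
       time_since_update = 0L)
}

#' Create an empty online tracker
#'
#' The tracker value is functional: [tracker_step()] consumes and returns
#' it, so a run is a fold over frames (see [track()] for the high-level
#' data-frame interface).
#'
#' @param config A [tracker_config()].
#' @return A tracker state object.
#' @export
tracker_init <- function(config = tracker_config()) {
  structure(list(config = config, tracks = list(), next_id = 1L,
                 last_frame = NA_integer_, warned_no_descriptors = FALSE),
            class = "mot_tracker")
}

track_box <- function(track) {
  measurement_to_box(track$state$mean[1:4])
}

#' Apply lifecycle rules after association
#'
#' Matched tentative tracks reaching `n_init` hits are confirmed;
#' unmatched confirmed tracks become missing; a missing track that is
#' re-matched resumes as confirmed under its original id; tracks missing
#' longer than `max_age` frames, and unmatched tentative tracks, are
#' deleted.
#'
#' @param tracks List of track records.
#' @param matched_idx Indices of tracks matched this frame.
#' @param config A [tracker_config()].
#' @return The surviving track list.
#' @export
update_lifecycle <- function(tracks, matched_idx, config) {
  keep <- logical(length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (i %in% matched_idx) {
      if (tr$status == "tentative" && tr$hits >= config$n_init) {
        tr$status <- "confirmed"
      } else if (tr$status == "missing") {
        tr$status <- "confirmed"
      }
      keep[i] <- TRUE
    } else {
      if (tr$status == "tentative") {
        keep[i] <- FALSE                       # one miss kills a tentative
      } else {
        if (tr$status == "confirmed") tr$status <- "missing"
        keep[i] <- tr$time_since_update <= config$max_age
      }
    }
    tracks[[i]] <- tr
  }
  tracks[keep]
}

#' Deterministic appearance descriptor from an image patch
#'
#' An 8x8x8 joint colour histogram of the cropped detection patch,
#' L2-normalized — a fixed, training-free embedder. Grey-level frames use
#' the intensity channel three times (the histogram degenerates to its
#' diagonal but still separates targets of different brightness).
#'
#' @param frame Grey matrix or H x W x 3 array, values `[0, 255]` (or
#'   `[0, 1]`).
#' @param box Detection box `(left, top, width, height)`, 0-based pixels.
#' @return Unit-norm numeric vector of length 512.
#' @export
embed_patch <- function(frame, box) {
  if (is.matrix(frame)) {
    arr <- array(frame, c(dim(frame), 3))
  } else {
    arr <- frame[, , 1:3, drop = FALSE]
  }
  if (max(arr) <= 1) arr <- arr * 255
  h_img <- dim(arr)[1]
  w_img <- dim(arr)[2]
  x0 <- max(1, floor(box[1]) + 1)
  x1 <- min(w_img, ceiling(box[1] + box[3]))
  y0 <- max(1, floor(box[2]) + 1)
  y1 <- min(h_img, ceiling(box[2] + box[4]))
  if (x0 > x1 || y0 > y1) stop("box does not intersect the frame",
                               call. = FALSE)
  patch <- arr[y0:y1, x0:x1, , drop = FALSE]
  bin <- patch %/% 32
  bin[bin > 7] <- 7
  idx <- as.integer(bin[, , 1] + 8 * bin[, , 2] + 64 * bin[, , 3] + 1)
  hist <- tabulate(idx, nbins = 512)
  hist / sqrt(sum(hist^2))
}

prepare_frame_dets <- function(boxes, conf, descriptors, tier_cfg, use_cos) {
  if (use_cos) {
    tier <- stratify_detections(conf, tier_cfg)
  } else {
    tier <- ifelse(conf >= tier_cfg$tau_high, "high", "discarded")
  }
  list(boxes = boxes, conf = conf, descriptors = descriptors,
       measurements = lapply(seq_len(nrow(boxes)),
                             function(i) box_to_measurement(boxes[i, ])),
       tier = tier)
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame pipeline: Kalman predict for every live
#' track; camera-motion estimation between `prev_frame` and `frame`
#' (or the supplied `known_affine`) and compensation of every predicted
#' state; confidence-tiered cascaded association; Kalman update and
#' gallery append (high/medium tiers only) for matches; lifecycle
#' bookkeeping; track birth from unmatched high-tier detections.
#'
#' @param tracker A tracker from [tracker_init()] / a previous step.
#' @param frame_index Strictly increasing integer frame number.
#' @param boxes n x 4 matrix of detection boxes
#'   `(left, top, width, height)`, 0-based pixels (may have 0 rows).
#' @param conf Numeric vector of detection confidences.
#' @param descriptors Optional matrix of unit row descriptors (n rows).
#' @param frame,prev_frame Optional grey-level matrices for CMC and for
#'   the patch embedder.
#' @param known_affine Optional externally estimated [affine_motion()]
#'   mapping the previous frame's coordinates to this frame's.
#' @return List with `tracker` (advanced state) and `result`, a tibble
#'   of confirmed tracks updated this frame
#'   (`frame, id, left, top, width, height, conf`).
#' @export
tracker_step <- function(tracker, frame_index, boxes, conf,
                         descriptors = NULL, frame = NULL,
                         prev_frame = NULL, known_affine = NULL) {
  cfg <- tracker$config
  if (!is.na(tracker$last_frame) && frame_index <= tracker$last_frame) {
    stop("frame_index must be strictly increasing", call. = FALSE)
  }
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  nd <- nrow(boxes)

  # descriptors: sidecar > patch embedder > none (motion-only)
  if (is.null(descriptors) && !is.null(frame) && nd > 0) {
    descriptors <- do.call(rbind, lapply(seq_len(nd), function(i) {
      embed_patch(frame, boxes[i, ])
    }))
  }
  lambda <- cfg$lambda
  if (is.null(descriptors) && lambda < 1) {
    if (!tracker$warned_no_descriptors) {
      warning("no descriptor source; falling back to pure motion cost ",
              "(lambda = 1)", call. = FALSE)
      tracker$warned_no_descriptors <- TRUE
    }
    lambda <- 1
  }

  # 1. predict
  for (i in seq_along(tracker$tracks)) {
    tr <- tracker$tracks[[i]]
    tr$state <- kf_predict(tr$state, cfg$noise)
    tr$time_since_update <- tr$time_since_update + 1L
    tracker$tracks[[i]] <- tr
  }

  # 2. camera motion compensation of every predicted state
  if (cfg$use_cmc && length(tracker$tracks)) {
    motion <- NULL
    if (!is.null(known_affine)) {
      motion <- known_affine
    } else if (!is.null(frame) && !is.null(prev_frame)) {
      motion <- estimate_cmc(prev_frame, frame,
                             prev_boxes = tracker$last_boxes,
                             curr_boxes = boxes, params = cfg$cmc)
    }
    if (!is.null(motion)) {
      for (i in seq_along(tracker$tracks)) {
        tr <- tracker$tracks[[i]]
        qn <- if (cfg$cmc$add_qn) kf_process_noise(tr$state$mean[4],
                                                   cfg$noise) else NULL
        tr$state <- compensate_track(tr$state, motion, qn, cfg$cmc$apply)
        tracker$tracks[[i]] <- tr
      }
    }
  }

  # 3. association
  dets <- prepare_frame_dets(boxes, conf, descriptors, cfg$tier, cfg$use_cos)
  track_info <- lapply(tracker$tracks, function(tr) {
    list(proj = kf_project(tr$state, cfg$noise),
         gallery = tr$gallery,
         age = tr$time_since_update,
         box = track_box(tr),
         tentative = tr$status == "tentative")
  })
  assoc <- tiered_associate(track_info, dets, cfg$tier, lambda,
                            cfg$motion_gate)

  # 4. update matched tracks
  if (nrow(assoc$matches)) {
    for (k in seq_len(nrow(assoc$matches))) {
      i <- assoc$matches[k, 1]
      j <- assoc$matches[k, 2]
      tr <- tracker$tracks[[i]]
      tr$state <- kf_update(tr$state, dets$measurements[[j]], cfg$noise)
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      tr$last_conf <- conf[j]
      # low-tier crops are occlusion-corrupted: keep them out of the gallery
      if (!is.null(descriptors) && assoc$tier[k] != "low") {
        tr$gallery <- gallery_append(tr$gallery, descriptors[j, ])
      }
      tracker$tracks[[i]] <- tr
    }
  }

  # 5. lifecycle
  tracker$tracks <- update_lifecycle(tracker$tracks,
                                     if (nrow(assoc$matches))
                                       assoc$matches[, 1] else integer(0),
                                     cfg)

  # 6. births from unmatched high-tier detections
  for (j in assoc$unmatched_detections) {
    if (dets$tier[j] != "high") next
    d <- if (!is.null(descriptors)) descriptors[j, ] else NULL
    tr <- new_track(tracker$next_id, dets$measurements[[j]], d, cfg)
    tr$last_conf <- conf[j]
    tracker$next_id <- tracker$next_id + 1L
    tracker$tracks <- c(tracker$tracks, list(tr))
  }

  tracker$last_frame <- frame_index
  tracker$last_boxes <- boxes

  out <- list()
  for (tr in tracker$tracks) {
    if (tr$status == "confirmed" && tr$time_since_update == 0L) {
      b <- track_box(tr)
      out[[length(out) + 1]] <- tibble::tibble(
        frame = frame_index, id = tr$id, left = b[1], top = b[2],
        width = b[3], height = b[4],
        conf = if (is.null(tr$last_conf)) 1 else tr$last_conf)
    }
  }
  result <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(frame = integer(0), id = integer(0), left = numeric(0),
                   top = numeric(0), width = numeric(0), height = numeric(0),
                   conf = numeric(0))
  list(tracker = tracker, result = dplyr::arrange(result, .data$id))
}

#' Track a detection table through a whole sequence
#'
#' The high-level tidy interface: a MOTChallenge-style detection table in,
#' an identity-labelled track table out.
#'
#' @param detections Tibble/data frame with columns
#'   `frame, left, top, width, height, conf` (0-based pixel coordinates,
#'   as produced by [read_mot_detections()] or [simulate_scenario()]).
#' @param config A [tracker_config()].
#' @param frames Optional frame source for CMC and the patch embedder:
#'   a directory of PNG files named by 6-digit frame number, or a list of
#'   grey matrices indexed by frame number.
#' @param descriptors Optional descriptor sidecar: tibble with columns
#'   `frame, det_index, v1..vD` ([read_descriptors()]) whose rows are
#'   unit vectors aligned with the detection order within each frame.
#' @param affines Optional list of [affine_motion()] per frame (entry
#'   `f` maps frame `f - 1` coordinates to frame `f`), an alternative to
#'   image-based estimation, e.g. from an external stabilizer.
#' @return An object of class `mot_tracking`: list with `results` (tibble
#'   `frame, id, left, top, width, height, conf`), `config`, `frames`
#'   (the frame index range).
#' @export
track <- function(detections, config = tracker_config(), frames = NULL,
                  descriptors = NULL, affines = NULL) {
  stopifnot(is.data.frame(detections))
  need <- c("frame", "left", "top", "width", "height", "conf")
  if (!all(need %in% names(detections))) {
    stop("detections must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  frame_dir <- NULL
  if (is.character(frames)) {
    frame_dir <- frames
    frames <- NULL
  }
  desc_by_frame <- NULL
  if (!is.null(descriptors)) {
    desc_by_frame <- split_descriptors(descriptors)
  }
  frame_ids <- sort(unique(detections$frame))
  if (length(frame_ids)) {
    frame_ids <- seq(min(frame_ids), max(frame_ids))
  }
  trk <- tracker_init(config)
  results <- list()
  prev_img <- NULL
  for (f in frame_ids) {
    rows <- detections[detections$frame == f, , drop = FALSE]
    boxes <- as.matrix(rows[, c("left", "top", "width", "height")])
    img <- NULL
    if (!is.null(frame_dir)) {
      img <- read_frame_png(frame_dir, f)
    } else if (!is.null(frames) && f <= length(frames)) {
      img <- frames[[f]]
    }
    desc <- if (!is.null(desc_by_frame)) desc_by_frame[[as.character(f)]]
            else NULL
    aff <- if (!is.null(affines) && f <= length(affines)) affines[[f]]
           else NULL
    st <- tracker_step(trk, f, boxes, rows$conf, descriptors = desc,
                       frame = img, prev_frame = prev_img,
                       known_affine = aff)
    trk <- st$tracker
    results[[length(results) + 1]] <- st$result
    prev_img <- img
  }
  res <- dplyr::bind_rows(results)
  structure(list(results = res, config = config,
                 frames = range(frame_ids)),
            class = "mot_tracking")
}

#' @export
print.mot_tracking <- function(x, ...) {
  cat("<mot_tracking>", nrow(x$results), "boxes,",
      length(unique(x$results$id)), "identities, frames",
      x$frames[1], "-", x$frames[2], "\n")
  invisible(x)
}
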