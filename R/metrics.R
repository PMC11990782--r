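#' Frame-level CLEAR correspondence
#'
#' One step of the CLEAR-MOT matching protocol: correspondences from the
#' previous frame persist when their IoU is still at least `iou_min`;
#' the remaining boxes are matched by the Hungarian algorithm on
#' `1 - IoU` with pairs below the overlap floor forbidden; an identity
#' switch is counted whenever a ground-truth id's matched prediction id
#' differs from its last known partner.
#'
#' @param gt List with `id` (vector) and `boxes` (n x 4) for the frame's
#'   ground truth.
#' @param pred Same structure for the predictions.
#' @param prev_mapping Named vector: last known pred id per gt id
#'   (names = gt ids).
#' @param iou_min Minimum overlap for a valid correspondence.
#' @return List: `pairs` (matrix gt index, pred index, iou), `fp`, `fn`,
#'   `idsw`, `mapping` (updated last-known mapping).
#' @export
match_frame <- function(gt, pred, prev_mapping = NULL, iou_min = 0.5) {
  ng <- length(gt$id)
  np <- length(pred$id)
  if (is.null(prev_mapping)) prev_mapping <- integer(0)
  pairs <- matrix(numeric(0), 0, 3)
  used_g <- logical(ng)
  used_p <- logical(np)
  iou <- iou_matrix(gt$boxes, pred$boxes)
  # 1. persist surviving correspondences
  for (gi in seq_len(ng)) {
    prev_p <- prev_mapping[as.character(gt$id[gi])]
    if (!is.na(prev_p) && length(prev_p)) {
      pj <- match(prev_p, pred$id)
      if (!is.na(pj) && !used_p[pj] && iou[gi, pj] >= iou_min) {
        pairs <- rbind(pairs, c(gi, pj, iou[gi, pj]))
        used_g[gi] <- TRUE
        used_p[pj] <- TRUE
      }
    }
  }
  # 2. Hungarian on the rest
  rem_g <- which(!used_g)
  rem_p <- which(!used_p)
  if (length(rem_g) && length(rem_p)) {
    cost <- 1 - iou[rem_g, rem_p, drop = FALSE]
    cost[cost > 1 - iou_min] <- Inf
    sol <- solve_assignment(cost)
    if (nrow(sol$matches)) {
      for (k in seq_len(nrow(sol$matches))) {
        gi <- rem_g[sol$matches[k, 1]]
        pj <- rem_p[sol$matches[k, 2]]
        pairs <- rbind(pairs, c(gi, pj, iou[gi, pj]))
      }
    }
  }
  idsw <- 0L
  mapping <- prev_mapping
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      gid <- as.character(gt$id[pairs[k, 1]])
      pid <- pred$id[pairs[k, 2]]
      old <- mapping[gid]
      if (!is.na(old) && length(old) && old != pid) idsw <- idsw + 1L
      mapping[gid] <- pid
    }
  }
  list(pairs = pairs, fp = np - nrow(pairs), fn = ng - nrow(pairs),
       idsw = idsw, mapping = mapping)
}

split_frames <- function(df) {
  lapply(split(df, df$frame), function(rows) {
    list(id = rows$id,
         boxes = as.matrix(rows[, c("left", "top", "width", "height")]))
  })
}

#' CLEAR-MOT metrics over a sequence
#'
#' `MOTA = 1 - (sum FN + FP + IDSW) / sum GT_t`, an overall accuracy that
#' may go negative, and `MOTP = sum d_{t,i} / sum c_t` with `d` the IoU
#' of each matched pair, a higher-is-better localization quality.
#'
#' @param gt,pred Data frames with columns
#'   `frame, id, left, top, width, height`.
#' @param iou_min Overlap floor for a correspondence. Default 0.5.
#' @return List: `mota`, `motp`, `fp`, `fn`, `idsw`, `n_gt`, `n_matches`.
#' @export
compute_clear <- function(gt, pred, iou_min = 0.5) {
  gtf <- split_frames(gt)
  prf <- split_frames(pred)
  frames <- sort(as.integer(union(names(gtf), names(prf))))
  tot_gt <- 0L; fp <- 0L; fn <- 0L; idsw <- 0L
  iou_sum <- 0; n_match <- 0L
  mapping <- integer(0)
  empty <- list(id = integer(0), boxes = matrix(numeric(0), 0, 4))
  for (f in as.character(frames)) {
    g <- if (!is.null(gtf[[f]])) gtf[[f]] else empty
    p <- if (!is.null(prf[[f]])) prf[[f]] else empty
    m <- match_frame(g, p, mapping, iou_min)
    mapping <- m$mapping
    tot_gt <- tot_gt + length(g$id)
    fp <- fp + m$fp
    fn <- fn + m$fn
    idsw <- idsw + m$idsw
    if (nrow(m$pairs)) {
      iou_sum <- iou_sum + sum(m$pairs[, 3])
      n_match <- n_match + nrow(m$pairs)
    }
  }
  if (tot_gt == 0) stop("undefined metric: no ground-truth boxes",
                        call. = FALSE)
  list(mota = 1 - (fn + fp + idsw) / tot_gt,
       motp = if (n_match > 0) iou_sum / n_match else NA_real_,
       fp = fp, fn = fn, idsw = idsw, n_gt = tot_gt, n_matches = n_match)
}

#' Identity F1 score
#'
#' Global (whole-sequence) min-cost bipartite matching between
#' ground-truth and predicted trajectories; with `IDTP` the per-frame
#' box pairs explained by the chosen trajectory pairing,
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams compute_clear
#' @return List: `idf1`, `idtp`, `idfp`, `idfn`.
#' @export
compute_idf1 <- function(gt, pred, iou_min = 0.5) {
  if (nrow(gt) == 0 || nrow(pred) == 0) {
    stop("undefined metric: empty sequence", call. = FALSE)
  }
  gids <- sort(unique(gt$id))
  pids <- sort(unique(pred$id))
  # overlap[i, j]: frames in which gt trajectory i and pred trajectory j
  # could be counted as the same identity (IoU >= iou_min)
  overlap <- matrix(0L, length(gids), length(pids))
  frames <- sort(unique(c(gt$frame, pred$frame)))
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    if (nrow(g) == 0 || nrow(p) == 0) next
    iou <- iou_matrix(as.matrix(g[, c("left", "top", "width", "height")]),
                      as.matrix(p[, c("left", "top", "width", "height")]))
    ok <- iou >= iou_min
    gi <- match(g$id, gids)
    pj <- match(p$id, pids)
    for (a in seq_len(nrow(g))) {
      for (b in seq_len(nrow(p))) {
        if (ok[a, b]) overlap[gi[a], pj[b]] <- overlap[gi[a], pj[b]] + 1L
      }
    }
  }
  # maximize total explained frames = min-cost assignment on -overlap
  n <- max(dim(overlap))
  cost <- matrix(max(overlap), n, n)
  cost[seq_len(nrow(overlap)), seq_len(ncol(overlap))] <-
    max(overlap) - overlap
  sol_rows <- hungarian_square(cost)
  idtp <- 0L
  for (i in seq_len(nrow(overlap))) {
    j <- sol_rows[i]
    if (j <= ncol(overlap)) idtp <- idtp + overlap[i, j]
  }
  idfn <- nrow(gt) - idtp
  idfp <- nrow(pred) - idtp
  list(idf1 = 2 * idtp / (2 * idtp + idfp + idfn),
       idtp = idtp, idfp = idfp, idfn = idfn)
}

#' Average precision of scored detections
#'
#' Confidence-descending sweep with greedy IoU matching (each ground
#' truth consumed once) and all-point interpolation of the
#' precision-recall curve.
#'
#' @param detections Data frame `frame, left, top, width, height, conf`.
#' @param gt Data frame `frame, id, left, top, width, height`.
#' @param iou_min Overlap for a true positive. Default 0.5.
#' @return The AP value in `[0, 1]`.
#' @export
average_precision <- function(detections, gt, iou_min = 0.5) {
  n_gt <- nrow(gt)
  if (n_gt == 0) {
    warning("no ground truth; AP undefined for this class", call. = FALSE)
    return(NA_real_)
  }
  if (nrow(detections) == 0) return(0)
  ord <- order(-detections$conf, detections$frame)
  det <- detections[ord, , drop = FALSE]
  used <- new.env()
  tp <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    g <- gt[gt$frame == det$frame[k], , drop = FALSE]
    if (nrow(g) == 0) next
    iou <- iou_matrix(as.matrix(det[k, c("left", "top", "width", "height")]),
                      as.matrix(g[, c("left", "top", "width", "height")]))[1, ]
    ok <- which(iou >= iou_min)
    if (length(ok) == 0) next
    ok <- ok[order(-iou[ok])]
    for (gi in ok) {
      key <- paste(det$frame[k], g$id[gi])
      if (is.null(used[[key]])) {
        used[[key]] <- TRUE
        tp[k] <- TRUE
        break
      }
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # all-point interpolation: precision envelope integrated over recall
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- 0
  ap <- 0
  for (k in seq_along(recall)) {
    if (recall[k] > r_prev) {
      ap <- ap + (recall[k] - r_prev) * prec_env[k]
      r_prev <- recall[k]
    }
  }
  ap
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class AP values (NA = class without
#'   ground truth, excluded with a warning).
#' @return Mean AP.
#' @export
mean_ap <- function(aps) {
  if (any(is.na(aps))) {
    warning("classes without ground truth excluded from mAP", call. = FALSE)
    aps <- aps[!is.na(aps)]
  }
  mean(aps)
}

#' Evaluate tracking output against ground truth
#'
#' Computes the CLEAR-MOT suite (MOTA, MOTP, FP, FN, identity switches)
#' and IDF1 in one call.
#'
#' @param gt Ground-truth data frame
#'   `frame, id, left, top, width, height` (e.g. [read_mot_gt()]).
#' @param results Tracking results: a `mot_tracking` object from
#'   [track()] or a data frame of the same columns.
#' @param iou_min Overlap floor for correspondences. Default 0.5.
#' @return Object of class `mot_metrics` (see [glance.mot_metrics()]).
#' @export
evaluate_tracking <- function(gt, results, iou_min = 0.5) {
  if (inherits(results, "mot_tracking")) results <- results$results
  clear <- compute_clear(gt, results, iou_min)
  idf <- compute_idf1(gt, results, iou_min)
  structure(c(clear, idf, list(iou_min = iou_min)), class = "mot_metrics")
}

#' @export
print.mot_metrics <- function(x, ...) {
  cat(sprintf(
    "MOT evaluation (IoU >= %.2f)\n  MOTA %6.1f%%   MOTP %6.1f%%   IDF1 %6.1f%%\n  FP %d   FN %d   IDs %d   (GT boxes %d)\n",
    x$iou_min, 100 * x$mota, 100 * x$motp, 100 * x$idf1,
    x$fp, x$fn, x$idsw, x$n_gt))
  invisible(x)
}
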