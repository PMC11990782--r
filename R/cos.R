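#' Confidence-tier configuration
#'
#' Detections are stratified by confidence into high / medium / low tiers
#' (anything below `tau_discard` is dropped) and associated in that
#' priority order with tier-specific matching thresholds: the reliable
#' high tier must satisfy a stringent (small) association-distance
#' ceiling, the medium tier a slightly looser one, and the low tier —
#' typically occluded or poorly lit targets — is matched last, by motion
#' overlap only, under a much more permissive criterion so occluded
#' targets are recovered instead of lost.
#'
#' @param tau_high,tau_low,tau_discard Confidence boundaries,
#'   `tau_discard < tau_low < tau_high`; a detection with confidence `c`
#'   lands in high if `c >= tau_high`, medium if `tau_low <= c <
#'   tau_high`, low if `tau_discard <= c < tau_low`, else discarded.
#' @param thr_high,thr_medium Maximum admissible combined association
#'   distance for the high / medium stages (`thr_high <= thr_medium`).
#' @param thr_low Maximum admissible `1 - IoU` distance for the
#'   low-confidence stage (0.5 = minimum IoU 0.5).
#' @return A list of class `tier_config`.
#' @export
tier_config <- function(tau_high = 0.6, tau_low = 0.3, tau_discard = 0.1,
                        thr_high = 0.2, thr_medium = 0.3, thr_low = 0.5) {
  if (!(tau_discard < tau_low && tau_low < tau_high)) {
    stop("require tau_discard < tau_low < tau_high", call. = FALSE)
  }
  if (!(thr_high <= thr_medium)) {
    stop("require thr_high <= thr_medium", call. = FALSE)
  }
  structure(as.list(environment()), class = "tier_config")
}

# degenerate boundaries (tau_high == tau_low == tau_discard) are allowed
# internally for the single-tier baseline reduction
tier_config_unchecked <- function(tau_high, tau_low, tau_discard,
                                  thr_high, thr_medium, thr_low) {
  structure(list(tau_high = tau_high, tau_low = tau_low,
                 tau_discard = tau_discard, thr_high = thr_high,
                 thr_medium = thr_medium, thr_low = thr_low),
            class = "tier_config")
}

#' Stratify detections into confidence tiers
#'
#' @param detections A data frame with a `conf` column, or a bare numeric
#'   vector of confidences in `[0, 1]`.
#' @param cfg A [tier_config()].
#' @return For a data frame input, the same rows with a `tier` column
#'   (`"high"`, `"medium"`, `"low"`, `"discarded"`); for a numeric input,
#'   the character vector of tiers.
#' @export
stratify_detections <- function(detections, cfg = tier_config()) {
  conf <- if (is.data.frame(detections)) detections$conf else detections
  if (any(conf < 0 | conf > 1)) {
    stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  tier <- ifelse(conf >= cfg$tau_high, "high",
          ifelse(conf >= cfg$tau_low, "medium",
          ifelse(conf >= cfg$tau_discard, "low", "discarded")))
  if (is.data.frame(detections)) {
    detections$tier <- tier
    detections
  } else {
    tier
  }
}

#' Pairwise intersection-over-union of two box sets
#'
#' @param a,b Matrices of boxes `(left, top, width, height)`.
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values in `[0, 1]`.
#' @export
iou_matrix <- function(a, b) {
  a <- matrix(as.numeric(as.matrix(a)), ncol = 4)
  b <- matrix(as.numeric(as.matrix(b)), ncol = 4)
  na <- nrow(a)
  nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0 || nb == 0) return(out)
  for (i in seq_len(na)) {
    ix0 <- pmax(a[i, 1], b[, 1])
    iy0 <- pmax(a[i, 2], b[, 2])
    ix1 <- pmin(a[i, 1] + a[i, 3], b[, 1] + b[, 3])
    iy1 <- pmin(a[i, 2] + a[i, 4], b[, 2] + b[, 4])
    inter <- pmax(0, ix1 - ix0) * pmax(0, iy1 - iy0)
    union <- a[i, 3] * a[i, 4] + b[, 3] * b[, 4] - inter
    out[i, ] <- pmin(1, ifelse(union > 0, inter / union, 0))
  }
  out
}

#' Confidence-tiered cascaded association
#'
#' Association in priority order. Stage 1: established (non-tentative)
#' tracks against the high tier, age-ordered cascade, combined
#' motion/appearance cost gated at `thr_high`; leftover high-tier boxes
#' are then offered to tentative tracks (and just-missed established
#' ones) by box overlap, the Deep SORT convention that stops a freshly
#' spawned duplicate from outranking the track it duplicates. Stage 2:
#' still-unmatched established tracks against the medium tier at
#' `thr_medium`. Stage 3: still-unmatched recently seen tracks against
#' the low tier by `1 - IoU` between the predicted box and the
#' detection (appearance is unreliable for occluded crops), gated at
#' `thr_low` and solved as one joint assignment. Each track and
#' detection matches at most once.
#'
#' @param tracks List per track: `proj` (projected measurement
#'   distribution), `gallery`, `age` (`time_since_update`), `box`
#'   (predicted box), optional `tentative` flag (default FALSE).
#' @param dets List with `measurements` (list of 4-vectors), `boxes`
#'   (n x 4), `conf`, `descriptors` (matrix or NULL), `tier` (character).
#' @param cfg [tier_config()].
#' @param lambda Motion weight of the combined cost.
#' @param motion_gate Chi-square gate on the Mahalanobis distance.
#' @return List `matches` (columns: track, detection, plus the tier of
#'   the matched detection), `unmatched_tracks`, `unmatched_detections`.
#' @export
tiered_associate <- function(tracks, dets, cfg = tier_config(),
                             lambda = 0, motion_gate = chi2_gate()) {
  nt <- length(tracks)
  nd <- length(dets$conf)
  all_matches <- matrix(integer(0), 0, 2)
  match_tier <- character(0)
  remaining_tracks <- seq_len(nt)

  appearance_cost_fn <- function(thr) {
    force(thr)
    function(tr_idx, det_idx) {
      proj <- lapply(tracks[tr_idx], `[[`, "proj")
      meas <- dets$measurements[det_idx]
      d1 <- mahalanobis_matrix(proj, meas)
      if (!is.null(dets$descriptors) && lambda < 1) {
        gals <- lapply(tracks[tr_idx], `[[`, "gallery")
        d2 <- cosine_matrix(gals, dets$descriptors[det_idx, , drop = FALSE])
        cost <- combined_cost(d1, d2, lambda)
        # tracks with empty galleries fall back to motion-only scoring,
        # with the Mahalanobis rescaled by gate/thr so the tier's
        # distance ceiling stays meaningful
        empty <- vapply(gals, gallery_size, 0L) == 0
        if (any(empty)) {
          cost[empty, ] <- d1[empty, , drop = FALSE] / motion_gate * thr
        }
      } else {
        cost <- d1 / motion_gate * thr
      }
      gate_cost(cost, d1, motion_gate, thr)
    }
  }

  run_stage <- function(det_idx, cost_fn, candidates, cascade = TRUE) {
    if (length(candidates) == 0 || length(det_idx) == 0) return(NULL)
    if (cascade) {
      ages <- vapply(tracks[candidates], `[[`, 0L, "age")
      sol <- matching_cascade(ages, length(det_idx), function(ti, di) {
        cost_fn(candidates[ti], det_idx[di])
      })
    } else {
      sol <- solve_assignment(cost_fn(candidates, det_idx))
      sol$matches <- sol$matches
    }
    if (nrow(sol$matches)) {
      cbind(candidates[sol$matches[, 1]], det_idx[sol$matches[, 2]])
    } else NULL
  }

  iou_cost_fn <- function(gate) {
    force(gate)
    function(tr_idx, det_idx) {
      tboxes <- do.call(rbind, lapply(tracks[tr_idx], `[[`, "box"))
      cost <- 1 - iou_matrix(tboxes, dets$boxes[det_idx, , drop = FALSE])
      cost[cost > gate] <- Inf
      cost
    }
  }

  tentative <- vapply(tracks, function(t) isTRUE(t$tentative), TRUE)
  ages_all <- vapply(tracks, `[[`, 0L, "age")
  commit <- function(m, stage) {
    if (is.null(m)) return()
    all_matches <<- rbind(all_matches, m)
    match_tier <<- c(match_tier, rep(stage, nrow(m)))
    remaining_tracks <<- setdiff(remaining_tracks, m[, 1])
  }

  for (stage in c("high", "medium", "low")) {
    det_idx <- setdiff(which(dets$tier == stage), all_matches[, 2])
    if (stage == "high") {
      # appearance cascade over established tracks only
      cand <- remaining_tracks[!tentative[remaining_tracks]]
      m <- run_stage(det_idx, appearance_cost_fn(cfg$thr_high), cand)
      commit(m, "high")
      # leftover boxes vs tentative tracks and just-missed established
      # ones, by overlap (a newborn cannot outrank the track it shadows
      # in the cascade, but may still claim an unclaimed box)
      det_idx <- setdiff(det_idx, all_matches[, 2])
      cand <- remaining_tracks[tentative[remaining_tracks] |
                                 ages_all[remaining_tracks] == 1L]
      m <- run_stage(det_idx, iou_cost_fn(0.7), cand, cascade = FALSE)
      commit(m, "high")
    } else if (stage == "medium") {
      cand <- remaining_tracks[!tentative[remaining_tracks]]
      m <- run_stage(det_idx, appearance_cost_fn(cfg$thr_medium), cand)
      commit(m, "medium")
    } else {
      # occluded boxes carry no appearance evidence, so only recently
      # tracked targets may claim them; long-missing tracks with stale
      # predictions are excluded to prevent identity theft through the
      # permissive IoU criterion, and the stage is one joint assignment:
      # the best-overlapping track wins a contested box regardless of
      # which competitor was seen more recently
      cand <- remaining_tracks[!tentative[remaining_tracks] &
                                 ages_all[remaining_tracks] <= 3L]
      m <- run_stage(det_idx, iou_cost_fn(cfg$thr_low), cand,
                     cascade = FALSE)
      commit(m, "low")
    }
  }

  list(matches = all_matches,
       tier = match_tier,
       unmatched_tracks = remaining_tracks,
       unmatched_detections = setdiff(which(dets$tier != "discarded"),
                                      all_matches[, 2]))
}
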