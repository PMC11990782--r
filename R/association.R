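#' Squared Mahalanobis distance between projected tracks and detections
#'
#' Entry `(i, j)` is `(d_j - y_i)^T S_i^{-1} (d_j - y_i)`, the motion-state
#' distance between track `i`'s predicted measurement distribution
#' `(y_i, S_i)` and detection measurement `d_j`. Under the Kalman model it
#' is chi-square distributed with 4 degrees of freedom, which is what the
#' standard gate at the 0.95 quantile exploits.
#'
#' @param projected_states List of lists with elements `mean` (length 4)
#'   and `cov` (4x4), as returned by [kf_project()].
#' @param measurements List of numeric 4-vectors `(x, y, gamma, h)`.
#' @return Matrix, rows = tracks, columns = detections, entries >= 0.
#' @export
mahalanobis_matrix <- function(projected_states, measurements) {
  nt <- length(projected_states)
  nd <- length(measurements)
  out <- matrix(0, nt, nd)
  if (nt == 0 || nd == 0) return(out)
  d <- do.call(rbind, lapply(measurements, as.numeric))
  for (i in seq_len(nt)) {
    ps <- projected_states[[i]]
    ch <- tryCatch(chol(ps$cov), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf("singular innovation covariance for track %d", i),
           call. = FALSE)
    }
    resid <- t(d) - ps$mean            # 4 x nd
    z <- forwardsolve(t(ch), resid)
    out[i, ] <- colSums(z^2)
  }
  out
}

#' Minimum cosine distance between track galleries and detection descriptors
#'
#' Entry `(i, j)` is `min_k (1 - r_j . r_k^i)` over track `i`'s stored
#' unit descriptors: the appearance cost of assigning detection `j` to
#' track `i`. A track with an empty gallery gets `Inf` in its row (it can
#' only be scored by motion).
#'
#' @param galleries List of descriptor galleries ([gallery_new()]).
#' @param descriptors Matrix of unit row vectors (one row per detection),
#'   or a list of unit vectors.
#' @return Matrix of cosine distances in `[0, 2]`, or `Inf`.
#' @export
cosine_matrix <- function(galleries, descriptors) {
  if (is.list(descriptors)) descriptors <- do.call(rbind, descriptors)
  nt <- length(galleries)
  nd <- if (is.null(descriptors)) 0L else nrow(descriptors)
  out <- matrix(Inf, nt, nd)
  if (nt == 0 || nd == 0) return(out)
  for (i in seq_len(nt)) {
    g <- gallery_matrix(galleries[[i]])
    if (is.null(g) || nrow(g) == 0) next
    # 1 - max similarity over gallery members
    sims <- descriptors %*% t(g)       # nd x gallery size
    out[i, ] <- pmax(0, 1 - apply(sims, 1, max))
  }
  out
}

#' Combine motion and appearance costs
#'
#' Elementwise `c = lambda * d1 + (1 - lambda) * d2`; `Inf` in either
#' operand propagates so a pair gated by one cue stays gated.
#'
#' @param d1 Motion (Mahalanobis) cost matrix.
#' @param d2 Appearance (cosine) cost matrix, same shape.
#' @param lambda Weight in `[0, 1]` on the motion term.
#' @return Combined cost matrix.
#' @export
combined_cost <- function(d1, d2, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  if (!all(dim(d1) == dim(d2))) stop("cost matrices must have equal shape",
                                     call. = FALSE)
  out <- lambda * d1 + (1 - lambda) * d2
  # 0 * Inf = NaN; any Inf operand must gate the pair
  out[is.infinite(d1) | is.infinite(d2)] <- Inf
  out
}

#' Gate a combined cost matrix
#'
#' Pairs whose Mahalanobis distance exceeds `motion_gate` or whose
#' combined cost exceeds `cost_gate` are set to `Inf` and can never be
#' matched. Gating is idempotent.
#'
#' @param cost Combined cost matrix.
#' @param d1 Mahalanobis cost matrix, same shape.
#' @param motion_gate Chi-square gate on `d1`; default the 0.95 quantile
#'   at 4 dof (9.4877).
#' @param cost_gate Ceiling on the combined cost (`Inf` disables).
#' @return Gated cost matrix.
#' @export
gate_cost <- function(cost, d1, motion_gate = chi2_gate(), cost_gate = Inf) {
  if (!all(dim(cost) == dim(d1))) stop("cost matrices must have equal shape",
                                       call. = FALSE)
  cost[d1 > motion_gate | cost > cost_gate] <- Inf
  cost
}

#' Chi-square motion gate
#'
#' @param p Quantile level, default 0.95.
#' @param df Degrees of freedom (4: the measurement dimension).
#' @return The gate value; 9.4877 at the defaults.
#' @export
chi2_gate <- function(p = 0.95, df = 4) stats::qchisq(p, df)

# -- descriptor gallery: ring buffer of at most n_budget unit vectors ------

#' Per-track appearance-descriptor gallery
#'
#' A ring buffer of the most recent `n_budget` unit descriptors observed
#' for one track; the oldest is evicted first. Incoming vectors that are
#' not unit norm are re-normalized with a warning.
#'
#' @param n_budget Maximum number of stored descriptors. Default 100.
#' @return An empty gallery object.
#' @export
gallery_new <- function(n_budget = 100) {
  structure(list(vectors = NULL, n_budget = n_budget), class = "descriptor_gallery")
}

#' @rdname gallery_new
#' @param gallery A gallery.
#' @param descriptor Unit-norm numeric vector.
#' @export
gallery_append <- function(gallery, descriptor) {
  nrm <- sqrt(sum(descriptor^2))
  if (nrm == 0) stop("cannot store a zero descriptor", call. = FALSE)
  if (abs(nrm - 1) > 1e-6) {
    warning("descriptor not unit norm; re-normalizing", call. = FALSE)
    descriptor <- descriptor / nrm
  }
  v <- rbind(gallery$vectors, as.numeric(descriptor))
  if (nrow(v) > gallery$n_budget) v <- v[-1, , drop = FALSE]
  gallery$vectors <- v
  gallery
}

#' @rdname gallery_new
#' @export
gallery_matrix <- function(gallery) gallery$vectors

#' @rdname gallery_new
#' @export
gallery_size <- function(gallery) {
  if (is.null(gallery$vectors)) 0L else nrow(gallery$vectors)
}

#' Age-ordered matching cascade
#'
#' Deep SORT's cascade: tracks are associated in groups of increasing
#' `time_since_update`, so recently seen tracks get first claim on the
#' detections; each detection is matched at most once overall.
#'
#' @param track_ages Integer vector of `time_since_update` per track.
#' @param n_detections Number of candidate detections.
#' @param cost_fn Function `(track_idx, det_idx) -> gated cost matrix` for
#'   the given index subsets (`Inf` = inadmissible).
#' @return List `matches` (track index, detection index),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
matching_cascade <- function(track_ages, n_detections, cost_fn) {
  matches <- matrix(integer(0), 0, 2)
  remaining <- seq_len(n_detections)
  for (age in sort(unique(track_ages))) {
    if (length(remaining) == 0) break
    grp <- which(track_ages == age)
    cost <- cost_fn(grp, remaining)
    sol <- solve_assignment(cost)
    if (nrow(sol$matches)) {
      matches <- rbind(matches,
                       cbind(grp[sol$matches[, 1]], remaining[sol$matches[, 2]]))
      remaining <- setdiff(remaining, remaining[sol$matches[, 2]])
    }
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_along(track_ages), matches[, 1]),
       unmatched_detections = remaining)
}
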