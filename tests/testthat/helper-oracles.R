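# Independent oracles used across the suite. Each re-derives a quantity by
# a route separate from the package implementation (closed form, brute
# force, or direct matrix algebra).

# scalar (position, velocity) Kalman recursion with dt = 1, written as
# plain loops over the textbook equations
scalar_kalman <- function(z, x0, P0, q_pos, q_vel, r) {
  f <- matrix(c(1, 0, 1, 1), 2, 2)
  h <- matrix(c(1, 0), 1, 2)
  x <- x0
  P <- P0
  out <- vector("list", length(z))
  for (k in seq_along(z)) {
    x <- f %*% x
    P <- f %*% P %*% t(f) + diag(c(q_pos, q_vel))
    S <- (h %*% P %*% t(h))[1, 1] + r
    K <- P %*% t(h) / S
    x <- x + K * (z[k] - (h %*% x)[1, 1])
    P <- (diag(2) - K %*% h) %*% P
    out[[k]] <- list(x = as.numeric(x), P = P)
  }
  out
}

# brute-force minimum-cost one-to-one assignment by enumerating every
# injection of the smaller side into the larger
brute_force_assignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  best <- Inf
  best_m <- matrix(integer(0), 0, 2)
  rows_first <- nr <= nc
  k <- min(nr, nc)
  n <- max(nr, nc)
  idx <- seq_len(n)
  rec <- function(pos, used, total, pairs) {
    if (total >= best) return()
    if (pos > k) {
      if (total < best) {
        best <<- total
        best_m <<- pairs
      }
      return()
    }
    # allow leaving this row/col unmatched
    rec(pos + 1, used, total, pairs)
    for (j in idx[!used]) {
      cc <- if (rows_first) cost[pos, j] else cost[j, pos]
      if (is.finite(cc)) {
        u <- used
        u[j] <- TRUE
        pr <- if (rows_first) rbind(pairs, c(pos, j)) else rbind(pairs, c(j, pos))
        rec(pos + 1, u, total + cc, pr)
      }
    }
  }
  rec(1, rep(FALSE, n), 0, matrix(integer(0), 0, 2))
  # an unmatched admissible pair can always be added at non-negative cost,
  # so among equal-cardinality solutions take the min cost of maximal ones:
  # rerun requiring maximum cardinality
  max_card <- 0
  count_card <- function(pos, used, card) {
    if (pos > k) {
      max_card <<- max(max_card, card)
      return()
    }
    count_card(pos + 1, used, card)
    for (j in idx[!used]) {
      cc <- if (rows_first) cost[pos, j] else cost[j, pos]
      if (is.finite(cc)) {
        u <- used
        u[j] <- TRUE
        count_card(pos + 1, u, card + 1)
      }
    }
  }
  count_card(1, rep(FALSE, n), 0)
  best <- Inf
  best_m <- matrix(integer(0), 0, 2)
  rec2 <- function(pos, used, total, pairs) {
    if (pos > k) {
      if (nrow(pairs) == max_card && total < best) {
        best <<- total
        best_m <<- pairs
      }
      return()
    }
    rec2(pos + 1, used, total, pairs)
    for (j in idx[!used]) {
      cc <- if (rows_first) cost[pos, j] else cost[j, pos]
      if (is.finite(cc)) {
        u <- used
        u[j] <- TRUE
        pr <- if (rows_first) rbind(pairs, c(pos, j)) else rbind(pairs, c(j, pos))
        rec2(pos + 1, u, total + cc, pr)
      }
    }
  }
  rec2(1, rep(FALSE, n), 0, matrix(integer(0), 0, 2))
  list(cost = best, matches = best_m, cardinality = max_card)
}

expect_symmetric_psd <- function(m, tol = 1e-9) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -tol)
}

# brute-force horizon: row of maximal mean |central-difference vertical
# gradient|, one-sided at the borders, smallest row on ties
brute_force_horizon <- function(img) {
  h <- nrow(img)
  best_row <- 1
  best_val <- -Inf
  for (y in seq_len(h)) {
    g <- numeric(ncol(img))
    for (x in seq_len(ncol(img))) {
      g[x] <- if (y == 1) img[2, x] - img[1, x]
      else if (y == h) img[h, x] - img[h - 1, x]
      else (img[y + 1, x] - img[y - 1, x]) / 2
    }
    v <- mean(abs(g))
    if (v > best_val + 1e-12) {
      best_val <- v
      best_row <- y
    }
  }
  best_row
}

ref_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# exhaustive best trajectory pairing for identity metrics (<= 4 x 4)
brute_force_idtp <- function(overlap) {
  ng <- nrow(overlap)
  np <- ncol(overlap)
  k <- min(ng, np)
  best <- 0
  combs <- function(pool, m) if (m == 0) list(integer(0)) else
    unlist(lapply(seq_along(pool), function(i) {
      lapply(combs(pool[-seq_len(i)], m - 1), function(rest) c(pool[i], rest))
    }), recursive = FALSE)
  for (m in 0:k) {
    for (gs in combs(seq_len(ng), m)) {
      for (ps in combs(seq_len(np), m)) {
        if (m == 0) next
        for (perm in asplit(perms_of(ps), 1)) {
          best <- max(best, sum(overlap[cbind(gs, perm)]))
        }
      }
    }
  }
  best
}

perms_of <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# small deterministic textured image for keypoint tests
make_texture <- function(h, w, seed = 42) {
  set.seed(seed)
  base <- matrix(runif(ceiling(h / 4) * ceiling(w / 4)), ceiling(h / 4))
  big <- base[rep(seq_len(nrow(base)), each = 4)[1:h],
              rep(seq_len(ncol(base)), each = 4)[1:w]]
  round(40 + 180 * big + matrix(runif(h * w, 0, 20), h))
}

shift_image <- function(img, dx, dy) {
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(mean(img), h, w)
  src_rows <- seq_len(h) - dy
  src_cols <- seq_len(w) - dx
  ok_r <- src_rows >= 1 & src_rows <= h
  ok_c <- src_cols >= 1 & src_cols <= w
  out[ok_r, ok_c] <- img[src_rows[ok_r], src_cols[ok_c]]
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.infinite(a))) b else a
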