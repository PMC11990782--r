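# Linear-sum assignment via the shortest-augmenting-path (Jonker-Volgenant
# style) Hungarian algorithm with row/column potentials, O(n^3). Written
# here because no installed package exposes a linear assignment solver;
# verified in the test suite against brute-force permutation enumeration.
hungarian_square <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  INF <- .Machine$double.xmax / 4
  # 1-indexed potentials with a virtual 0-th column handled via index n+1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  # assignment: row i -> column
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assign_row[p[j]] <- j
  assign_row
}

#' Solve the detection-to-track assignment problem
#'
#' Minimum-total-cost one-to-one matching between the rows (tracks) and
#' columns (detections) of a cost matrix. Entries of `Inf` mark
#' inadmissible (gated) pairs and are never matched. Rectangular matrices
#' are padded internally; unmatched rows/columns are reported.
#'
#' @param cost Numeric matrix with non-negative finite entries or `Inf`.
#' @return List with `matches` (two-column integer matrix: row index,
#'   column index, ordered by row), `unmatched_rows`, `unmatched_cols`.
#' @export
solve_assignment <- function(cost) {
  if (is.null(cost) || length(cost) == 0 ||
      nrow(cost) == 0 || ncol(cost) == 0) {
    nr <- if (is.null(cost)) 0L else nrow(cost)
    nc <- if (is.null(cost)) 0L else ncol(cost)
    return(list(matches = matrix(integer(0), 0, 2),
                unmatched_rows = seq_len(nr),
                unmatched_cols = seq_len(nc)))
  }
  stopifnot(is.matrix(cost))
  fin <- cost[is.finite(cost)]
  if (length(fin) && any(fin < 0)) {
    stop("cost matrix entries must be >= 0", call. = FALSE)
  }
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  big <- if (length(fin)) max(fin) * n + 1 else 1
  sq <- matrix(big, n, n)
  sq[seq_len(nr), seq_len(nc)] <- pmin(cost, big)
  assign_row <- hungarian_square(sq)
  matches <- matrix(integer(0), 0, 2)
  for (i in seq_len(nr)) {
    j <- assign_row[i]
    if (j <= nc && is.finite(cost[i, j])) {
      matches <- rbind(matches, c(i, j))
    }
  }
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(nr), matches[, 1]),
       unmatched_cols = setdiff(seq_len(nc), matches[, 2]))
}
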