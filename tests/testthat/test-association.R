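proj_of <- function(mean4, cov4) list(mean = mean4, cov = cov4)

test_that("mahalanobis matrix computes the gated quadratic form", {
  p <- list(proj_of(c(1, 2, 0.5, 10), diag(4)))
  expect_equal(mahalanobis_matrix(p, list(c(1, 2, 0.5, 10)))[1, 1], 0)
  expect_equal(mahalanobis_matrix(p, list(c(2, 2, 0.5, 10)))[1, 1], 1)
  p2 <- list(proj_of(c(0, 0, 0, 0), diag(c(4, 1, 1, 1))))
  expect_equal(mahalanobis_matrix(p2, list(c(2, 0, 0, 0)))[1, 1], 1)
  expect_error(
    mahalanobis_matrix(list(proj_of(rep(0, 4), matrix(0, 4, 4))),
                       list(rep(0, 4))),
    "track 1")
})

test_that("mahalanobis distance is invariant under linear reparameterization", {
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(rnorm(16), 4)
    cov <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    y <- rnorm(4)
    d <- rnorm(4)
    d0 <- mahalanobis_matrix(list(proj_of(y, cov)), list(d))[1, 1]
    d1 <- mahalanobis_matrix(list(proj_of(as.numeric(a %*% y),
                                          a %*% cov %*% t(a))),
                             list(as.numeric(a %*% d)))[1, 1]
    expect_equal(d0, d1, tolerance = 1e-6)
  }
})

test_that("cosine matrix takes the minimum distance over the gallery", {
  g <- gallery_new(10)
  u <- c(1, 0, 0, 0)
  v <- c(0, 1, 0, 0)
  g <- gallery_append(gallery_append(g, u), v)
  expect_equal(cosine_matrix(list(g), rbind(u))[1, 1], 0)
  expect_equal(cosine_matrix(list(g), rbind(c(0, 0, 1, 0)))[1, 1], 1)
  # gallery members with similarities 0.9 and 0.4 -> min rule gives 0.1
  r <- c(1, 0, 0)
  g2 <- gallery_append(gallery_new(10), c(0.9, sqrt(1 - 0.81), 0))
  g2 <- gallery_append(g2, c(0.4, 0, sqrt(1 - 0.16)))
  expect_equal(cosine_matrix(list(g2), rbind(r))[1, 1], 0.1,
               tolerance = 1e-12)
  # empty gallery scores +Inf
  expect_equal(cosine_matrix(list(gallery_new(5)), rbind(u))[1, 1], Inf)
})

test_that("the gallery is a bounded ring buffer of unit vectors", {
  g <- gallery_new(3)
  for (k in 1:5) {
    e <- numeric(8)
    e[k] <- 1
    g <- gallery_append(g, e)
  }
  expect_equal(gallery_size(g), 3)
  expect_equal(gallery_matrix(g)[1, ], c(0, 0, 1, 0, 0, 0, 0, 0)) # oldest kept
  expect_warning(gallery_append(gallery_new(2), c(2, 0, 0)), "re-normalizing")
})

test_that("combined cost mixes linearly and propagates gates", {
  d1 <- matrix(c(0.2, Inf), 1)
  d2 <- matrix(c(0.4, 0.1), 1)
  expect_equal(combined_cost(d1, d2, 1)[1, 1], 0.2)
  expect_equal(combined_cost(d1, d2, 0)[1, 1], 0.4)
  expect_equal(combined_cost(d1, d2, 0.5)[1, 1], 0.3)
  expect_equal(combined_cost(d1, d2, 0)[1, 2], Inf)   # Inf survives lambda = 0
  expect_error(combined_cost(d1, d2, 1.5), "lambda")
  expect_error(combined_cost(d1, matrix(0, 2, 2), 0.5), "shape")
})

test_that("gating removes exactly the violating entries and is idempotent", {
  d1 <- matrix(c(1, 100, 5, 9.5), 2)
  cost <- matrix(c(0.1, 0.1, 0.3, 0.15), 2)
  g <- gate_cost(cost, d1, motion_gate = 9.4877, cost_gate = 0.25)
  expect_equal(g, matrix(c(0.1, Inf, Inf, Inf), 2))
  expect_equal(gate_cost(g, d1, 9.4877, 0.25), g)
  all_ok <- gate_cost(matrix(0.1, 2, 2), matrix(1, 2, 2))
  expect_equal(all_ok, matrix(0.1, 2, 2))
  expect_equal(chi2_gate(), 9.4877, tolerance = 1e-4)
})

test_that("assignment solves tiny cases exactly", {
  expect_equal(solve_assignment(matrix(5, 1, 1))$matches,
               matrix(c(1L, 1L), 1))
  sol <- solve_assignment(matrix(c(1, 10, 10, 1), 2, 2))
  expect_equal(sol$matches, rbind(c(1L, 1L), c(2L, 2L)))
  empty <- solve_assignment(matrix(numeric(0), 0, 3))
  expect_equal(nrow(empty$matches), 0)
  expect_equal(empty$unmatched_cols, 1:3)
})

test_that("assignment equals brute-force enumeration on seeded matrices", {
  set.seed(123)
  for (trial in 1:100) {
    nr <- sample(1:5, 1)
    nc <- sample(1:5, 1)
    cost <- matrix(runif(nr * nc, 0, 10), nr, nc)
    if (trial %% 3 == 0) cost[runif(nr * nc) < 0.3] <- Inf
    sol <- solve_assignment(cost)
    bf <- brute_force_assignment(cost)
    expect_equal(nrow(sol$matches), bf$cardinality)
    total <- if (nrow(sol$matches)) sum(cost[sol$matches]) else 0
    expect_equal(total, bf$cost %||% 0, tolerance = 1e-9)
    if (nrow(sol$matches)) {
      expect_true(all(is.finite(cost[sol$matches])))
      expect_false(any(duplicated(sol$matches[, 1])))
      expect_false(any(duplicated(sol$matches[, 2])))
    }
  }
})

test_that("the matching cascade gives younger tracks first claim", {
  # one age group: identical to plain assignment
  cost <- matrix(c(1, 3, 2, 0.5), 2)
  cf <- function(ti, di) cost[ti, di, drop = FALSE]
  one <- matching_cascade(c(0L, 0L), 2, cf)
  expect_equal(one$matches[order(one$matches[, 1]), , drop = FALSE],
               solve_assignment(cost)$matches)

  # fresh track and stale track both near one detection: fresh wins
  cost2 <- matrix(c(0.2, 0.1), 2, 1)   # stale track is even closer
  two <- matching_cascade(c(0L, 5L), 1, function(ti, di) {
    cost2[ti, di, drop = FALSE]
  })
  expect_equal(two$matches, cbind(1L, 1L))
  expect_equal(two$unmatched_tracks, 2L)

  # three age groups with scripted costs, hand-traced:
  # tracks 1,2 age 0; track 3 age 2; track 4 age 7; detections 1..3
  big <- matrix(Inf, 4, 3)
  big[1, ] <- c(0.1, 0.5, Inf)   # t1 takes d1
  big[2, ] <- c(0.2, 0.3, Inf)   # t2 then takes d2
  big[3, ] <- c(0.05, 0.1, 0.4)  # t3 (age 2) left with d3
  big[4, ] <- c(0.01, 0.01, 0.2) # t4 (age 7) nothing left
  tr <- matching_cascade(c(0L, 0L, 2L, 7L), 3, function(ti, di) {
    big[ti, di, drop = FALSE]
  })
  got <- tr$matches[order(tr$matches[, 1]), ]
  expect_equal(got, rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L)))
  expect_equal(tr$unmatched_tracks, 4L)
})
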