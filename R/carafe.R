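#' Normalize a CARAFE reassembly kernel field
#'
#' Applies a softmax over the kernel axis at every output location, so
#' each per-location reassembly kernel is nonnegative and sums to 1 —
#' the property that makes reassembly average-preserving.
#'
#' @param raw Array `(sigma H) x (sigma W) x k_up^2` of kernel logits.
#' @return Array of the same shape with normalized kernels.
#' @export
carafe_normalize_kernels <- function(raw) {
  if (!all(is.finite(raw))) stop("kernel logits must be finite",
                                 call. = FALSE)
  d <- dim(raw)
  if (length(d) != 3) stop("kernel field must be a 3-d array", call. = FALSE)
  m <- apply(raw, c(1, 2), max)
  ex <- exp(sweep(raw, c(1, 2), m))
  sweep(ex, c(1, 2), apply(ex, c(1, 2), sum), "/")
}

#' Content-aware reassembly of features (CARAFE)
#'
#' Upsamples a feature map by integer factor `sigma` using one
#' softmax-normalized `k_up x k_up` kernel per output location: each
#' output pixel is the kernel-weighted sum (a dot product) over the
#' neighborhood of its source pixel, the source being the floor-division
#' of the output coordinate by `sigma` (each `sigma x sigma` output
#' block shares a source centre). Borders are zero-padded, and the same
#' kernel is applied to every channel.
#'
#' @param feat Array `H x W x C` (a matrix is treated as `H x W x 1`).
#' @param kernels Array `(sigma H) x (sigma W) x k_up^2` of normalized
#'   kernels ([carafe_normalize_kernels()]).
#' @param sigma Upsampling factor (default 2).
#' @param k_up Kernel side length (default 5); must be odd.
#' @return Array `(sigma H) x (sigma W) x C`.
#' @export
carafe_reassemble <- function(feat, kernels, sigma = 2, k_up = 5) {
  if (is.matrix(feat)) feat <- array(feat, c(dim(feat), 1))
  d <- dim(feat)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (k_up %% 2 != 1) stop("k_up must be odd", call. = FALSE)
  kd <- dim(kernels)
  if (length(kd) != 3 || kd[1] != sigma * H || kd[2] != sigma * W ||
      kd[3] != k_up^2) {
    stop(sprintf(
      "kernel field must be %d x %d x %d, got %s",
      sigma * H, sigma * W, k_up^2, paste(kd, collapse = " x ")),
      call. = FALSE)
  }
  r <- (k_up - 1) / 2
  out <- array(0, c(sigma * H, sigma * W, C))
  # source centre per output row/column: floor(l / sigma), 0-based
  src_y <- (seq_len(sigma * H) - 1) %/% sigma + 1
  src_x <- (seq_len(sigma * W) - 1) %/% sigma + 1
  tap <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      tap <- tap + 1L
      yy <- src_y + dy
      xx <- src_x + dx
      ok_y <- yy >= 1 & yy <= H
      ok_x <- xx >= 1 & xx <= W
      if (!any(ok_y) || !any(ok_x)) next
      w <- kernels[, , tap]
      for (ch in seq_len(C)) {
        vals <- matrix(0, sigma * H, sigma * W)
        vals[ok_y, ok_x] <- feat[yy[ok_y], xx[ok_x], ch]
        out[, , ch] <- out[, , ch] + w * vals
      }
    }
  }
  out
}
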