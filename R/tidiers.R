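#' Tidy a tracking result
#'
#' @param x A `mot_tracking` object from [track()].
#' @param ... Unused.
#' @return Tibble `frame, id, left, top, width, height, conf`, one row
#'   per emitted box.
#' @method tidy mot_tracking
#' @export
tidy.mot_tracking <- function(x, ...) x$results

#' One-row summary of a tracking run
#'
#' @param x A `mot_tracking` object.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_boxes`, `n_identities`,
#'   `mean_track_length` (frames per identity).
#' @method glance mot_tracking
#' @export
glance.mot_tracking <- function(x, ...) {
  lens <- table(x$results$id)
  tibble::tibble(
    n_frames = x$frames[2] - x$frames[1] + 1,
    n_boxes = nrow(x$results),
    n_identities = length(lens),
    mean_track_length = if (length(lens)) mean(lens) else NA_real_)
}

#' Tidy an evaluation report
#'
#' @param x A `mot_metrics` object from [evaluate_tracking()].
#' @param ... Unused.
#' @return Long tibble `metric, value` (rates as fractions, counts as
#'   counts).
#' @method tidy mot_metrics
#' @export
tidy.mot_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("MOTA", "MOTP", "IDF1", "FP", "FN", "IDs"),
    value = c(x$mota, x$motp, x$idf1, x$fp, x$fn, x$idsw))
}

#' @rdname tidy.mot_metrics
#' @method glance mot_metrics
#' @export
glance.mot_metrics <- function(x, ...) {
  tibble::tibble(mota = x$mota, motp = x$motp, idf1 = x$idf1,
                 fp = x$fp, fn = x$fn, ids = x$idsw,
                 n_gt = x$n_gt, iou_min = x$iou_min)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
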