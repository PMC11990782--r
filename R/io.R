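#' Read a MOTChallenge detection file
#'
#' Comma-separated rows `frame, id, left, top, width, height, conf, ...`
#' with 1-based pixel coordinates on file, converted to the package's
#' 0-based internal convention. Malformed or non-numeric rows raise an
#' error naming the offending line rather than being skipped.
#'
#' @param path Path to the det file.
#' @return Tibble `frame, left, top, width, height, conf`, sorted by
#'   frame (the id column of det files is ignored).
#' @export
read_mot_detections <- function(path) {
  rows <- parse_mot_rows(path, min_cols = 7)
  tibble::tibble(frame = as.integer(rows[, 1]),
                 left = rows[, 3] - 1, top = rows[, 4] - 1,
                 width = rows[, 5], height = rows[, 6],
                 conf = rows[, 7]) |>
    dplyr::arrange(.data$frame)
}

#' Read a MOTChallenge ground-truth file
#'
#' Rows `frame, id, left, top, width, height, flag, class, visibility`;
#' coordinates converted from 1-based file to 0-based internal.
#'
#' @param path Path to the gt file.
#' @return Tibble `frame, id, left, top, width, height`.
#' @export
read_mot_gt <- function(path) {
  rows <- parse_mot_rows(path, min_cols = 6)
  tibble::tibble(frame = as.integer(rows[, 1]), id = as.integer(rows[, 2]),
                 left = rows[, 3] - 1, top = rows[, 4] - 1,
                 width = rows[, 5], height = rows[, 6]) |>
    dplyr::arrange(.data$frame, .data$id)
}

#' Read a MOTChallenge result file
#'
#' @param path Path to a result file written by [write_mot_results()].
#' @return Tibble `frame, id, left, top, width, height, conf`.
#' @export
read_mot_results <- function(path) {
  rows <- parse_mot_rows(path, min_cols = 7)
  tibble::tibble(frame = as.integer(rows[, 1]), id = as.integer(rows[, 2]),
                 left = rows[, 3] - 1, top = rows[, 4] - 1,
                 width = rows[, 5], height = rows[, 6],
                 conf = rows[, 7]) |>
    dplyr::arrange(.data$frame, .data$id)
}

parse_mot_rows <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(matrix(numeric(0), 0, min_cols))
  out <- matrix(NA_real_, length(lines), min_cols)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < min_cols) {
      stop(sprintf("malformed row at line %d of %s: expected >= %d fields",
                   i, path, min_cols), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[seq_len(min_cols)]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric field at line %d of %s", i, path),
           call. = FALSE)
    }
    out[i, ] <- vals
  }
  out
}

#' Write tracking results in MOTChallenge format
#'
#' Rows `frame,id,left,top,width,height,conf,-1,-1,-1` with `%.2f` box
#' coordinates, 1-based on file, ordered by frame then id. Writing the
#' re-read file again is byte-identical.
#'
#' @param results A `mot_tracking` object or tibble
#'   `frame, id, left, top, width, height, conf`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_mot_results <- function(results, path) {
  if (inherits(results, "mot_tracking")) results <- results$results
  res <- dplyr::arrange(results, .data$frame, .data$id)
  lines <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.2f,-1,-1,-1",
                   res$frame, res$id, res$left + 1, res$top + 1,
                   res$width, res$height, res$conf)
  writeLines(lines, path)
  invisible(path)
}

#' Write detections / ground truth in MOTChallenge format
#'
#' Detections are written with six decimals so a write-read round trip
#' preserves values to well below a pixel.
#'
#' @param detections Tibble from [simulate_scenario()] or
#'   [read_mot_detections()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_mot_detections <- function(detections, path) {
  d <- dplyr::arrange(detections, .data$frame)
  lines <- sprintf("%d,-1,%.6f,%.6f,%.6f,%.6f,%.6f,-1,-1,-1",
                   d$frame, d$left + 1, d$top + 1, d$width, d$height, d$conf)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mot_detections
#' @param gt Ground-truth tibble `frame, id, left, top, width, height`.
#' @export
write_mot_gt <- function(gt, path) {
  g <- dplyr::arrange(gt, .data$frame, .data$id)
  lines <- sprintf("%d,%d,%.6f,%.6f,%.6f,%.6f,1,1,1.0",
                   g$frame, g$id, g$left + 1, g$top + 1, g$width, g$height)
  writeLines(lines, path)
  invisible(path)
}

#' Descriptor sidecar files
#'
#' CSV with header `frame,det_index,v1..vD`; one unit descriptor per
#' detection, `det_index` counting detections within each frame in file
#' order.
#'
#' @param descriptors Tibble as produced by [simulate_scenario()].
#' @param path File path.
#' @return `write_descriptors`: invisibly, the path.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("frame", "det_index") %in% names(d))) {
    stop("descriptor sidecar must have frame and det_index columns",
         call. = FALSE)
  }
  tibble::as_tibble(d)
}

# split a sidecar tibble into per-frame descriptor matrices, keyed by
# frame number as character; rows re-normalized (with a warning) if the
# stored vectors drifted off unit norm
split_descriptors <- function(descriptors) {
  vcols <- grep("^v[0-9]+$", names(descriptors), value = TRUE)
  vcols <- vcols[order(as.integer(sub("v", "", vcols)))]
  m <- as.matrix(descriptors[, vcols, drop = FALSE])
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("descriptors not unit norm; re-normalizing", call. = FALSE)
    m <- m / pmax(nrm, 1e-12)
  }
  lapply(split(seq_len(nrow(m)), descriptors$frame), function(idx) {
    m[idx[order(descriptors$det_index[idx])], , drop = FALSE]
  })
}

#' Read one frame of a PNG image sequence
#'
#' Sequences are directories of files named by 6-digit frame number
#' (`000001.png`, ...).
#'
#' @param dir Directory path.
#' @param frame 1-based frame number.
#' @return Grey-level matrix, or NULL if the file does not exist.
#' @export
read_frame_png <- function(dir, frame) {
  path <- file.path(dir, sprintf("%06d.png", frame))
  if (!file.exists(path)) return(NULL)
  as_gray_frame(png::readPNG(path))
}

#' Write a scenario to disk in the package's exchange formats
#'
#' Emits `gt.txt` and `det.txt` (MOTChallenge), `descriptors.csv`
#' (sidecar), optionally a `frames/` PNG sequence, and a YAML manifest
#' of the generating configuration.
#'
#' @param scenario A `mot_scenario`.
#' @param dir Output directory (created if needed).
#' @param frames Optional rendered frames ([render_frames()]) to write.
#' @return Invisibly, `dir`.
#' @export
write_scenario <- function(scenario, dir, frames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mot_gt(scenario$gt, file.path(dir, "gt.txt"))
  write_mot_detections(scenario$detections, file.path(dir, "det.txt"))
  write_descriptors(scenario$descriptors, file.path(dir, "descriptors.csv"))
  if (!is.null(frames)) {
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    for (f in seq_along(frames)) {
      png::writePNG(frames[[f]] / 255,
                    file.path(fdir, sprintf("%06d.png", f)))
    }
  }
  cfg <- scenario$config
  cfg_out <- lapply(unclass(cfg), function(x) if (length(x) == 1) x else
    as.list(x))
  yaml::write_yaml(cfg_out, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# -- YAML configuration ----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1,
    tracker = list(n_init = 3, max_age = 30, lambda = 0,
                   motion_gate = chi2_gate(), gallery_budget = 100,
                   use_cmc = TRUE, use_cos = TRUE),
    noise = list(std_weight_position = 1 / 20,
                 std_weight_velocity = 1 / 160),
    tier = list(tau_high = 0.6, tau_low = 0.3, tau_discard = 0.1,
                thr_high = 0.2, thr_medium = 0.3, thr_low = 0.5),
    cmc = list(fast_threshold = 20, max_keypoints = 500, lowe_ratio = 0.75,
               max_shift_frac = 0.10, ransac_threshold = 3,
               ransac_conf = 0.995, ransac_max_iter = 500, min_pairs = 8,
               mask_margin = 0.1, mask_above_horizon = TRUE,
               apply = "position_only", add_qn = TRUE),
    scenario = lapply(unclass(scenario_config()), function(x)
      if (length(x) == 1) x else as.list(x)))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their documented
#' defaults. The configuration covers the tracker, Kalman noise,
#' confidence tiers, camera motion compensation and the synthetic
#' scenario generator.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Nested configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(normalize_config(cfg), class = "run_config")
}

# YAML renders length-2 numeric fields as lists; fold unnamed scalar
# lists back into vectors so load(dump(cfg)) = cfg
normalize_config <- function(x) {
  if (!is.list(x)) return(x)
  if (is.null(names(x)) && length(x) &&
      all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE))) {
    return(unlist(x))
  }
  lapply(x, normalize_config)
}

#' Build a [tracker_config()] from a run configuration
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @return A [tracker_config()].
#' @export
as_tracker_config <- function(cfg) {
  tiers <- cfg$tier
  tracker_config(
    n_init = cfg$tracker$n_init, max_age = cfg$tracker$max_age,
    lambda = cfg$tracker$lambda, motion_gate = cfg$tracker$motion_gate,
    gallery_budget = cfg$tracker$gallery_budget,
    tier = tier_config(tiers$tau_high, tiers$tau_low, tiers$tau_discard,
                       tiers$thr_high, tiers$thr_medium, tiers$thr_low),
    noise = kf_noise(cfg$noise$std_weight_position,
                     cfg$noise$std_weight_velocity),
    cmc = do.call(cmc_params, cfg$cmc),
    use_cmc = cfg$tracker$use_cmc, use_cos = cfg$tracker$use_cos)
}

#' @rdname as_tracker_config
#' @export
as_scenario_config <- function(cfg) {
  sc <- cfg$scenario
  sc <- lapply(sc, function(x) if (is.list(x)) unlist(x) else x)
  do.call(scenario_config, sc)
}
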