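#' Process/measurement noise configuration for the Kalman tracker
#'
#' The tracker uses an 8-dimensional constant-velocity state
#' `(x, y, gamma, h, vx, vy, vgamma, vh)`: box centre in pixels, aspect
#' ratio `gamma = w/h` (unitless), box height `h` in pixels, and their
#' per-frame rates of change. All position/size standard deviations are
#' proportional to the current box height `h`, the convention of the
#' Deep SORT family of trackers, so that uncertainty scales with apparent
#' target size (i.e. with flight altitude).
#'
#' @param std_weight_position Unitless scale of positional noise std;
#'   per-frame position std is `std_weight_position * h`. Default 1/20.
#' @param std_weight_velocity Unitless scale of velocity noise std;
#'   per-frame velocity std is `std_weight_velocity * h`. Default 1/160.
#' @return A list of class `kf_noise`.
#' @export
kf_noise <- function(std_weight_position = 1 / 20,
                     std_weight_velocity = 1 / 160) {
  if (!is.numeric(std_weight_position) || std_weight_position <= 0 ||
      !is.numeric(std_weight_velocity) || std_weight_velocity <= 0) {
    stop("noise weights must be strictly positive", call. = FALSE)
  }
  structure(list(std_weight_position = std_weight_position,
                 std_weight_velocity = std_weight_velocity),
            class = "kf_noise")
}

#' Observation model mapping state to measurement space
#'
#' A 4x8 selector picking `(x, y, gamma, h)` out of the 8-dimensional
#' state.
#'
#' @return A 4x8 matrix with exactly four unit entries.
#' @export
kf_observation_matrix <- function() {
  cbind(diag(4), matrix(0, 4, 4))
}

# constant-velocity transition, dt = 1 frame
kf_transition_matrix <- function() {
  f <- diag(8)
  f[cbind(1:4, 5:8)] <- 1
  f
}

kf_check_measurement <- function(measurement) {
  if (!is.numeric(measurement) || length(measurement) != 4 ||
      any(!is.finite(measurement))) {
    stop("measurement must be a finite numeric 4-vector (x, y, gamma, h)",
         call. = FALSE)
  }
  if (measurement[4] <= 0) stop("invalid measurement: height must be > 0",
                                call. = FALSE)
  if (measurement[3] <= 0) stop("invalid measurement: aspect ratio must be > 0",
                                call. = FALSE)
  invisible(measurement)
}

new_track_state <- function(mean, cov) {
  # symmetrize to control floating-point drift
  cov <- (cov + t(cov)) / 2
  list(mean = as.numeric(mean), cov = cov)
}

#' Initiate a Kalman track state from a first measurement
#'
#' Velocities start at zero; the covariance is diagonal with position/size
#' stds proportional to the measured height and inflated velocity stds,
#' reflecting that a single observation carries no velocity information.
#'
#' @param measurement Numeric 4-vector `(x, y, gamma, h)`.
#' @param noise A [kf_noise()] configuration.
#' @return A track state: list with `mean` (length 8) and `cov` (8x8).
#' @export
kf_initiate <- function(measurement, noise = kf_noise()) {
  kf_check_measurement(measurement)
  h <- measurement[4]
  wp <- noise$std_weight_position
  wv <- noise$std_weight_velocity
  std <- c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
           10 * wv * h, 10 * wv * h, 1e-5, 10 * wv * h)
  new_track_state(c(measurement, rep(0, 4)), diag(std^2))
}

kf_process_noise <- function(h, noise) {
  wp <- noise$std_weight_position
  wv <- noise$std_weight_velocity
  std <- c(wp * h, wp * h, 1e-2, wp * h,
           wv * h, wv * h, 1e-5, wv * h)
  diag(std^2)
}

#' One constant-velocity prediction step
#'
#' `mean' = F mean`, `cov' = F P F^T + Q` with `F` the dt = 1 constant
#' velocity transition and `Q` diagonal process noise whose stds scale
#' with the current box height.
#'
#' @param state A track state from [kf_initiate()] or a previous step.
#' @param noise A [kf_noise()] configuration.
#' @return The predicted (prior) track state.
#' @export
kf_predict <- function(state, noise = kf_noise()) {
  f <- kf_transition_matrix()
  q <- kf_process_noise(state$mean[4], noise)
  new_track_state(f %*% state$mean, f %*% state$cov %*% t(f) + q)
}

#' Project a state into measurement space
#'
#' Returns the predicted measurement distribution `(H mean, H P H^T + R)`
#' consumed by the Mahalanobis association cost; `R` is diagonal
#' measurement noise with stds proportional to height.
#'
#' @inheritParams kf_predict
#' @param obs Observation matrix, default [kf_observation_matrix()].
#' @return List with `mean` (length 4) and `cov` (4x4).
#' @export
kf_project <- function(state, noise = kf_noise(),
                       obs = kf_observation_matrix()) {
  h <- state$mean[4]
  wp <- noise$std_weight_position
  std <- c(wp * h, wp * h, 1e-1, wp * h)
  r <- diag(std^2)
  s <- obs %*% state$cov %*% t(obs) + r
  list(mean = as.numeric(obs %*% state$mean), cov = (s + t(s)) / 2)
}

#' Kalman measurement update
#'
#' Standard gain-form correction: `K = P H^T S^{-1}`,
#' `mean'' = mean' + K (z - H mean')`, `P'' = (I - K H) P'`. The innovation
#' covariance `S` is inverted via Cholesky; a singular `S` raises an error
#' rather than continuing with a broken state.
#'
#' @inheritParams kf_project
#' @param measurement Numeric 4-vector `(x, y, gamma, h)`.
#' @return The posterior track state.
#' @export
kf_update <- function(state, measurement, noise = kf_noise(),
                      obs = kf_observation_matrix()) {
  kf_check_measurement(measurement)
  proj <- kf_project(state, noise, obs)
  ch <- tryCatch(chol(proj$cov), error = function(e) NULL)
  if (is.null(ch)) {
    stop("numerical failure: singular innovation covariance in Kalman update",
         call. = FALSE)
  }
  k <- t(backsolve(ch, forwardsolve(t(ch), obs %*% state$cov)))
  innov <- measurement - proj$mean
  mean_post <- state$mean + as.numeric(k %*% innov)
  cov_post <- (diag(8) - k %*% obs) %*% state$cov
  new_track_state(mean_post, cov_post)
}

#' Convert between boxes and Kalman measurements
#'
#' A detection box `(left, top, width, height)` maps to the measurement
#' `(cx, cy, w/h, h)` and back.
#'
#' @param box Numeric 4-vector `(left, top, width, height)`.
#' @return `box_to_measurement`: numeric 4-vector `(x, y, gamma, h)`.
#' @export
box_to_measurement <- function(box) {
  c(box[1] + box[3] / 2, box[2] + box[4] / 2, box[3] / box[4], box[4])
}

#' @rdname box_to_measurement
#' @param z Numeric 4-vector `(x, y, gamma, h)`.
#' @export
measurement_to_box <- function(z) {
  w <- z[3] * z[4]
  c(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}
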