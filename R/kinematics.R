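#' Interior angle at a joint via the vector-cosine method
#'
#' The angle at `vertex` subtended by points `a` and `b`:
#' `acos(u.v / (|u||v|))` with `u = a - vertex`, `v = b - vertex`, returned
#' in degrees and clamped into [0, 180] against floating-point overshoot.
#' Being a function of vector directions only, the result is invariant to
#' translation, rotation, uniform scaling, and the image y-axis direction.
#'
#' @param vertex,a,b length-2 numeric vectors (x, y).
#' @return angle in degrees in [0, 180].
#' @export
joint_angle <- function(vertex, a, b) {
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("Degenerate geometry: coincident landmarks at the joint.",
          class = "gaitloop_error_geometry")
  }
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Signed pendulum (limb-axis) angle
#'
#' Angle of the hip-to-MTP vector relative to the downward vertical through
#' the hip, in image coordinates (y grows downward): positive when the MTP
#' is anterior to the hip (toward the direction of travel), negative when
#' posterior. Its per-cycle extrema mark touch-down (maximal protraction)
#' and lift-off (maximal retraction).
#'
#' @param hip,mtp length-2 numeric vectors (x, y) in image coordinates.
#' @param direction +1 if travel is toward +x, -1 otherwise.
#' @return signed angle in degrees in (-180, 180].
#' @export
pendulum_angle <- function(hip, mtp, direction = 1) {
  d <- mtp - hip
  if (all(d == 0)) {
    abort("Degenerate geometry: MTP coincident with hip.",
          class = "gaitloop_error_geometry")
  }
  atan2(direction * d[1], d[2]) * 180 / pi
}

#' Per-frame joint angles, pendulum angle and validity from a session
#'
#' Computes, for every frame: the hip angle (at the hip, subtended by iliac
#' crest and knee), knee angle (at the knee, by hip and ankle), ankle angle
#' (at the ankle, by knee and MTP), the signed pendulum angle of the
#' hip-to-MTP axis, the minimum landmark likelihood, and a validity flag.
#' A frame is valid when all five landmark likelihoods are at or above
#' `likelihood_threshold` (frames strictly below 0.8 are conventionally
#' treated as unreliable); degenerate geometry also invalidates a frame.
#'
#' @param session a `gait_session`.
#' @param likelihood_threshold minimum acceptable landmark likelihood
#'   (default 0.8; a frame at exactly the threshold is valid).
#' @return tibble with columns `frame`, `hip_deg`, `knee_deg`, `ankle_deg`,
#'   `pendulum_deg`, `min_likelihood`, `valid`.
#' @export
compute_angles <- function(session, likelihood_threshold = 0.8) {
  dir <- session_direction(session)
  s <- as.data.frame(session)
  ang3 <- function(vx, vy, ax, ay, bx, by) {
    ux <- ax - vx; uy <- ay - vy
    wx <- bx - vx; wy <- by - vy
    nu <- sqrt(ux^2 + uy^2)
    nw <- sqrt(wx^2 + wy^2)
    cosang <- (ux * wx + uy * wy) / (nu * nw)
    out <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    out[nu == 0 | nw == 0] <- NA_real_
    out
  }
  hip <- ang3(s$hip_x, s$hip_y, s$iliac_crest_x, s$iliac_crest_y,
              s$knee_x, s$knee_y)
  knee <- ang3(s$knee_x, s$knee_y, s$hip_x, s$hip_y, s$ankle_x, s$ankle_y)
  ankle <- ang3(s$ankle_x, s$ankle_y, s$knee_x, s$knee_y, s$mtp_x, s$mtp_y)
  dx <- s$mtp_x - s$hip_x
  dy <- s$mtp_y - s$hip_y
  pend <- atan2(dir * dx, dy) * 180 / pi
  pend[dx == 0 & dy == 0] <- NA_real_
  lik <- pmin(s$iliac_crest_likelihood, s$hip_likelihood, s$knee_likelihood,
              s$ankle_likelihood, s$mtp_likelihood)
  valid <- lik >= likelihood_threshold &
    !is.na(hip) & !is.na(knee) & !is.na(ankle) & !is.na(pend)
  tibble::tibble(frame = s$frame, hip_deg = hip, knee_deg = knee,
                 ankle_deg = ankle, pendulum_deg = pend,
                 min_likelihood = lik, valid = valid)
}
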