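# Ballistic reconstruction of escape jumps from horizontal displacement and
# airborne time, assuming level take-off and landing and no air resistance.

#' Gravitational acceleration used throughout (m/s^2)
#'
#' The analyses use g = 9.8 m/s^2 exactly.
#' @export
GRAVITY <- 9.8

#' Reconstruct jump kinematics from displacement and airborne time
#'
#' Given the horizontal displacement of a jump (take-off to landing, metres)
#' and the time spent airborne (seconds), recovers the take-off velocity
#' vector under level projectile motion:
#' \deqn{v_h = d / t, \quad v_v = g t / 2,}
#' \deqn{speed = \sqrt{v_h^2 + v_v^2}, \quad angle = \arctan(v_v / v_h) \cdot 180/\pi,}
#' \deqn{height = v_v^2 / (2 g).}
#' Jump height depends only on airborne time (\eqn{g t^2 / 8}).
#'
#' A displacement of exactly zero is a purely vertical jump and yields a
#' 90-degree take-off angle.
#'
#' @param displacement_m horizontal displacement in metres (vector, >= 0)
#' @param airborne_s airborne time in seconds (vector, > 0)
#' @param g gravitational acceleration, m/s^2
#' @return data.frame with columns `v_h`, `v_v`, `takeoff_speed`,
#'   `takeoff_angle_deg`, `jump_height_m`
#' @examples
#' compute_kinematics(0.4, 0.2)
#' @export
compute_kinematics <- function(displacement_m, airborne_s, g = GRAVITY) {
  stopifnot(is.numeric(displacement_m), is.numeric(airborne_s))
  n <- max(length(displacement_m), length(airborne_s))
  displacement_m <- rep_len(displacement_m, n)
  airborne_s <- rep_len(airborne_s, n)
  ok <- !is.na(displacement_m) & !is.na(airborne_s)
  if (any(airborne_s[ok] <= 0))
    stop("airborne_s must be > 0")
  if (any(displacement_m[ok] < 0))
    stop("displacement_m must be >= 0")
  v_h <- displacement_m / airborne_s
  v_v <- g * airborne_s / 2
  speed <- sqrt(v_h^2 + v_v^2)
  angle <- atan2(v_v, v_h) * 180 / pi
  height <- v_v^2 / (2 * g)
  data.frame(
    v_h = v_h, v_v = v_v,
    takeoff_speed = speed,
    takeoff_angle_deg = angle,
    jump_height_m = height
  )
}

#' Forward ballistics: displacement and airborne time from speed and angle
#'
#' Exact inverse of [compute_kinematics()]: for a take-off speed \eqn{v} and
#' angle \eqn{\theta} (degrees above horizontal),
#' \eqn{t = 2 v \sin\theta / g} and \eqn{d = v \cos\theta \cdot t}.
#' An angle of 90 degrees gives zero displacement.
#'
#' @param speed take-off speed, m/s (> 0)
#' @param angle_deg take-off angle in degrees, in (0, 90]
#' @param g gravitational acceleration, m/s^2
#' @return data.frame with columns `displacement_m`, `airborne_s`
#' @export
forward_ballistics <- function(speed, angle_deg, g = GRAVITY) {
  stopifnot(is.numeric(speed), is.numeric(angle_deg))
  n <- max(length(speed), length(angle_deg))
  speed <- rep_len(speed, n)
  angle_deg <- rep_len(angle_deg, n)
  ok <- !is.na(speed) & !is.na(angle_deg)
  if (any(speed[ok] <= 0))
    stop("speed must be > 0")
  if (any(angle_deg[ok] <= 0 | angle_deg[ok] > 90))
    stop("angle_deg must lie in (0, 90]")
  theta <- angle_deg * pi / 180
  t <- 2 * speed * sin(theta) / g
  d <- speed * cos(theta) * t
  data.frame(displacement_m = d, airborne_s = t)
}

#' Convert a frame count to milliseconds
#'
#' One frame lasts `1000 / fps` ms: 8.3 ms at 120 fps (ground-squirrel
#' video), 4.0-4.2 ms at 240-250 fps.
#'
#' @param frames number of frames (>= 0)
#' @param fps recording frame rate, frames per second (> 0)
#' @return time in milliseconds
#' @export
frames_to_ms <- function(frames, fps) {
  stopifnot(is.numeric(frames), is.numeric(fps))
  if (any(fps <= 0, na.rm = TRUE)) stop("fps must be > 0")
  if (any(frames < 0, na.rm = TRUE)) stop("frames must be >= 0")
  frames * 1000 / fps
}

#' Down-sample frame indices to a lower frame rate
#'
#' Maps an index at the source rate to `floor(i / factor)` at the target
#' rate (e.g. 500 fps footage reduced to 250 fps, factor 2). Event order is
#' preserved and event times move by less than one target-frame period.
#'
#' @param frame_indices integer frame indices at the source rate
#' @param source_fps source frame rate
#' @param target_fps target frame rate; must divide `source_fps`
#' @return integer indices at the target rate
#' @export
downsample_frames <- function(frame_indices, source_fps, target_fps) {
  stopifnot(is.numeric(frame_indices), source_fps > 0, target_fps > 0)
  factor <- source_fps / target_fps
  if (abs(factor - round(factor)) > 1e-9)
    stop("source_fps must be an integer multiple of target_fps")
  as.integer(floor(frame_indices / round(factor)))
}

#' Reaction, take-off and overall response times from event frames
#'
#' Reaction time runs from the first movement of the cork to the first
#' visible movement of the animal; take-off time from that first movement to
#' the frame immediately preceding toe-off (for scrambles, the last frame
#' with the hind feet on the ground). Overall response time is their sum.
#' A reaction frame before the cork frame corresponds to a premature
#' reaction and is rejected.
#'
#' @param cork_frame frame of first cork movement
#' @param reaction_frame frame of first visible movement of the animal
#' @param toeoff_frame frame immediately preceding toe-off
#' @param fps recording frame rate
#' @return list with `reaction_ms`, `takeoff_ms`, `overall_ms`
#' @export
timing_from_frames <- function(cork_frame, reaction_frame, toeoff_frame, fps) {
  if (any(reaction_frame < cork_frame))
    stop("reaction_frame precedes cork_frame (premature reaction)")
  if (any(toeoff_frame < reaction_frame))
    stop("toeoff_frame precedes reaction_frame")
  reaction <- frames_to_ms(reaction_frame - cork_frame, fps)
  takeoff <- frames_to_ms(toeoff_frame - reaction_frame, fps)
  list(reaction_ms = reaction, takeoff_ms = takeoff,
       overall_ms = reaction + takeoff)
}
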