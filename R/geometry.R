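# Linkage kinematics of the 1-DOF powered ankle-foot orthosis (PAFO).
#
# The orthosis actuates the ankle through a ball screw connecting two rigid
# parts with three revolute joints (R1 = ankle, R2, R3) and one prismatic
# joint. The joint triangle has sides l1 (R1-R2), l2 (R1-R3) and
# l3 (R2-R3), with l3^2 = lscrew^2 + lR3^2 where lscrew is the ball-nut
# travel and lR3 the moment arm at R3.

#' Linkage geometry of the PAFO ball-screw drive
#'
#' @param l1 distance R1-R2 in metres.
#' @param l2 distance R1-R3 in metres.
#' @param lR3 moment arm of joint R3 in metres.
#' @param theta_P1 fixed structural angle of the shank part, radians.
#' @param screw_lead ball-screw lead in metres per revolution.
#' @param screw_travel_limits numeric length-2, admissible ball-nut travel
#'   `c(min, max)` in metres.
#'
#' The defaults place a +/-30 degree ankle range inside roughly 60 mm of
#' travel of a 2 mm-lead screw; linkage lengths are configurable because
#' they depend on the physical build.
#'
#' @return an object of class `linkage_geometry`.
#' @export
linkage_geometry <- function(l1 = 0.25, l2 = 0.06, lR3 = 0.03,
                             theta_P1 = 0.35, screw_lead = 0.002,
                             screw_travel_limits = c(0.224, 0.284)) {
  stopifnot(l1 > 0, l2 > 0, lR3 > 0, screw_lead > 0,
            length(screw_travel_limits) == 2,
            screw_travel_limits[1] < screw_travel_limits[2])
  geom <- structure(
    list(l1 = l1, l2 = l2, lR3 = lR3, theta_P1 = theta_P1,
         screw_lead = screw_lead,
         screw_travel_limits = as.numeric(screw_travel_limits)),
    class = "linkage_geometry"
  )
  # triangle inequality must hold at both travel extremes
  for (ls in screw_travel_limits) {
    l3 <- sqrt(ls^2 + lR3^2)
    if (!(abs(l1 - l2) < l3 && l3 < l1 + l2)) {
      abort(sprintf(
        "screw travel %.4f m breaks the linkage triangle inequality", ls),
        "hybridgait_geometry_error")
    }
  }
  geom
}

#' @export
print.linkage_geometry <- function(x, ...) {
  cat("PAFO linkage geometry\n")
  cat(sprintf("  l1 = %.4f m, l2 = %.4f m, lR3 = %.4f m\n", x$l1, x$l2, x$lR3))
  cat(sprintf("  theta_P1 = %.3f rad, screw lead = %.4f m/rev\n",
              x$theta_P1, x$screw_lead))
  cat(sprintf("  travel limits = [%.4f, %.4f] m\n",
              x$screw_travel_limits[1], x$screw_travel_limits[2]))
  invisible(x)
}

check_travel <- function(geom, lscrew) {
  lim <- geom$screw_travel_limits
  if (any(lscrew < lim[1] - 1e-12 | lscrew > lim[2] + 1e-12)) {
    abort("lscrew outside screw travel limits", "hybridgait_travel_error")
  }
}

#' Ankle angle from ball-screw travel
#'
#' Forward kinematics of the linkage: the ankle joint angle is recovered from
#' the joint triangle by the law of cosines,
#' `theta = acos((l1^2 + l2^2 - lscrew^2 - lR3^2) / (2 l1 l2)) + theta_P1`.
#'
#' @param geom a [linkage_geometry()].
#' @param lscrew ball-nut travel in metres (vectorised).
#' @return ankle angle theta in radians.
#' @export
ankle_angle_from_screw <- function(geom, lscrew) {
  check_travel(geom, lscrew)
  arg <- (geom$l1^2 + geom$l2^2 - lscrew^2 - geom$lR3^2) /
    (2 * geom$l1 * geom$l2)
  if (any(arg < -1 - 1e-12 | arg > 1 + 1e-12)) {
    abort("linkage cosine argument outside [-1, 1]; geometry/travel mismatch",
          "hybridgait_domain_error")
  }
  acos(clamp(arg, -1, 1)) + geom$theta_P1
}

#' Ball-screw travel from ankle angle
#'
#' Closed-form inverse of [ankle_angle_from_screw()]:
#' `lscrew^2 = l1^2 + l2^2 - lR3^2 - 2 l1 l2 cos(theta - theta_P1)`.
#'
#' @param geom a [linkage_geometry()].
#' @param theta ankle angle in radians (vectorised).
#' @return ball-nut travel in metres.
#' @export
screw_from_ankle_angle <- function(geom, theta) {
  ls2 <- geom$l1^2 + geom$l2^2 - geom$lR3^2 -
    2 * geom$l1 * geom$l2 * cos(theta - geom$theta_P1)
  if (any(ls2 < 0)) {
    abort("angle unreachable: no real screw travel satisfies the linkage",
          "hybridgait_unreachable_error")
  }
  ls <- sqrt(ls2)
  lim <- geom$screw_travel_limits
  if (any(ls < lim[1] - 1e-9 | ls > lim[2] + 1e-9)) {
    abort("angle unreachable within screw travel limits",
          "hybridgait_unreachable_error")
  }
  ls
}

#' External ankle torque from the shank load cell
#'
#' Maps the interaction force between shank and orthosis, measured by the
#' load cell in the shank part, to torque about the ankle joint R1 through
#' the linkage:
#' `tau_ext = F * l1 * sin(acos((l2^2+l3^2-l1^2)/(2 l2 l3)) + atan2(lscrew, lR3) - theta_P1)
#'          * cos(acos((l1^2+l3^2-l2^2)/(2 l1 l3)) + atan2(lR3, lscrew) - pi/2)`
#' with `l3 = sqrt(lscrew^2 + lR3^2)`. The first factor projects the sensed
#' force onto the screw axis; the second is the normalised moment arm of a
#' screw-axis force about R1.
#'
#' @param geom a [linkage_geometry()].
#' @param lscrew ball-nut travel in metres.
#' @param F_sensor load-cell force in newtons (vectorised).
#' @return external torque about the ankle, newton-metres.
#' @export
external_torque <- function(geom, lscrew, F_sensor) {
  check_travel(geom, lscrew)
  l1 <- geom$l1; l2 <- geom$l2; lR3 <- geom$lR3
  l3 <- sqrt(lscrew^2 + lR3^2)
  a1 <- (l2^2 + l3^2 - l1^2) / (2 * l2 * l3)
  a2 <- (l1^2 + l3^2 - l2^2) / (2 * l1 * l3)
  if (any(abs(a1) > 1 + 1e-12) || any(abs(a2) > 1 + 1e-12)) {
    abort("linkage cosine argument outside [-1, 1]; geometry/travel mismatch",
          "hybridgait_domain_error")
  }
  ang1 <- acos(clamp(a1, -1, 1)) + atan2(lscrew, lR3) - geom$theta_P1
  ang2 <- acos(clamp(a2, -1, 1)) + atan2(lR3, lscrew) - pi / 2
  F_sensor * l1 * sin(ang1) * cos(ang2)
}

#' Gravity torque of the foot segment
#'
#' Point-mass pendulum model of the foot about the ankle:
#' `tau_g = -m g l sin(theta_abs)` where `theta_abs` is the foot-segment
#' angle measured from the downward vertical. Used both for the true plant
#' gravity torque and (with possibly perturbed parameters) for the
#' controller's gravity-compensation estimate.
#'
#' @param foot_mass foot (plus attached orthosis) mass, kg.
#' @param com_distance distance from ankle to segment centre of mass, m.
#' @param theta_abs foot segment angle from vertical, radians (vectorised).
#' @param g gravitational acceleration, m/s^2.
#' @return gravity torque, newton-metres (angle convention).
#' @export
gravity_torque <- function(foot_mass, com_distance, theta_abs, g = 9.81) {
  stopifnot(foot_mass >= 0, com_distance >= 0)
  -foot_mass * g * com_distance * sin(theta_abs)
}
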