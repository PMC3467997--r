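#' Grood-Suntay joint pose
#'
#' Construct a tibiofemoral joint pose in the Grood-Suntay joint coordinate
#' system (JCS): flexion about the femur-fixed medial-lateral axis,
#' internal-external rotation about the tibia-fixed long axis, varus-valgus
#' about the mutually perpendicular floating axis, plus the three JCS
#' translations. Conventions (right knee): anterior tibial translation
#' positive, internal rotation positive, varus positive, distraction positive.
#' Flexion is the prescribed coordinate during a laxity test; the other five
#' are free.
#'
#' @param flexion flexion angle, degrees (0 = full extension)
#' @param vv varus(+)/valgus(-) rotation, degrees
#' @param ie internal(+)/external(-) rotation, degrees
#' @param ap anterior(+)/posterior(-) translation, mm
#' @param ml medial-lateral translation (lateral positive), mm
#' @param dc distraction(+)/compression(-) translation, mm
#' @return a named numeric vector of class `joint_pose`
#' @export
joint_pose <- function(flexion = 0, vv = 0, ie = 0, ap = 0, ml = 0, dc = 0) {
  p <- c(flexion = flexion, vv = vv, ie = ie, ap = ap, ml = ml, dc = dc)
  class(p) <- "joint_pose"
  p
}

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Rigid transform of the tibia relative to the femur from a joint pose
#'
#' Floating-axis composition: flexion about the femoral fixed axis (global Z,
#' pointing laterally for a right knee), then varus-valgus about the floating
#' axis, then internal-external rotation about the tibial long axis (tibial
#' Y). Translations act along the (generally non-orthogonal) JCS axes
#' e1 = femoral Z, e3 = tibial long axis, e2 = floating axis.
#'
#' @param pose a [joint_pose()]
#' @return list with rotation matrix `R` (tibia -> femur) and translation `t`
#'   (position of the tibial frame origin in the femoral frame), class
#'   `rigid_transform`
#' @export
pose_to_transform <- function(pose) {
  fl <- pose[["flexion"]]
  if (fl < -1e-9 || fl > 150 + 1e-9)
    stop("flexion angle out of the supported 0-150 degree range: ", fl)
  vv <- deg2rad(pose[["vv"]])
  if (abs(pose[["vv"]]) >= 90)
    stop("varus-valgus at +/-90 degrees is a JCS gimbal degeneracy")
  ie <- deg2rad(pose[["ie"]])
  a <- -deg2rad(fl)  # +flexion carries the distal tibia posteriorly
  R <- rot_z(a) %*% rot_x(vv) %*% rot_y(ie)
  ax <- jcs_axes(R)
  t <- pose[["ml"]] * ax$e1 + pose[["ap"]] * ax$e2 - pose[["dc"]] * ax$e3
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' JCS axes for a given tibia-to-femur rotation
#'
#' @param R 3x3 rotation matrix (tibia -> femur)
#' @return list of unit vectors in the femoral frame: `e1` femoral
#'   flexion axis, `e3` tibial long axis, `e2` floating axis
#' @export
jcs_axes <- function(R) {
  e1 <- c(0, 0, 1)
  e3 <- R[, 2]
  e2 <- normalize(cross3(e3, e1))
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Decompose a rigid transform into Grood-Suntay coordinates
#'
#' Inverse of [pose_to_transform()]; exact up to numerical precision away
#' from the varus-valgus gimbal degeneracy.
#'
#' @param tf a `rigid_transform`
#' @return a [joint_pose()]
#' @export
transform_to_pose <- function(tf) {
  R <- tf$R
  sb <- max(-1, min(1, R[3, 2]))
  if (abs(sb) > 1 - 1e-9)
    stop("varus-valgus at +/-90 degrees: JCS decomposition is degenerate")
  b <- asin(sb)
  a <- atan2(-R[1, 2], R[2, 2])
  G <- t(rot_z(a) %*% rot_x(b)) %*% R
  g <- atan2(G[1, 3], G[1, 1])
  ax <- jcs_axes(R)
  coef <- solve(cbind(ax$e1, ax$e2, ax$e3), tf$t)
  joint_pose(flexion = rad2deg(-a), vv = rad2deg(b), ie = rad2deg(g),
             ap = coef[2], ml = coef[1], dc = -coef[3])
}

apply_transform <- function(tf, pts) {
  # pts: n x 3 matrix of tibia-frame points -> femur frame
  pts %*% t(tf$R) + matrix(tf$t, nrow(pts), 3, byrow = TRUE)
}

#' Laxity load case
#'
#' @param type one of `"AP"` (anterior-posterior drawer force, N), `"IE"`
#'   (internal-external moment about the tibial long axis, Nm), `"VV"`
#'   (varus-valgus moment about the joint anterior-posterior axis, Nm)
#' @param amplitude signed load amplitude (N for AP, Nm for IE/VV)
#' @return list of class `load_case`
#' @export
load_case <- function(type = c("AP", "IE", "VV"), amplitude) {
  type <- match.arg(type)
  structure(list(type = type, amplitude = amplitude), class = "load_case")
}

#' Generalized load for a laxity test
#'
#' Expresses a load case both as a wrench (force and moment about the joint
#' centre, femoral frame) and as the generalized force vector conjugate to
#' the five free JCS coordinates. The AP drawer force acts along the joint
#' AP (floating) axis through the centre of the tibial plateau, so it
#' produces no moment about that axis; IE and VV moments are pure couples
#' about the tibial long axis and the joint AP axis respectively.
#'
#' @param case a [load_case()]
#' @param pose the current [joint_pose()] (the JCS axes are pose dependent)
#' @return list with `force` (N), `moment` (N mm), both length-3 in the
#'   femoral frame, and `generalized`: named vector (vv, ie, ap, ml, dc) of
#'   conjugate generalized forces (N mm per radian for rotations, N for
#'   translations)
#' @export
generalized_load <- function(case, pose = joint_pose()) {
  stopifnot(inherits(case, "load_case"))
  ax <- jcs_axes(pose_to_transform(pose)$R)
  gen <- c(vv = 0, ie = 0, ap = 0, ml = 0, dc = 0)
  force <- c(0, 0, 0); moment <- c(0, 0, 0)
  if (case$type == "AP") {
    force <- case$amplitude * ax$e2
    gen[["ap"]] <- case$amplitude
  } else if (case$type == "IE") {
    m <- case$amplitude * 1000  # Nm -> N mm
    moment <- m * ax$e3
    gen[["ie"]] <- m
  } else {
    m <- case$amplitude * 1000
    moment <- m * ax$e2
    gen[["vv"]] <- m
  }
  list(force = force, moment = moment, generalized = gen)
}

#' @export
print.joint_pose <- function(x, ...) {
  cat(sprintf(
    "joint pose: flexion %.2f deg | vv %+.3f deg | ie %+.3f deg | ap %+.3f mm | ml %+.3f mm | dc %+.3f mm\n",
    x[["flexion"]], x[["vv"]], x[["ie"]], x[["ap"]], x[["ml"]], x[["dc"]]))
  invisible(x)
}
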