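#' Nonlinear ligament force-strain law
#'
#' Piecewise tension-strain relation used for every ligament bundle: a
#' quadratic low-stiffness toe region for small strains, a linear region
#' beyond, and zero tension for slack bundles,
#' \deqn{f(\epsilon) = \frac{1}{4} k \epsilon^2 / c \quad (0 \le \epsilon \le 2c),
#'       \qquad f(\epsilon) = k(\epsilon - c) \quad (\epsilon > 2c),
#'       \qquad f(\epsilon) = 0 \quad (\epsilon < 0).}
#' Both branches equal \eqn{kc} at \eqn{\epsilon = 2c}, so the law is
#' continuous (and C1) and non-decreasing.
#'
#' @param eps strain (dimensionless), vectorized
#' @param k bundle stiffness parameter, N
#' @param c toe-region constant (dimensionless, default 0.03)
#' @return tension, N (same length as `eps`)
#' @export
force_from_strain <- function(eps, k, c = 0.03) {
  stopifnot(all(k > 0), all(c > 0))
  f <- ifelse(eps < 0, 0,
       ifelse(eps <= 2 * c, 0.25 * k * eps^2 / c, k * (eps - c)))
  as.numeric(f)
}

# strain-energy density per unit zero-load length: integral of f over strain.
# dU/dL = f with U(L) = L0 * strain_energy_density(eps).
strain_energy_density <- function(eps, k, c) {
  ifelse(eps < 0, 0,
  ifelse(eps <= 2 * c, k * eps^3 / (12 * c),
         k * (2 / 3 * c^2 + 0.5 * eps^2 - c * eps)))
}

#' Zero-load length from the full-extension reference strain
#'
#' Inverts the reference-strain definition
#' \eqn{\epsilon_i = (L_i - L_0)/L_0} to give the length at which bundle
#' tension vanishes: \eqn{L_0 = L_i / (1 + \epsilon_i)}.
#'
#' @param L_i bundle length at full extension, mm
#' @param eps_i reference strain at full extension (may be negative for
#'   bundles slack at extension; must exceed -1)
#' @return zero-load length, mm
#' @export
zero_length_from_reference <- function(L_i, eps_i) {
  if (any(eps_i <= -1)) stop("reference strain <= -1 is non-physical")
  L_i / (1 + eps_i)
}

# --- wrapping ---------------------------------------------------------------

# world-frame wrapping obstacle: cylinder section on the medial tibial edge
obstacle_to_world <- function(obstacle, tf) {
  list(point = as.numeric(tf$R %*% obstacle$point + tf$t),
       axis = as.numeric(tf$R %*% obstacle$axis),
       radius = obstacle$radius,
       probe_radius = obstacle$probe_radius)
}

# vectorized via-point wrap: Pf, Pt n x 3 world-frame endpoints.
# Returns list(L = path lengths, via = n x 3 via points or NA rows when the
# straight path clears the obstacle).
wrap_paths <- function(Pf, Pt, obs) {
  n <- nrow(Pf)
  mid <- 0.5 * (Pf + Pt)
  rel <- mid - matrix(obs$point, n, 3, byrow = TRUE)
  along <- rel %*% obs$axis
  radial <- rel - along %*% t(obs$axis)
  rho <- sqrt(rowSums(radial^2))
  clear <- obs$radius + obs$probe_radius
  straight <- sqrt(rowSums((Pf - Pt)^2))
  L <- straight
  via <- matrix(NA_real_, n, 3)
  hit <- which(rho < clear)
  for (i in hit) {
    dir <- if (rho[i] > 1e-9) radial[i, ] / rho[i] else {
      # probe exactly on the axis: push along the global -Z (medial) direction
      normalize(c(0, 0, -1) - sum(c(0, 0, -1) * obs$axis) * obs$axis)
    }
    v <- obs$point + as.numeric(along[i]) * obs$axis + clear * dir
    via[i, ] <- v
    L[i] <- vnorm(Pf[i, ] - v) + vnorm(v - Pt[i, ])
  }
  list(L = L, via = via, straight = straight)
}

#' Wrapped path of a single bundle around the tibial-edge obstacle
#'
#' Via-point wrapping scheme: a probe sphere at the midpoint of the straight
#' segment is tested against the obstacle (a cylinder section on the medial
#' aspect of the tibia); if it penetrates, the path is deflected through the
#' probe centre pushed radially to the obstacle surface. The wrapped length
#' is never shorter than the straight-line distance.
#'
#' @param p_femur bundle endpoint on the femur, femoral frame, mm
#' @param p_tibia bundle endpoint on the tibia, tibial frame, mm
#' @param obstacle list with `point`, `axis` (tibial frame), `radius`,
#'   `probe_radius` (mm), e.g. `model$obstacle`
#' @param pose tibia pose, a [joint_pose()]
#' @return list with `L` (path length, mm), `wrapped` (logical), and
#'   `polyline` (2 x 3 or 3 x 3 matrix of path vertices, femoral frame)
#' @export
wrapped_path <- function(p_femur, p_tibia, obstacle, pose = joint_pose()) {
  tf <- pose_to_transform(pose)
  pt_w <- as.numeric(tf$R %*% vec3(p_tibia) + tf$t)
  obs <- obstacle_to_world(obstacle, tf)
  w <- wrap_paths(matrix(vec3(p_femur), 1), matrix(pt_w, 1), obs)
  wrapped <- is.finite(w$via[1, 1])
  poly <- if (wrapped) rbind(p_femur, w$via[1, ], pt_w) else rbind(p_femur, pt_w)
  list(L = w$L[1], wrapped = wrapped, polyline = unname(poly))
}

#' Tension and line of action of one bundle at a pose
#'
#' Composes the (possibly wrapped) path length, the strain, and the
#' force-strain law. The tension acts along the path segment adjacent to
#' each endpoint; the force on the tibia and its moment about the femoral
#' origin are reported in the femur-fixed frame.
#'
#' @param model a knee model (see [build_default_knee()])
#' @param id bundle id (row of `model$bundles`)
#' @param pose a [joint_pose()]
#' @return list with `L`, `strain`, `tension` (N), `dir_femur`, `dir_tibia`
#'   (unit vectors from each endpoint into the path), `force_on_tibia` (N)
#'   and `moment_on_tibia` (N mm about the femoral origin)
#' @export
bundle_tension <- function(model, id, pose = joint_pose()) {
  b <- model$bundles[model$bundles$id == id, ]
  if (nrow(b) != 1) stop("unknown bundle id: ", id)
  tf <- pose_to_transform(pose)
  pf <- as.numeric(b[1, c("fx", "fy", "fz")])
  pt <- as.numeric(b[1, c("tx", "ty", "tz")])
  pt_w <- as.numeric(tf$R %*% pt + tf$t)
  if (isTRUE(b$wraps) && !is.null(model$obstacle)) {
    wp <- wrapped_path(pf, pt, model$obstacle, pose)
    L <- wp$L
    poly <- wp$polyline
  } else {
    L <- vnorm(pf - pt_w)
    poly <- rbind(pf, pt_w)
  }
  if (L < 1e-9) stop("degenerate zero-length bundle path for id ", id)
  eps <- (L - b$L_0) / b$L_0
  f <- force_from_strain(eps, b$k, b$c)
  dir_f <- normalize(poly[2, ] - poly[1, ])         # from femoral endpoint
  m <- nrow(poly)
  dir_t <- normalize(poly[m - 1, ] - poly[m, ])     # from tibial endpoint
  force_on_tibia <- f * dir_t
  moment <- cross3(pt_w, force_on_tibia)
  list(L = L, strain = eps, tension = f,
       dir_femur = dir_f, dir_tibia = dir_t,
       force_on_tibia = force_on_tibia, moment_on_tibia = moment,
       polyline = poly)
}

#' Bundle definitions as a data frame
#'
#' One row per spring element with its ligament group, region, endpoint
#' coordinates (femoral/tibial bone frames), stiffness share, toe constant,
#' reference strain, full-extension length and zero-load length.
#'
#' @param model a knee model
#' @return data.frame
#' @export
bundle_table <- function(model) {
  model$bundles
}

#' Export bundle definitions to CSV or JSON
#'
#' @param model a knee model
#' @param path output file
#' @param format `"csv"` or `"json"`
#' @return `path`, invisibly
#' @export
export_bundles <- function(model, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- bundle_table(model)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
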