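# Synthetic articular geometry and ligament attachment construction.
#
# The articular surfaces are parametric primitives: two femoral condylar
# spheres centred on the flexion axis, a concave (more congruent) medial
# tibial dish and a flat (least congruent) lateral tibial patch. Contact is
# evaluated analytically on these primitives; triangle meshes for STL export
# are generated from the same primitives (see mesh.R).

# attachment frame: origin on the footprint centroid, X = anterior direction
# projected onto the footprint plane, Y = normal x X
make_frame <- function(ligament, bone, origin, normal, refX = c(1, 0, 0)) {
  n <- normalize(vec3(normal))
  x <- refX - sum(refX * n) * n
  if (vnorm(x) < 1e-9) stop("reference X parallel to footprint normal")
  x <- normalize(x)
  y <- cross3(n, x)
  list(ligament = ligament, bone = bone, origin = vec3(origin),
       X = x, Y = y, normal = n)
}

# region u offsets within a footprint (anterior positive along frame X)
region_offset <- function(regions, fu) {
  if (all(c("anterior", "middle", "posterior") %in% regions)) {
    c(anterior = fu, middle = 0, posterior = -fu)
  } else {
    c(anterior = fu * 0.8, posterior = -fu * 0.8)
  }
}

# regular within-region bundle layout: one (u, v) pair per bundle, shared by
# the femoral and tibial footprints (ordered connectivity map)
bundle_layout <- function(groups, fu, fv) {
  rows <- list()
  id <- 0L
  for (lig in names(groups)) {
    regs <- groups[[lig]]$regions
    offs <- region_offset(names(regs), fu)
    for (reg in names(regs)) {
      n <- regs[[reg]]$n
      v <- fv * (seq_len(n) - (n + 1) / 2)
      for (j in seq_len(n)) {
        id <- id + 1L
        rows[[id]] <- data.frame(
          id = id, ligament = lig, region = reg,
          group = paste(lig, reg, sep = "."),
          u = offs[[reg]], v = v[j], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

new_knee_model <- function(config, frames, layout, offsets, group_k, eps,
                           obstacle, contact, bundles = NULL) {
  m <- structure(list(
    config = config, frames = frames, layout = layout, offsets = offsets,
    group_k = group_k, eps = eps,
    nominal = list(offsets = offsets, group_k = group_k, eps = eps),
    obstacle = obstacle, contact = contact, bundles = bundles),
    class = "knee_model")
  refresh_model(m)
}

# Recompute derived bundle quantities: endpoint coordinates from the
# attachment frames + accumulated (TX,TY,FX,FY) offsets, per-bundle stiffness
# share (group stiffness split equally), reference strains by region group,
# the full-extension path length L_i (wrapped where applicable) and the
# zero-load length L_0 = L_i / (1 + eps_i). Pure: returns a new model.
refresh_model <- function(model) {
  b <- model$bundles
  if (!is.null(model$frames)) {
    lay <- model$layout
    n <- nrow(lay)
    P <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      lig <- lay$ligament[i]
      fr <- model$frames[[lig]]
      off <- model$offsets[[lig]]
      pf <- fr$femur$origin + (lay$u[i] + off[["FX"]]) * fr$femur$X +
        (lay$v[i] + off[["FY"]]) * fr$femur$Y
      pt <- fr$tibia$origin + (lay$u[i] + off[["TX"]]) * fr$tibia$X +
        (lay$v[i] + off[["TY"]]) * fr$tibia$Y
      P[i, ] <- c(pf, pt)
    }
    groups <- model$config$ligaments$groups
    nb <- vapply(groups, function(g) sum(vapply(g$regions, `[[`, 0, "n")), 0)
    b <- data.frame(
      lay,
      fx = P[, 1], fy = P[, 2], fz = P[, 3],
      tx = P[, 4], ty = P[, 5], tz = P[, 6],
      k = unname(model$group_k[lay$ligament] / nb[lay$ligament]),
      c = model$config$ligaments$toe_constant,
      eps_i = unname(model$eps[paste(lay$ligament, lay$region, sep = ".")]),
      wraps = vapply(groups[lay$ligament], `[[`, TRUE, "wraps"),
      stringsAsFactors = FALSE)
    rownames(b) <- NULL
  }
  # full-extension lengths at the reference pose (identity transform)
  Pf <- as.matrix(b[, c("fx", "fy", "fz")])
  Pt <- as.matrix(b[, c("tx", "ty", "tz")])
  L <- sqrt(rowSums((Pf - Pt)^2))
  wi <- which(b$wraps)
  if (length(wi) && !is.null(model$obstacle)) {
    w <- wrap_paths(Pf[wi, , drop = FALSE], Pt[wi, , drop = FALSE],
                    model$obstacle)
    L[wi] <- w$L
  }
  b$L_i <- L
  b$L_0 <- zero_length_from_reference(b$L_i, b$eps_i)
  if (any(b$L_0 <= 0)) stop("non-positive zero-load length")
  model$bundles <- b
  model
}

#' Build the default synthetic knee model
#'
#' Constructs the fully parametric knee: analytic articular primitives (two
#' femoral condylar spheres, a concave medial tibial dish, a flat lateral
#' patch), six ligament groups with the standard bundle census (ACL 10 = 4
#' anterior + 3 middle + 3 posterior, PCL 9 = 3/3/3, sMCL 4 = 2/2, dMCL 2,
#' LCL 4 = 2/2, PMC 2; 31 spring elements in total), group stiffness split
#' equally among the bundles of each ligament, per-region reference strains,
#' planar attachment frames and the medial tibial-edge wrapping obstacle for
#' the MCL.
#'
#' @param config configuration list, see [default_config()]
#' @param seed optional integer seed, used only when
#'   `config$geometry$jitter_sd > 0` to jitter footprint centroids
#' @return an object of class `knee_model`
#' @export
build_default_knee <- function(config = default_config(), seed = NULL) {
  g <- config$geometry
  if (g$condyle_radius_medial <= 0 || g$condyle_radius_lateral <= 0 ||
      g$dish_clearance <= 0 || g$condyle_spacing <= 0)
    stop("geometry radii and spacing must be positive")
  dish_radius <- g$condyle_radius_medial + g$dish_clearance
  if (dish_radius > g$lateral_radius)
    stop("medial tibial compartment must be at least as congruent as the lateral")

  att <- g$attachments
  if (g$jitter_sd > 0) {
    if (is.null(seed)) stop("footprint jitter requested but no seed given")
    set.seed(seed)
    for (lig in names(att)) for (bone in c("femur", "tibia"))
      att[[lig]][[bone]]$origin <- att[[lig]][[bone]]$origin +
        stats::rnorm(3, 0, g$jitter_sd)
  }
  frames <- lapply(names(att), function(lig) {
    list(femur = make_frame(lig, "femur", att[[lig]]$femur$origin,
                            att[[lig]]$femur$normal),
         tibia = make_frame(lig, "tibia", att[[lig]]$tibia$origin,
                            att[[lig]]$tibia$normal))
  })
  names(frames) <- names(att)

  groups <- config$ligaments$groups
  layout <- bundle_layout(groups, g$footprint_u, g$footprint_v)
  offsets <- lapply(groups, function(...) c(TX = 0, TY = 0, FX = 0, FY = 0))
  group_k <- vapply(groups, `[[`, 0, "k")
  eps <- unlist(lapply(names(groups), function(lig)
    stats::setNames(
      vapply(groups[[lig]]$regions, `[[`, 0, "eps"),
      paste(lig, names(groups[[lig]]$regions), sep = "."))))

  s2 <- g$condyle_spacing / 2
  contact <- list(
    medial = list(type = "sphere_in_socket",
                  femur_center = c(0, 0, -s2),
                  femur_radius = g$condyle_radius_medial,
                  socket_center = c(0, dish_radius - g$condyle_radius_medial, -s2),
                  socket_radius = dish_radius),
    lateral = list(type = "sphere_on_plane",
                   femur_center = c(0, 0, s2),
                   femur_radius = g$condyle_radius_lateral,
                   plane_point = c(0, -g$condyle_radius_lateral, s2),
                   plane_normal = c(0, 1, 0)))

  obstacle <- list(point = vec3(g$wrap$point), axis = normalize(g$wrap$axis),
                   radius = g$wrap$radius,
                   probe_radius = g$wrap$probe_diameter / 2)

  model <- new_knee_model(config, frames, layout, offsets, group_k, eps,
                          obstacle, contact)

  # bundle census is a construction invariant
  census <- table(model$bundles$ligament)
  expected <- vapply(groups, function(gr) sum(vapply(gr$regions, `[[`, 0, "n")), 0)
  if (!all(census[names(expected)] == expected))
    stop("bundle census does not match the ligament definition table")
  model
}

#' Minimal knee-model constructor for bespoke bundle sets
#'
#' Low-level entry used for reduced or idealized models (e.g. single-spring
#' checks): supply bundle endpoints directly instead of attachment frames.
#' Either `eps_i` (reference strain at the identity pose) or `L_0` must be
#' present in `bundles`.
#'
#' @param bundles data.frame with columns id, ligament, region, fx, fy, fz,
#'   tx, ty, tz, k, c, wraps and eps_i or L_0
#' @param contact contact primitive list or NULL to disable contact
#' @param obstacle wrapping obstacle list or NULL
#' @param config configuration list
#' @return `knee_model`
#' @export
knee_model <- function(bundles, contact = NULL, obstacle = NULL,
                       config = default_config()) {
  if (is.null(bundles$c)) bundles$c <- config$ligaments$toe_constant
  if (is.null(bundles$wraps)) bundles$wraps <- FALSE
  if (is.null(bundles$eps_i)) {
    if (is.null(bundles$L_0)) stop("bundles need eps_i or L_0")
    Pf <- as.matrix(bundles[, c("fx", "fy", "fz")])
    Pt <- as.matrix(bundles[, c("tx", "ty", "tz")])
    bundles$eps_i <- sqrt(rowSums((Pf - Pt)^2)) / bundles$L_0 - 1
  }
  m <- structure(list(config = config, frames = NULL, layout = NULL,
                      offsets = NULL, group_k = NULL, eps = NULL,
                      nominal = NULL, obstacle = obstacle, contact = contact,
                      bundles = bundles), class = "knee_model")
  refresh_model(m)
}

#' Translate a ligament's attachment footprint in its attachment frame
#'
#' Moves every bundle of `ligament` on `bone` by `dx` along the frame X axis
#' and `dy` along Y, then recomputes each affected bundle's full-extension
#' length and zero-load length so the reference strain is unchanged
#' (strain-preserving update).
#'
#' @param model a `knee_model` built by [build_default_knee()]
#' @param ligament ligament id (e.g. `"ACL"`)
#' @param bone `"tibia"` or `"femur"`
#' @param dx,dy in-plane offsets, mm
#' @return perturbed `knee_model` (input untouched)
#' @export
perturb_attachment <- function(model, ligament, bone = c("tibia", "femur"),
                               dx = 0, dy = 0) {
  bone <- match.arg(bone)
  if (is.null(model$offsets[[ligament]]))
    stop("unknown ligament id: ", ligament)
  keys <- if (bone == "tibia") c("TX", "TY") else c("FX", "FY")
  off <- model$offsets[[ligament]]
  off[keys] <- off[keys] + c(dx, dy)
  bound <- model$config$geometry$footprint_bound
  if (any(abs(off[keys]) > bound + 1e-9))
    stop("attachment offset exceeds the footprint bound of ", bound, " mm")
  model$offsets[[ligament]] <- off
  refresh_model(model)
}

#' Shift a ligament region's reference strain
#'
#' Models intraoperative release (negative `delta`) or retensioning
#' (positive) by changing the full-extension reference strain of the bundles
#' in the region; zero-load lengths are recomputed.
#'
#' @param model a `knee_model` built by [build_default_knee()]
#' @param ligament ligament id
#' @param region region name, or NULL for all regions of the ligament
#' @param delta strain change (dimensionless)
#' @return updated `knee_model`
#' @export
adjust_reference_strain <- function(model, ligament, region = NULL, delta) {
  keys <- names(model$eps)
  sel <- if (is.null(region)) startsWith(keys, paste0(ligament, "."))
         else keys == paste(ligament, region, sep = ".")
  if (!any(sel)) stop("unknown ligament/region: ", ligament, " ", region)
  model$eps[sel] <- model$eps[sel] + delta
  refresh_model(model)
}

#' Export attachment frames and bundle endpoints as JSON
#'
#' @param model a `knee_model`
#' @param path output .json file
#' @return `path`, invisibly
#' @export
export_attachments <- function(model, path) {
  out <- list(frames = model$frames, offsets = model$offsets,
              bundles = model$bundles)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.knee_model <- function(x, ...) {
  cat("knee model:", nrow(x$bundles), "ligament bundles\n")
  tab <- table(x$bundles$ligament)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"),
      "\n")
  if (!is.null(x$contact)) cat("contact: medial dish + lateral patch\n")
  invisible(x)
}
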