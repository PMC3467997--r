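#' Default campaign configuration
#'
#' Nested list of every tunable of the synthetic knee and the study: articular
#' geometry, ligament nominal properties (bundle census, group stiffnesses,
#' reference strains), DOE perturbation levels, laxity load amplitudes,
#' flexion angles, solver settings and analysis thresholds. The defaults are
#' the study conditions; they can be overridden selectively via
#' [read_config()] / `merge_config` semantics in [run_full_study()].
#'
#' Units: mm, N, Nm, degrees. Right-knee convention; femoral frame X
#' anterior, Y proximal, Z lateral, origin at the joint centre midway between
#' the condylar sphere centres. At the full-extension reference pose the
#' tibial frame coincides with the femoral frame.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    geometry = list(
      condyle_radius_medial = 22,    # femoral condylar sphere radii, mm
      condyle_radius_lateral = 20,
      condyle_spacing = 46,          # distance between condylar sphere centres
      dish_clearance = 8,            # medial tibial dish radius = medial condyle + clearance
      lateral_radius = Inf,          # flat (least congruent) lateral tibial patch
      dish_rim_radius = 12,          # in-plane extent of the medial dish patch
      lateral_patch_halfwidth = 12,
      mesh_edge = 1.0,               # target triangle edge length, mm
      wrap = list(                   # medial tibial edge the sMCL/dMCL wrap around
        point = c(0, -22, -34),      # tibial frame, on the medial plateau rim
        axis = c(1, 0, 0),
        radius = 5,
        probe_diameter = 1           # midpoint probe sphere, mm
      ),
      # attachment footprint frames: origin (bone frame, mm) + outward plane
      # normal; in-plane X is the anterior direction projected to the plane,
      # Y = normal x X. Placed from published anatomic descriptions scaled to
      # the synthetic bone.
      attachments = list(
        ACL  = list(femur = list(origin = c(-4, 1, 6),    normal = c(0, 0, -1)),
                    tibia = list(origin = c(10, -21, -2),  normal = c(0, 1, 0))),
        PCL  = list(femur = list(origin = c(5, 0, -6),    normal = c(0, 0, 1)),
                    tibia = list(origin = c(-12, -25, 0),  normal = c(0, 1, 0))),
        sMCL = list(femur = list(origin = c(0, 5, -42),   normal = c(0, 0, -1)),
                    tibia = list(origin = c(2, -50, -32),  normal = c(0, 0, -1))),
        dMCL = list(femur = list(origin = c(0, 3, -40),   normal = c(0, 0, -1)),
                    tibia = list(origin = c(2, -28, -33),  normal = c(0, 0, -1))),
        LCL  = list(femur = list(origin = c(0, 5, 42),    normal = c(0, 0, 1)),
                    tibia = list(origin = c(-5, -35, 40),  normal = c(0, 0, 1))),
        PMC  = list(femur = list(origin = c(-12, 2, -25), normal = c(-1, 0, -1)),
                    tibia = list(origin = c(-14, -22, -22), normal = c(-1, 0, -1)))
      ),
      footprint_u = 2.5,   # anterior/posterior region offset inside a footprint, mm
      footprint_v = 2.0,   # bundle spacing across a region, mm
      footprint_bound = 5, # allowed attachment perturbation |dx|,|dy|, mm
      jitter_sd = 0        # optional seeded jitter of footprint centroids, mm
    ),
    ligaments = list(
      toe_constant = 0.03,
      # bundle census, group stiffness (N) and reference strains at full
      # extension per ligament region
      groups = list(
        ACL  = list(k = 5000, wraps = FALSE,
                    regions = list(anterior = list(n = 4, eps = 0.160),
                                   middle   = list(n = 3, eps = 0.100),
                                   posterior = list(n = 3, eps = 0.100))),
        PCL  = list(k = 9000, wraps = FALSE,
                    regions = list(anterior = list(n = 3, eps = -0.068),
                                   middle   = list(n = 3, eps = -0.169),
                                   posterior = list(n = 3, eps = -0.169))),
        sMCL = list(k = 2750, wraps = TRUE,
                    regions = list(anterior = list(n = 2, eps = 0.180),
                                   posterior = list(n = 2, eps = 0.180))),
        dMCL = list(k = 1000, wraps = TRUE,
                    regions = list(anterior = list(n = 1, eps = 0.030),
                                   posterior = list(n = 1, eps = 0.030))),
        LCL  = list(k = 2000, wraps = FALSE,
                    regions = list(anterior = list(n = 2, eps = 0.050),
                                   posterior = list(n = 2, eps = 0.050))),
        PMC  = list(k = 1000, wraps = FALSE,
                    regions = list(anterior = list(n = 1, eps = 0.030),
                                   posterior = list(n = 1, eps = 0.030)))
      )
    ),
    doe = list(
      attachment_step_mm = 1,  # attachment levels: nominal + {-1, 0, +1} mm
      stiffness_frac = 0.05,   # stiffness levels: nominal x {0.95, 1.00, 1.05}
      strain_step = 0.05       # strain levels: nominal + {-0.05, 0, +0.05}
    ),
    loads = list(
      ap_force_N = 100,
      ie_moment_Nm = 8,
      vv_moment_Nm = 30,
      preload_N = 10           # light compressive preload keeping surfaces engaged
    ),
    flexions = c(0, 30, 60, 90, 120),
    solver = list(
      penalty_N_per_mm = 1e4,  # contact penalty stiffness
      smoothing_mm = 0.01,     # quadratic force smoothing depth
      max_penetration_mm = 1,
      tol_force_N = 0.1,
      tol_moment_Nm = 0.01,
      max_iter = 500
    ),
    analysis = list(
      rank_threshold = 3       # ligament mean-rank cutoff for test selection
    )
  )
}

#' Read a configuration file (YAML), merged over the defaults
#'
#' @param path YAML file with any subset of the [default_config()] entries
#' @return full configuration list
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' Write a configuration list to YAML
#'
#' @param config configuration list
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
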