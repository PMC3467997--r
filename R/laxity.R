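# Quasistatic laxity simulation: frictionless articular contact as a smooth
# unilateral penalty, total-potential minimization over the five free
# Grood-Suntay coordinates at fixed flexion, and the AP/IE/VV laxity battery.

# smoothed unilateral penalty: force k*p^2/(2d) on [0, d], k*(p - d/2) beyond
# (C1-continuous, zero force at zero penetration); energy is its integral
contact_energy <- function(pen, k, d) {
  ifelse(pen <= 0, 0,
  ifelse(pen <= d, k * pen^3 / (6 * d),
         k * (0.5 * pen^2 - 0.5 * d * pen + d^2 / 6)))
}

contact_force_mag <- function(pen, k, d) {
  ifelse(pen <= 0, 0, ifelse(pen <= d, k * pen^2 / (2 * d), k * (pen - d / 2)))
}

# signed penetrations of the analytic contact pairs at a transform
contact_penetrations <- function(contact, tf) {
  if (is.null(contact)) return(numeric(0))
  pen <- numeric(0)
  if (!is.null(contact$medial)) {
    cm <- contact$medial
    sc <- as.numeric(tf$R %*% cm$socket_center + tf$t)
    d <- vnorm(sc - cm$femur_center)
    pen <- c(pen, medial = d - (cm$socket_radius - cm$femur_radius))
  }
  if (!is.null(contact$lateral)) {
    cl <- contact$lateral
    p0 <- as.numeric(tf$R %*% cl$plane_point + tf$t)
    nw <- as.numeric(tf$R %*% cl$plane_normal)
    s <- sum((cl$femur_center - p0) * nw)
    pen <- c(pen, lateral = cl$femur_radius - s)
  }
  pen
}

# one-time extraction of everything the energy function needs
prepare_sim <- function(model) {
  b <- model$bundles
  list(
    Pf = as.matrix(b[, c("fx", "fy", "fz")]),
    Pt = as.matrix(b[, c("tx", "ty", "tz")]),
    k = b$k, c = b$c, L0 = b$L_0,
    wrap_idx = which(b$wraps),
    obstacle = model$obstacle,
    contact = model$contact,
    solver = model$config$solver,
    preload = model$config$loads$preload_N
  )
}

# transform from fixed flexion + free coordinates x = (vv, ie, ap, ml, dc),
# rotations in radians
free_transform <- function(flex_rad, x) {
  R <- rot_z(-flex_rad) %*% rot_x(x[1]) %*% rot_y(x[2])
  e1 <- c(0, 0, 1)
  e3 <- R[, 2]
  e2 <- normalize(cross3(e3, e1))
  list(R = R, t = x[4] * e1 + x[3] * e2 - x[5] * e3)
}

# total potential, N mm: ligament strain energy + contact penalty
# - work of the generalized loads (gen: conjugate to (vv, ie, ap, ml, dc))
total_potential <- function(sim, flex_rad, x, gen) {
  tf <- free_transform(flex_rad, x)
  U <- 0
  if (nrow(sim$Pt) > 0) {
    Pt_w <- sim$Pt %*% t(tf$R) + matrix(tf$t, nrow(sim$Pt), 3, byrow = TRUE)
    d <- sim$Pf - Pt_w
    L <- sqrt(rowSums(d * d))
    if (length(sim$wrap_idx) && !is.null(sim$obstacle)) {
      obs <- obstacle_to_world(sim$obstacle, tf)
      w <- wrap_paths(sim$Pf[sim$wrap_idx, , drop = FALSE],
                      Pt_w[sim$wrap_idx, , drop = FALSE], obs)
      L[sim$wrap_idx] <- w$L
    }
    eps <- (L - sim$L0) / sim$L0
    U <- sum(sim$L0 * strain_energy_density(eps, sim$k, sim$c))
  }
  pen <- contact_penetrations(sim$contact, tf)
  if (length(pen))
    U <- U + sum(contact_energy(pen, sim$solver$penalty_N_per_mm,
                                sim$solver$smoothing_mm))
  # preload: light compressive force along the distraction coordinate
  U <- U + sim$preload * x[5]
  U - sum(gen * x)
}

num_gradient <- function(fn, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# damped Newton polish with a numeric Hessian: drives the residual below
# tolerance when the quasi-Newton stage stalls near the minimum
newton_polish <- function(fn, x, tol, max_iter = 25, h = 1e-5) {
  n <- length(x)
  g <- num_gradient(fn, x, h)
  for (it in seq_len(max_iter)) {
    if (all(abs(g) <= 0.5 * tol)) break
    H <- matrix(0, n, n)
    for (i in seq_len(n)) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h
      xm[i] <- xm[i] - h
      H[, i] <- (num_gradient(fn, xp, h) - num_gradient(fn, xm, h)) / (2 * h)
    }
    H <- 0.5 * (H + t(H))
    lam <- 1e-6 * max(abs(diag(H)), 1)
    improved <- FALSE
    for (try in 1:8) {
      dx <- tryCatch(solve(H + lam * diag(n), -g), error = function(e) NULL)
      if (!is.null(dx)) {
        xn <- x + dx
        gn <- num_gradient(fn, xn, h)
        if (max(abs(gn) / tol) < max(abs(g) / tol)) {
          x <- xn; g <- gn; improved <- TRUE
          break
        }
      }
      lam <- lam * 10
    }
    if (!improved) break
  }
  list(x = x, g = g)
}

#' Solve the quasistatic equilibrium at fixed flexion
#'
#' Minimizes the total potential (ligament strain energy + contact penalty +
#' preload - load work) over the five free Grood-Suntay coordinates by
#' quasi-Newton descent with numeric gradients. The returned pose satisfies
#' the residual tolerances of `model$config$solver` (default 0.1 N on
#' translational and 0.01 Nm on rotational generalized forces).
#'
#' @param model a `knee_model`
#' @param flexion prescribed flexion angle, degrees
#' @param load a [load_case()] or NULL for the zero-load (preload only)
#'   equilibrium
#' @param start warm-start [joint_pose()] (its flexion entry is ignored)
#' @return the equilibrium [joint_pose()], with attributes `residual`
#'   (named generalized-force residuals: N mm for rotations, N for
#'   translations), `energy`, `penetration` (named contact penetrations, mm)
#'   and `contact_force` (N)
#' @export
solve_equilibrium <- function(model, flexion, load = NULL,
                              start = joint_pose(flexion = flexion)) {
  sim <- prepare_sim(model)
  solve_equilibrium_sim(sim, flexion, load, start)
}

solve_equilibrium_sim <- function(sim, flexion, load, start) {
  flex_rad <- deg2rad(flexion)
  gen <- c(vv = 0, ie = 0, ap = 0, ml = 0, dc = 0)
  if (!is.null(load)) {
    gl <- generalized_load(load, joint_pose(flexion = flexion))
    gen <- gl$generalized
  }
  x0 <- c(deg2rad(start[["vv"]]), deg2rad(start[["ie"]]),
          start[["ap"]], start[["ml"]], start[["dc"]])
  fn <- function(x) total_potential(sim, flex_rad, x, gen)
  gr <- function(x) num_gradient(fn, x)
  ps <- c(0.05, 0.2, 2, 2, 0.5)  # typical magnitudes: rad, rad, mm, mm, mm
  tol <- c(rep(sim$solver$tol_moment_Nm * 1000, 2), rep(sim$solver$tol_force_N, 3))
  ctrl <- list(maxit = sim$solver$max_iter, parscale = ps, factr = 1e7)
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B", control = ctrl)
  res <- gr(opt$par)
  if (any(abs(res) > tol)) {  # deterministic polish ladder
    np <- newton_polish(fn, opt$par, tol)
    opt$par <- np$x; opt$value <- fn(np$x); res <- np$g
    for (pass in 1:2) {
      if (all(abs(res) <= tol)) break
      opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                           control = list(maxit = 2000, parscale = ps / 10^pass,
                                          factr = 10))
      if (opt2$value <= opt$value) opt <- opt2
      np <- newton_polish(fn, opt$par, tol)
      opt$par <- np$x; opt$value <- fn(np$x); res <- np$g
    }
  }
  if (any(abs(res) > tol))
    stop(sprintf(
      "equilibrium did not converge at flexion %.0f deg: residual (Nmm,Nmm,N,N,N) = %s",
      flexion, paste(signif(res, 3), collapse = ", ")))
  x <- opt$par
  tf <- free_transform(flex_rad, x)
  pen <- contact_penetrations(sim$contact, tf)
  if (length(pen) && any(pen > sim$solver$max_penetration_mm))
    stop(sprintf("contact penetration %.3f mm exceeds the %.3f mm cap",
                 max(pen), sim$solver$max_penetration_mm))
  pose <- joint_pose(flexion = flexion, vv = rad2deg(x[1]), ie = rad2deg(x[2]),
                     ap = x[3], ml = x[4], dc = x[5])
  names(res) <- c("vv", "ie", "ap", "ml", "dc")
  attr(pose, "residual") <- res
  # residual scaled by the per-component tolerance (< 1 at convergence)
  attr(pose, "residual_scaled") <- max(abs(res) / tol)
  attr(pose, "energy") <- opt$value
  attr(pose, "penetration") <- pen
  attr(pose, "contact_force") <- contact_force_mag(
    pen, sim$solver$penalty_N_per_mm, sim$solver$smoothing_mm)
  pose
}

default_amplitude <- function(model, type) {
  switch(type,
         AP = model$config$loads$ap_force_N,
         IE = model$config$loads$ie_moment_Nm,
         VV = model$config$loads$vv_moment_Nm)
}

laxity_coord <- c(AP = "ap", IE = "ie", VV = "vv")

#' Run one laxity test
#'
#' Solves the zero-load equilibrium at the given flexion, then the
#' equilibria at the positive and negative load amplitudes (both warm-started
#' from the zero-load pose). Laxity is the total excursion between the two
#' extreme poses, in mm for AP and degrees for IE/VV.
#'
#' @param model a `knee_model`
#' @param flexion flexion angle, degrees
#' @param type `"AP"`, `"IE"` or `"VV"`
#' @param amplitude load amplitude (N or Nm); defaults to the configured
#'   study amplitudes (AP 100 N, IE 8 Nm, VV 30 Nm)
#' @param start warm start for the zero-load solve
#' @param zero_pose optional precomputed zero-load equilibrium pose
#' @return list of class `laxity_result` with the flexion, test type,
#'   laxity, both extreme poses and their residual norms
#' @export
run_laxity_test <- function(model, flexion, type = c("AP", "IE", "VV"),
                            amplitude = NULL,
                            start = joint_pose(flexion = flexion),
                            zero_pose = NULL) {
  type <- match.arg(type)
  sim <- prepare_sim(model)
  run_laxity_test_sim(sim, model, flexion, type, amplitude, start, zero_pose)
}

run_laxity_test_sim <- function(sim, model, flexion, type, amplitude,
                                start, zero_pose) {
  if (is.null(amplitude)) amplitude <- default_amplitude(model, type)
  wrap_err <- function(expr) tryCatch(expr, error = function(e)
    stop(sprintf("[flexion %.0f, %s] %s", flexion, type, conditionMessage(e)),
         call. = FALSE))
  if (is.null(zero_pose))
    zero_pose <- wrap_err(solve_equilibrium_sim(sim, flexion, NULL, start))
  pos <- wrap_err(solve_equilibrium_sim(
    sim, flexion, load_case(type, +amplitude), zero_pose))
  neg <- wrap_err(solve_equilibrium_sim(
    sim, flexion, load_case(type, -amplitude), zero_pose))
  coord <- laxity_coord[[type]]
  laxity <- pos[[coord]] - neg[[coord]]
  structure(list(
    flexion = flexion, type = type, amplitude = amplitude,
    laxity = laxity, unit = if (type == "AP") "mm" else "deg",
    pose_pos = pos, pose_neg = neg, pose_zero = zero_pose,
    residual_pos = attr(pos, "residual_scaled"),
    residual_neg = attr(neg, "residual_scaled")),
    class = "laxity_result")
}

#' Run the full laxity battery
#'
#' Three laxity tests (AP drawer 100 N, IE moment 8 Nm, VV moment 30 Nm by
#' default) at each of the configured flexion angles (0, 30, 60, 90, 120
#' degrees): 15 results. Flexion is incremented with warm-starting from the
#' previous angle's zero-load equilibrium; both load extremes of each test
#' are warm-started from the current angle's zero-load pose. Deterministic.
#'
#' @param model a `knee_model`
#' @param flexions flexion angles, degrees
#' @param types laxity test types
#' @return list of `laxity_result` (named `<type>-<angle>`); errors in
#'   individual tests are collected and reported while the completed subset
#'   is returned with attribute `failures`
#' @export
run_battery <- function(model, flexions = model$config$flexions,
                        types = c("AP", "IE", "VV")) {
  sim <- prepare_sim(model)
  results <- list()
  failures <- character(0)
  start <- joint_pose(flexion = flexions[1])
  for (fl in flexions) {
    zero <- tryCatch(solve_equilibrium_sim(sim, fl, NULL, start),
                     error = function(e) e)
    if (inherits(zero, "error")) {
      failures <- c(failures, sprintf("[flexion %.0f, zero-load] %s", fl,
                                      conditionMessage(zero)))
      next
    }
    start <- zero  # warm start for the next flexion angle
    for (ty in types) {
      key <- sprintf("%s-%02d", ty, fl)
      r <- tryCatch(
        run_laxity_test_sim(sim, model, fl, ty, NULL, zero, zero),
        error = function(e) e)
      if (inherits(r, "error")) {
        failures <- c(failures, conditionMessage(r))
      } else {
        results[[key]] <- r
      }
    }
  }
  attr(results, "failures") <- failures
  results
}

#' Tabulate laxity results
#'
#' @param results output of [run_battery()]
#' @return data.frame with one row per (flexion, test): laxity, extreme-pose
#'   coordinates and residual norms
#' @export
laxity_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(test = r$type, flexion = r$flexion,
               id = sprintf("%s-%02d", r$type, r$flexion),
               laxity = r$laxity, unit = r$unit,
               pos = r$pose_pos[[laxity_coord[[r$type]]]],
               neg = r$pose_neg[[laxity_coord[[r$type]]]],
               residual_pos = r$residual_pos, residual_neg = r$residual_neg,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.laxity_result <- function(x, ...) {
  cat(sprintf("%s laxity at %.0f deg flexion (amplitude %g): %.3f %s\n",
              x$type, x$flexion, x$amplitude, x$laxity, x$unit))
  invisible(x)
}
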