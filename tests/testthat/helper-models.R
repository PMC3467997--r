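# shared fixtures and independent oracles, built in code

# nominal synthetic knee, built once per test run
nominal_knee <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_default_knee()
    cache
  }
})

# idealized axial model: three parallel vertical springs on a 5 mm circle,
# slack length L0, resting span 20 mm; no contact
axial_spring_model <- function(L0 = 19, k = 1000, preload_N = 0) {
  ang <- 2 * pi * (0:2) / 3
  b <- data.frame(id = 1:3, ligament = "toy", region = "m",
                  fx = 5 * cos(ang), fy = 0, fz = 5 * sin(ang),
                  tx = 5 * cos(ang), ty = -20, tz = 5 * sin(ang),
                  k = k, L_0 = L0)
  cfg <- default_config()
  cfg$loads$preload_N <- preload_N
  knee_model(b, contact = NULL, config = cfg)
}

# brute-force RIM oracle: explicit row partitioning, independent of rim()
rim_oracle <- function(levels, response) {
  m <- mean(response)
  groups <- split(response, levels)
  ss <- 0
  for (g in groups) ss <- ss + length(g) * (mean(g) - m)^2
  ss / sum((response - m)^2)
}

# analytic shortest path over a circular cylinder for endpoints in a plane
# perpendicular to the axis (2D circle geodesic): tangent + arc + tangent
cylinder_geodesic <- function(p1, p2, r) {
  d1 <- sqrt(sum(p1^2)); d2 <- sqrt(sum(p2^2))
  wrap_angle <- acos(sum(p1 * p2) / (d1 * d2)) - acos(r / d1) - acos(r / d2)
  if (wrap_angle <= 0) return(sqrt(sum((p1 - p2)^2)))
  sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) + r * wrap_angle
}
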