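# synthetic knee construction, attachment perturbation, surface I/O

test_that("default build has the standard bundle census", {
  m <- nominal_knee()
  b <- m$bundles
  census <- table(b$ligament)
  expect_equal(unname(census["ACL"]), 10)
  expect_equal(unname(census["PCL"]), 9)
  expect_equal(unname(census["sMCL"]), 4)
  expect_equal(unname(census["dMCL"]), 2)
  expect_equal(unname(census["LCL"]), 4)
  expect_equal(unname(census["PMC"]), 2)
  expect_equal(nrow(b), 31)
  reg <- table(b$ligament, b$region)
  expect_equal(unname(reg["ACL", c("anterior", "middle", "posterior")]),
               c(4, 3, 3))
  expect_equal(unname(reg["PCL", c("anterior", "middle", "posterior")]),
               c(3, 3, 3))
})

test_that("reference strains follow the nominal table and L_0 is consistent", {
  m <- nominal_knee()
  b <- m$bundles
  eps_of <- function(lig, reg) unique(b$eps_i[b$ligament == lig & b$region == reg])
  expect_equal(eps_of("ACL", "anterior"), 0.160)
  expect_equal(eps_of("ACL", "middle"), 0.100)
  expect_equal(eps_of("PCL", "anterior"), -0.068)
  expect_equal(eps_of("PCL", "posterior"), -0.169)
  expect_equal(eps_of("sMCL", "anterior"), 0.180)
  expect_equal(eps_of("LCL", "posterior"), 0.050)
  expect_equal(b$L_0, b$L_i / (1 + b$eps_i))
  expect_true(all(b$L_0 > 0))
})

test_that("medial compartment is always at least as congruent as lateral", {
  m <- nominal_knee()
  expect_lte(m$contact$medial$socket_radius, m$config$geometry$lateral_radius)
  cfg <- default_config()
  cfg$geometry$lateral_radius <- 10  # less than the medial dish radius
  expect_error(build_default_knee(cfg), "congruent")
  cfg2 <- default_config()
  cfg2$geometry$condyle_radius_medial <- -1
  expect_error(build_default_knee(cfg2), "positive")
})

test_that("attachment frames are orthonormal with origin on the plane", {
  m <- nominal_knee()
  for (fr in m$frames) for (bone in c("femur", "tibia")) {
    f <- fr[[bone]]
    expect_equal(sum(f$X * f$Y), 0, tolerance = 1e-12)
    expect_equal(sum(f$X * f$normal), 0, tolerance = 1e-12)
    expect_equal(sum(f$Y * f$normal), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(f$X^2)), 1)
    expect_equal(sqrt(sum(f$Y^2)), 1)
    expect_equal(sqrt(sum(f$normal^2)), 1)
  }
})

test_that("attachment perturbation is strain-preserving and invertible", {
  m <- nominal_knee()
  expect_identical(perturb_attachment(m, "ACL", "tibia", 0, 0)$bundles,
                   m$bundles)
  p <- perturb_attachment(m, "ACL", "tibia", dx = 1, dy = 0)
  moved <- p$bundles$ligament == "ACL"
  X <- m$frames$ACL$tibia$X
  d <- as.matrix(p$bundles[moved, c("tx", "ty", "tz")]) -
    as.matrix(m$bundles[moved, c("tx", "ty", "tz")])
  expect_equal(unname(d), matrix(X, sum(moved), 3, byrow = TRUE),
               tolerance = 1e-12)
  # other ligaments and femoral endpoints untouched
  expect_equal(p$bundles[!moved, ], m$bundles[!moved, ])
  expect_equal(p$bundles[moved, c("fx", "fy", "fz")],
               m$bundles[moved, c("fx", "fy", "fz")])
  # reference strain unchanged although lengths changed
  expect_lt(max(abs(p$bundles$eps_i - m$bundles$eps_i)), 1e-9)
  expect_false(isTRUE(all.equal(p$bundles$L_i, m$bundles$L_i)))
  # inverse perturbation restores the model
  back <- perturb_attachment(p, "ACL", "tibia", dx = -1, dy = 0)
  expect_equal(back$bundles, m$bundles, tolerance = 1e-12)
  expect_error(perturb_attachment(m, "XYZ", "tibia", 1, 0), "unknown ligament")
  expect_error(perturb_attachment(m, "ACL", "tibia", 99, 0), "footprint bound")
})

test_that("strain-preservation holds under arbitrary in-bound perturbations", {
  m <- nominal_knee()
  set.seed(7)
  ligs <- names(m$offsets)
  for (i in 1:25) {
    p <- perturb_attachment(m, sample(ligs, 1),
                            sample(c("tibia", "femur"), 1),
                            runif(1, -3, 3), runif(1, -3, 3))
    expect_lt(max(abs(p$bundles$eps_i - m$bundles$eps_i)), 1e-9)
  }
})

test_that("articular surface meshes are consistently oriented manifolds", {
  m <- nominal_knee()
  s <- build_surfaces(m)
  expect_named(s, c("femur_medial", "femur_lateral", "tibia_medial",
                    "tibia_lateral"))
  for (surf in s) expect_true(check_mesh(surf$vertices, surf$triangles))
  # congruence descriptor: medial tibial radius <= lateral
  expect_lte(s$tibia_medial$radius, s$tibia_lateral$radius)
  # medial dish vertices lie on the dish sphere
  cm <- m$contact$medial
  r <- sqrt(rowSums((s$tibia_medial$vertices -
    matrix(cm$socket_center, nrow(s$tibia_medial$vertices), 3, byrow = TRUE))^2))
  expect_equal(r, rep(cm$socket_radius, length(r)), tolerance = 1e-9)
})

test_that("STL round trip preserves geometry in both dialects", {
  m <- nominal_knee()
  mesh <- build_surfaces(m)$tibia_medial
  fb <- tempfile(fileext = ".stl"); fa <- tempfile(fileext = ".stl")
  write_stl(mesh, fb, ascii = FALSE)
  write_stl(mesh, fa, ascii = TRUE)
  rb <- read_stl(fb); ra <- read_stl(fa)
  expect_equal(nrow(rb$triangles), nrow(mesh$triangles))
  expect_equal(nrow(ra$triangles), nrow(mesh$triangles))
  # float32 storage: coordinates agree to single precision
  expect_equal(sort(rb$vertices), sort(mesh$vertices), tolerance = 1e-6)
  expect_equal(sort(ra$vertices), sort(rb$vertices), tolerance = 1e-6)
})

test_that("malformed STL files are rejected with informative errors", {
  f <- tempfile(fileext = ".stl")
  file.create(f)
  expect_error(read_stl(f), "empty file")
  # truncated binary: header promises more facets than the data holds
  con <- file(f, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(numeric(12), con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(f), "byte offset")
})

test_that("surface and attachment exports round-trip through files", {
  m <- nominal_knee()
  dir <- tempfile("surf")
  paths <- write_surfaces(m, dir)
  expect_length(list.files(dir, pattern = "\\.stl$"), 4)
  surfs <- read_surfaces(dir)
  expect_length(surfs, 4)
  jf <- tempfile(fileext = ".json")
  export_attachments(m, jf)
  j <- jsonlite::read_json(jf)
  expect_named(j, c("frames", "offsets", "bundles"))
  expect_length(j$bundles, 31)
  cf <- tempfile(fileext = ".csv")
  export_bundles(m, cf)
  expect_equal(nrow(utils::read.csv(cf)), 31)
})

test_that("configuration round-trips through YAML", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$ligaments$groups$ACL$k, 5000)
  expect_equal(cfg2$geometry$lateral_radius, Inf)
  expect_equal(cfg2$doe$strain_step, cfg$doe$strain_step)
  # partial override file merges over the defaults
  writeLines("loads:\n  ap_force_N: 50", f)
  cfg3 <- read_config(f)
  expect_equal(cfg3$loads$ap_force_N, 50)
  expect_equal(cfg3$loads$ie_moment_Nm, 8)
})
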