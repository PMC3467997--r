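# force-strain law, zero-load lengths, wrapping, tension composition

test_that("force law matches hand-evaluated values on both branches", {
  expect_equal(force_from_strain(-0.10, 5000, 0.03), 0)
  expect_equal(force_from_strain(0, 5000, 0.03), 0)
  # at the branch point both formulas give k*c
  toe <- 0.25 * 5000 * 0.06^2 / 0.03
  lin <- 5000 * (0.06 - 0.03)
  expect_equal(toe, lin)
  expect_equal(force_from_strain(0.06, 5000, 0.03), 150)
  expect_equal(force_from_strain(0.13, 5000, 0.03), 500)
})

test_that("force law is continuous at 2c and non-decreasing for every group stiffness", {
  ks <- c(5000, 9000, 2750, 1000, 2000, 1000)
  for (k in ks) {
    for (c in c(0.01, 0.03, 0.1)) {
      below <- force_from_strain(2 * c - 1e-12, k, c)
      above <- force_from_strain(2 * c + 1e-12, k, c)
      expect_equal(below, k * c, tolerance = 1e-6)
      expect_equal(above, k * c, tolerance = 1e-6)
      grid <- force_from_strain(seq(-0.2, 0.4, by = 1e-3), k, c)
      expect_true(all(diff(grid) >= 0))
      expect_true(all(grid[seq(-0.2, 0.4, by = 1e-3) < 0] == 0))
    }
  }
})

test_that("strain energy density integrates the force law", {
  k <- 2750; c <- 0.03; L0 <- 25
  for (eps in c(0.01, 0.05, 0.06, 0.12, 0.3)) {
    h <- 1e-6
    L <- L0 * (1 + eps)
    dU <- (L0 * kneelax:::strain_energy_density((L + h) / L0 - 1, k, c) -
           L0 * kneelax:::strain_energy_density((L - h) / L0 - 1, k, c)) / (2 * h)
    expect_equal(dU, force_from_strain(eps, k, c), tolerance = 1e-5)
  }
  expect_equal(kneelax:::strain_energy_density(-0.3, k, c), 0)
})

test_that("zero-load length inverts the reference-strain definition", {
  expect_equal(zero_length_from_reference(20, 0), 20)
  expect_equal(zero_length_from_reference(20, 0.05), 20 / 1.05)
  expect_equal(zero_length_from_reference(20, -0.169), 20 / (1 - 0.169))
  # round trip
  L0 <- zero_length_from_reference(31.4, 0.18)
  expect_equal((31.4 - L0) / L0, 0.18)
  expect_error(zero_length_from_reference(20, -1), "non-physical")
})

test_that("wrapped path matches the analytic cylinder geodesic within 2%", {
  obs <- list(point = c(0, 0, 0), axis = c(1, 0, 0), radius = 5,
              probe_radius = 0)
  p1 <- c(0, 20, -3); p2 <- c(0, -20, -3)
  w <- wrapped_path(p1, p2, obs, joint_pose())
  expect_true(w$wrapped)
  geo <- cylinder_geodesic(p1[2:3], p2[2:3], 5)
  expect_lt(abs(w$L - geo) / geo, 0.02)
  expect_gte(w$L, sqrt(sum((p1 - p2)^2)))
})

test_that("non-penetrating straight paths are unchanged by the obstacle", {
  obs <- list(point = c(0, 0, 0), axis = c(1, 0, 0), radius = 5,
              probe_radius = 0.5)
  p1 <- c(0, 20, 10); p2 <- c(0, -20, 12)  # same side, clears the cylinder
  w <- wrapped_path(p1, p2, obs, joint_pose())
  expect_false(w$wrapped)
  expect_equal(w$L, sqrt(sum((p1 - p2)^2)))
})

test_that("wrapped length is never shorter than the straight path (sweep)", {
  obs <- list(point = c(0, 0, 0), axis = c(1, 0, 0), radius = 5,
              probe_radius = 0.5)
  set.seed(42)
  for (i in 1:1000) {
    p1 <- runif(3, -25, 25); p2 <- runif(3, -25, 25)
    straight <- sqrt(sum((p1 - p2)^2))
    if (straight < 1e-6) next
    w <- wrapped_path(p1, p2, obs, joint_pose())
    expect_gte(w$L, straight - 1e-12)
  }
})

test_that("bundle tension composes path length, strain and force law", {
  m <- nominal_knee()
  # slack pose: large anterior translation slackens the PCL
  b <- m$bundles[m$bundles$ligament == "PCL", ][1, ]
  bt <- bundle_tension(m, b$id, joint_pose())
  eps_ref <- (bt$L - b$L_0) / b$L_0
  expect_equal(bt$strain, eps_ref)
  expect_equal(bt$tension, force_from_strain(eps_ref, b$k, b$c))
  # PCL is slack at full extension (negative reference strain)
  expect_equal(bt$tension, 0)
  expect_equal(sqrt(sum(bt$force_on_tibia^2)), 0)
  # taut ACL bundle: force along the straight path, magnitude from the law
  a <- m$bundles[m$bundles$ligament == "ACL", ][1, ]
  at <- bundle_tension(m, a$id, joint_pose())
  expect_gt(at$tension, 0)
  expect_equal(sqrt(sum(at$force_on_tibia^2)), at$tension, tolerance = 1e-9)
  expect_equal(at$dir_tibia, -at$dir_femur, tolerance = 1e-12)
})

test_that("group stiffness is split equally and sums back exactly", {
  m <- nominal_knee()
  b <- m$bundles
  for (lig in names(m$group_k)) {
    ks <- b$k[b$ligament == lig]
    expect_equal(length(unique(ks)), 1)
    expect_equal(sum(ks), unname(m$group_k[lig]))
  }
  expect_equal(unique(b$k[b$ligament == "ACL"]), 5000 / 10)
})
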