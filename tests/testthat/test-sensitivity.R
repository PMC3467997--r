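# RIM ANOVA statistic, rank scaling, test selection

test_that("RIM is exactly 1 for a response driven by one factor and 0 for others", {
  A <- build_L81()
  y <- A[, 5] - 2  # response equal to the centred level of factor 5
  expect_equal(rim(A[, 5], y), 1.0)
  # SS_A = TSS = 54: 27 * ((-1)^2 + 0 + 1^2) = 54
  expect_equal(sum((y - mean(y))^2), 54)
  for (j in c(1, 12, 23, 40)) expect_equal(rim(A[, j], y), 0)
})

test_that("RIM matches the brute-force group-mean oracle to 1e-12", {
  A <- build_L81()
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    y <- rgamma(81, shape = 2, rate = 0.5)
    j <- sample(40, 1)
    worst <- max(worst, abs(rim(A[, j], y) - rim_oracle(A[, j], y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("degenerate and unbalanced inputs are rejected", {
  A <- build_L81()
  expect_error(rim(A[, 1], rep(3.3, 81)), "degenerate")
  expect_error(rim(A[1:10, 1], rnorm(10)), "not balanced")
  expect_error(rim(A[, 1], rnorm(80)), "lengths differ")
})

test_that("main-effect RIMs never sum above 1, and reach 1 for additive responses", {
  A <- build_L81()
  set.seed(55)
  for (rep in 1:20) {
    y <- rlnorm(81)
    s <- sum(vapply(1:40, function(j) rim(A[, j], y), 0))
    expect_lte(s, 1 + 1e-9)
  }
  # noise-free additive response: main effects explain everything
  coefs <- runif(40, -2, 2)
  y_add <- as.numeric((A - 2) %*% coefs)
  s_add <- sum(vapply(1:40, function(j) rim(A[, j], y_add), 0))
  expect_equal(s_add, 1, tolerance = 1e-6)
})

test_that("rank scaling maps RIM rows linearly onto 1..5", {
  x <- c(0.0, 0.5, 1.0)
  expect_equal(rank_scale(x), c(1L, 3L, 5L))
  expect_equal(rank_scale(c(0.1, 0.1, 0.9))[3], 5L)
  expect_equal(rank_scale(c(0.1, 0.1, 0.9))[1], 1L)
  # midpoint rounds half-up
  expect_equal(rank_scale(c(0, 0.375, 1))[2], 3L)  # 1 + 4*0.375 = 2.5 -> 3
  # monotone input gives monotone ranks
  r <- rank_scale(seq(0.2, 0.8, length.out = 15))
  expect_true(all(diff(r) >= 0))
  expect_warning(r0 <- rank_scale(rep(0.4, 6)), "midpoint")
  expect_equal(r0, rep(3L, 6))
})

test_that("per-ligament aggregation averages the bundle-region ranks", {
  ranks <- matrix(c(5L, 1L,
                    3L, 1L,
                    1L, 5L), 3, 2, byrow = TRUE,
                  dimnames = list(c("ACL-a", "ACL-p", "LCL-a"),
                                  c("AP-00", "VV-00")))
  lm <- ligament_rank_table(ranks)
  expect_equal(lm["ACL", "AP-00"], 4)
  expect_equal(lm["ACL", "VV-00"], 1)
  expect_equal(lm["LCL", "VV-00"], 5)
})

test_that("test selection applies the mean-rank threshold", {
  ranks <- matrix(c(5L, 1L, 2L,
                    5L, 1L, 2L), 2, 3, byrow = TRUE,
                  dimnames = list(c("ACL-a", "ACL-p"),
                                  c("AP-00", "IE-00", "VV-00")))
  expect_equal(select_tests(ranks, threshold = 3)$selected, "AP-00")
  expect_equal(select_tests(ranks, threshold = 1)$selected,
               c("AP-00", "IE-00", "VV-00"))
  expect_length(select_tests(ranks, threshold = 6)$selected, 0)
})

test_that("a planted dominant strain factor earns rank 5 for its laxity test", {
  # simulated laxity that depends only on one strain factor: evaluate the
  # model at the factor's three levels and index by the design column
  m <- nominal_knee()
  A <- build_L81()
  f <- design_factors(m$config)
  lax_at_level <- function(idx, lev, flexion, type) {
    row <- rep(2L, 40); row[idx] <- lev
    run_laxity_test(realize_row(m, row, f), flexion, type)$laxity
  }
  # factor 29: ACL posterior strain -> AP laxity at 0 deg
  ap0 <- vapply(1:3, lax_at_level, 0, idx = 29L, flexion = 0, type = "AP")
  # factor 37: LCL anterior strain -> VV laxity at 0 deg
  vv0 <- vapply(1:3, lax_at_level, 0, idx = 37L, flexion = 0, type = "VV")
  responses <- cbind("AP-00" = ap0[A[, 29]], "VV-00" = vv0[A[, 37]])
  rims <- rim_table(A, responses)
  expect_equal(rims["P29", "AP-00"], 1, tolerance = 1e-9)
  expect_equal(rims["P37", "VV-00"], 1, tolerance = 1e-9)
  expect_lt(max(rims["P29", "VV-00"], rims["P37", "AP-00"]), 1e-9)
  # factors the response ignores have constant (zero) RIM rows: midpoint ranks
  ranks <- suppressWarnings(rank_table(rims))
  expect_equal(unname(ranks["P29", "AP-00"]), 5L)
  expect_equal(unname(ranks["P37", "VV-00"]), 5L)
})

test_that("sensitivity_table assembles RIM, ranks and selection coherently", {
  A <- build_L81()
  set.seed(9)
  ids <- kneelax:::test_ids()
  # additive synthetic responses over the strain factors with varying weights
  resp <- sapply(seq_along(ids), function(j)
    as.numeric((A[, 27:40] - 2) %*% runif(14)) + rnorm(81, sd = 0.05) + 10)
  colnames(resp) <- ids
  st <- sensitivity_table(A, resp, threshold = 3)
  expect_equal(dim(st$rim), c(40, 15))
  expect_true(all(st$rim >= 0 & st$rim <= 1))
  expect_equal(dim(st$ranks_strain), c(14, 15))
  expect_true(all(st$ranks_strain %in% 1:5))
  # within every factor row the max-RIM test has rank 5 and the min rank 1
  for (i in 1:14) {
    r <- st$rim_strain[i, ]
    expect_equal(unname(st$ranks_strain[i, which.max(r)]), 5L)
    expect_equal(unname(st$ranks_strain[i, which.min(r)]), 1L)
  }
  expect_true(all(st$selected %in% ids))
})
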