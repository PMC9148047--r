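# independent oracle: scan candidate values, keep the largest whose
# exceedance volume fraction reaches q percent
.percentile_oracle <- function(values, weights, q) {
  tot <- sum(weights)
  cand <- sort(unique(values), decreasing = TRUE)
  best <- NA_real_
  for (v in cand) {
    if (sum(weights[values >= v]) / tot >= q / 100) { best <- v; break }
  }
  best
}

test_that("exceedance percentile matches hand-computed cases", {
  expect_equal(volume_percentile(c(1, 1, 1, 2), q = 5), 2)
  expect_equal(volume_percentile(c(1, 1, 1, 2), q = 95), 1)
  # 60% of the volume at 2, 40% at 1
  expect_equal(volume_percentile(c(2, 1), c(0.6, 0.4), q = 5), 2)
  expect_equal(volume_percentile(c(2, 1), c(0.6, 0.4), q = 95), 1)
  expect_equal(volume_percentile(c(2, 1), c(0.6, 0.4), q = 50), 2)
  # uniform field: every percentile equals the value
  for (q in c(5, 50, 95))
    expect_equal(volume_percentile(rep(3.3, 7), q = q), 3.3)
  expect_error(volume_percentile(numeric(0), q = 5), "empty region")
})

test_that("percentile agrees with the brute-force oracle on random fields", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    v <- round(runif(n, 0, 10), sample(0:2, 1))
    w <- runif(n, 0.1, 2)
    q <- sample(c(5, 20, 50, 80, 95), 1)
    expect_equal(volume_percentile(v, w, q), .percentile_oracle(v, w, q))
  }
})

test_that("heterogeneity coefficients reproduce closed-form cases", {
  mats <- default_materials()
  map <- coaxtherm:::.map_skeleton(seq(0, 0.02, by = 5e-4),
                                   seq(-0.02, 0.02, by = 5e-4), mats)
  class(map) <- "material_map"
  # uniform field -> zero heterogeneity
  u <- matrix(7, map$nr, map$nz)
  loss_u <- structure(list(p_loss = u, map = map), class = "loss_field")
  expect_equal(eta_P(loss_u, voi_spec(), map), 0)
  expect_equal(eta_T(u * 0 + 40, voi_spec(), map), 0)
  # two-level temperature field split at z = 0: (40 - 30)/40
  two <- matrix(30, map$nr, map$nz)
  two[, map$zc > 0] <- 40
  expect_equal(eta_T(two, voi_spec(n = 50), map), 0.25, tolerance = 0.02)
  # eta_P is invariant under positive rescaling of the field
  f <- matrix(runif(map$nr * map$nz, 1, 3), map$nr, map$nz)
  lf <- structure(list(p_loss = f, map = map), class = "loss_field")
  lf2 <- structure(list(p_loss = 17.3 * f, map = map), class = "loss_field")
  expect_equal(eta_P(lf, voi_spec(), map), eta_P(lf2, voi_spec(), map),
               tolerance = 1e-12)
  expect_error(eta_P(structure(list(p_loss = 0 * f, map = map),
                               class = "loss_field"), voi_spec(), map),
               "undefined metric")
})

test_that("VOI sampling integrates the cube volume within 1%", {
  mats <- default_materials()
  map <- coaxtherm:::.map_skeleton(seq(0, 0.02, by = 5e-4),
                                   seq(-0.02, 0.02, by = 5e-4), mats)
  class(map) <- "material_map"
  ones <- structure(list(p_loss = matrix(1, map$nr, map$nz), map = map),
                    class = "loss_field")
  got <- alpha_voi(ones, voi_spec(), supplied_power = 100, map) / 100 * 100
  expect_equal(got, 1e-6, tolerance = 0.01)   # 1 cm^3 in m^3
})

test_that("deposited-power fraction handles the degenerate splits", {
  mats <- default_materials()
  map <- coaxtherm:::.map_skeleton(seq(0, 0.02, by = 5e-4),
                                   seq(-0.02, 0.02, by = 5e-4), mats)
  class(map) <- "material_map"
  inside <- matrix(0, map$nr, map$nz)
  lat_r <- sqrt(2) / 2 * 0.005               # cube circumradius in the plane
  inside[map$rc < lat_r, abs(map$zc) < 0.005] <- 1
  # all loss inside the VOI, supplied = absorbed -> alpha can only reach the
  # cube fraction of the rasterized region; uniform-zero in VOI -> 0
  zero <- structure(list(p_loss = 0 * inside, map = map), class = "loss_field")
  expect_equal(alpha_voi(zero, voi_spec(), 1, map), 0)
  P <- sum(inside * cell_volumes(map))
  all_in <- structure(list(p_loss = inside, map = map), class = "loss_field")
  expect_gt(alpha_voi(all_in, voi_spec(), P, map), 70)
  expect_lte(alpha_voi(all_in, voi_spec(), P, map), 100 + 1e-6)
})

test_that("profile extraction normalizes at the origin", {
  em <- fast_proto()
  pr <- extract_profiles(em$loss$sar, em$map, "radial", normalize = TRUE)
  expect_equal(pr$value[1], 1, tolerance = 0.02)
  expect_true(all(pr$coord_cm < 1.5))
  pz <- extract_profiles(em$loss$sar, em$map, "longitudinal")
  expect_true(all(abs(pz$coord_cm) < 5))
})
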