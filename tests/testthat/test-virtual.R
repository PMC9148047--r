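test_that("probe layout honours the documented point constraints", {
  lay <- probe_layout()
  pts <- lay$points
  expect_equal(nrow(pts), 14)
  expect_equal(unlist(pts[pts$id == 3, c("r_cm", "z_cm")]), c(r_cm = 0, z_cm = 0))
  expect_setequal(pts$z_cm[pts$id %in% c(2, 4)], c(2, -2))
  expect_equal(unlist(pts[pts$id == 9, c("r_cm", "z_cm")]),
               c(r_cm = 0.5, z_cm = 0))
  expect_equal(unlist(pts[pts$id == 12, c("r_cm", "z_cm")]),
               c(r_cm = 1, z_cm = 0))
  # 2 cm grid along each fiber, all points inside the 3 x 10 cm phantom
  expect_true(all(pts$z_cm %% 2 == 0))
  expect_true(all(abs(pts$z_cm) <= 5 & pts$r_cm <= 1.5))
  expect_setequal(unique(pts$r_cm), c(0, 0.5, 1))
})

test_that("noise-free probes reproduce the solver output exactly and seeds are reproducible", {
  fp <- fast_proto()
  ser <- run_transient(fp$map, fp$loss, power_schedule(5, 60), dt = 5,
                       duration = 60)
  clean <- sample_probes(ser, probe_layout(), noise_model(fiber_sd = 0))
  ids <- ser$probe_points$id
  for (k in c(3, 9, 12))
    expect_equal(clean$temperature_C[clean$point_id == k],
                 unname(ser$probe[, ids == k]))
  a <- sample_probes(ser, noise = noise_model(seed = 123))
  b <- sample_probes(ser, noise = noise_model(seed = 123))
  expect_identical(a, b)
  c2 <- sample_probes(ser, noise = noise_model(seed = 124))
  expect_false(identical(a$temperature_C, c2$temperature_C))
})

test_that("fiber noise has the configured standard deviation", {
  fp <- fast_proto()
  # hold the phantom at a uniform 43 C: zero power from a 43 C ambient
  ser <- run_transient(fp$map, fp$loss, power_schedule(0, 1000),
                       T_ext = 43, dt = 1, duration = 1000)
  rd <- sample_probes(ser, noise = noise_model(fiber_sd = 0.05, seed = 5))
  x <- rd$temperature_C[rd$point_id == 3]
  expect_gte(length(x), 1000)
  s <- sd(x - 43)
  # 99% chi-square band for sd of ~1000 draws at sd = 0.05
  expect_gt(s, 0.045)
  expect_lt(s, 0.055)
})

test_that("virtual infrared image mirrors the half-plane and needs cooling data", {
  fp <- fast_proto()
  ser <- run_transient(fp$map, fp$loss, power_schedule(5, 120), dt = 2,
                       duration = 120, save_every = 10)
  expect_error(ir_snapshot(ser, delay = 60), "power-off")
  cooled <- cooling_phase(ser, 100, save_every = 10)
  expect_error(ir_snapshot(cooled, delay = 300), "insufficient cooling")
  img <- ir_snapshot(cooled, delay = 60, noise = noise_model(ir_sd = 0))
  # exact left-right mirror symmetry without noise
  expect_equal(img$image, img$image[rev(seq_along(img$x_cm)), ],
               tolerance = 1e-12)
  # maximum on the axis row, at the aperture-centre column
  idx <- arrayInd(which.max(img$image), dim(img$image))
  expect_lt(abs(img$x_cm[idx[1]]), 0.2)
  expect_lt(abs(img$z_cm[idx[2]]), 0.5)
  img2 <- ir_snapshot(cooled, delay = 60, noise = noise_model(seed = 9))
  img3 <- ir_snapshot(cooled, delay = 60, noise = noise_model(seed = 9))
  expect_identical(img2$image, img3$image)
})

test_that("phantom property sampling is positive, unbiased and seed-stable", {
  expect_equal(sample_phantom_properties(relative_sd = 0)$sigma, 0.755)
  draws <- vapply(1:1000, function(i)
    sample_phantom_properties(noise_model(seed = i), 0.02)$sigma, numeric(1))
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 0.755, tolerance = 0.005)
  expect_identical(sample_phantom_properties(noise_model(seed = 3)),
                   sample_phantom_properties(noise_model(seed = 3)))
})

test_that("power-meter traces track the schedule", {
  s <- power_schedule(3.6, duration = 700)
  exact <- power_trace(s, noise_model(power_rel_sd = 0))
  expect_equal(exact$power_W[exact$time_s < 700],
               rep(3.6, sum(exact$time_s < 700)))
  noisy <- power_trace(s, noise_model(seed = 2))
  hold <- noisy$power_W[noisy$time_s < 700]
  expect_gte(length(hold), 600)
  expect_equal(mean(hold), 3.6, tolerance = 0.005)
  expect_identical(power_trace(s, noise_model(seed = 4)),
                   power_trace(s, noise_model(seed = 4)))
})

test_that("ambient sampling stays inside the climate-control band", {
  amb <- vapply(1:200, function(i) sample_ambient(noise_model(seed = i)),
                numeric(1))
  expect_true(all(amb >= 20.5 & amb <= 22.5))
  expect_gt(diff(range(amb)), 0.5)
})
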