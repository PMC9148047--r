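test_that("matched uniform line reproduces the analytic characteristic impedance", {
  ml <- matched_line()
  expect_true(ml$sol$converged)
  Z0 <- coax_impedance(11.7, 3.5, 2.1)
  expect_equal(Mod(ml$sol$input_impedance), Z0, tolerance = 0.02)
})

test_that("delivered power into a matched line follows the source circuit", {
  # ideal matched 50-Ohm load with a 1 V, 50-Ohm source: V^2/(8R) = 2.5 mW;
  # the numerical feed carries a small parasitic gap reactance
  ml <- matched_line()
  expect_equal(delivered_power(ml$sol), 1 / (8 * 50), tolerance = 0.15)
  expect_gt(delivered_power(ml$sol), 0)
})

test_that("loss density follows the closed form and vanishes without conductivity", {
  mats <- default_materials()
  map <- coaxtherm:::.map_skeleton(seq(0, 0.01, by = 1e-3),
                                  seq(0, 0.01, by = 1e-3), mats)
  class(map) <- "material_map"
  nr <- map$nr; nz <- map$nz
  map$cell_material[] <- match("agar gel", mats$name)
  sol <- structure(list(Er = matrix(1 + 0i, nr, nz + 1),
                        Ez = matrix(0i, nr + 1, nz), converged = TRUE),
                   class = "phasor_solution")
  loss <- compute_sar(sol, map)
  expect_equal(unique(as.vector(loss$p_loss)), 0.5 * 0.755)
  expect_equal(unique(as.vector(loss$sar)), 0.5 * 0.755 / 1000)
  # sigma = 0 everywhere -> identically zero loss
  map$cell_material[] <- match("air", mats$name)
  loss0 <- compute_sar(sol, map)
  expect_true(all(loss0$p_loss == 0))
  expect_equal(loss0$total_absorbed, 0)
  # unconverged input is refused
  sol$converged <- FALSE
  expect_error(compute_sar(sol, map), "unconverged")
})

test_that("reflection coefficient handles matched, shorted and degenerate feeds", {
  fake <- function(V, I) structure(list(feed_voltage = V, feed_current = I,
                                        input_impedance = V / I,
                                        converged = TRUE),
                                   class = "phasor_solution")
  expect_equal(compute_s11(fake(50 + 0i, 1 + 0i)), -120)   # Zin = Z0 -> floor
  expect_equal(compute_s11(fake(0 + 0i, 1 + 0i)), 0)       # short -> 0 dB
  expect_error(compute_s11(fake(1 + 0i, 0i)), "degenerate")
})

test_that("tangential E vanishes on conductor sheets at steady state", {
  fp <- fast_proto()
  map <- fp$map
  ie_d <- which(abs(map$r_edges - 0.0175) < 1e-9)
  on_sheet <- map$pec_ez[ie_d, ]
  expect_true(all(Mod(fp$sol$Ez[ie_d, on_sheet]) == 0))
  ie_D <- which(abs(map$r_edges - 0.0585) < 1e-9)
  expect_true(all(Mod(fp$sol$Ez[ie_D, map$pec_ez[ie_D, ]]) == 0))
})

test_that("prototype power balance closes within 5%", {
  em <- char_proto()
  expect_true(em$sol$converged)
  expect_lte(em$loss$total_absorbed, delivered_power(em$sol) * 1.05)
  expect_gte(em$loss$total_absorbed, delivered_power(em$sol) * 0.95)
})

test_that("prototype SAR focuses at the aperture centre", {
  em <- char_proto()
  fc <- sar_focus(em$loss, em$map)
  expect_gt(fc$center_to_max, 0.95)
  pr <- extract_profiles(em$loss$sar, em$map, "radial", normalize = TRUE)
  pz <- extract_profiles(em$loss$sar, em$map, "longitudinal", normalize = TRUE)
  expect_lt(abs(pr$coord_cm[which.max(pr$value)]), 0.3)
  expect_lt(abs(pz$coord_cm[which.max(pz$value)]), 0.5)
  # faster decay away from the focus along z than along r
  at <- function(p, x) approx(p$coord_cm, p$value, x)$y
  expect_lt(at(pz, 1.4), at(pr, 1.4))
})

test_that("focus SAR is grid-converged", {
  em1 <- char_proto()                      # 1 mm
  fp <- fast_proto()                       # 2 mm, reduced padding
  s1 <- interp_field(em1$map, em1$loss$sar, 0, 0) / em1$loss$total_absorbed
  s2 <- interp_field(fp$map, fp$loss$sar, 0, 0) / fp$loss$total_absorbed
  expect_equal(s1, s2, tolerance = 0.05)
})

test_that("an unstable Courant setting is rejected as configuration error", {
  expect_error(run_ctrl(courant = 1.2), "Courant")
  expect_error(run_ctrl(courant = 0), "Courant")
})
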