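test_that("coaxial impedance relation matches its closed form", {
  # hand evaluation: 138 * log10(11.7/3.5) / sqrt(2.1) = 49.91 Ohm
  expect_equal(coax_impedance(11.7, 3.5, 2.1), 49.91, tolerance = 1e-4)
  expect_equal(coax_impedance(5, 5, 2.1), 0)
  expect_equal(round(solve_outer_diameter(50, 3.5, 2.1), 1), 11.7)
  expect_equal(solve_outer_diameter(0, 3.5, 2.1), 3.5)
  expect_equal(solve_outer_diameter(50, 2.2, 2.1), 7.37, tolerance = 1e-3)
  expect_equal(solve_outer_diameter(50, 4.3, 2.1), 14.40, tolerance = 1e-3)
  expect_error(coax_impedance(3, 5), "invalid")
  expect_error(coax_impedance(-1, -2), "invalid")
  expect_error(solve_outer_diameter(50, -1), "d must")
})

test_that("sizing round-trips and the 50-Ohm diameter ratio is constant", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(1, 0.5, 10); Z <- runif(1, 5, 120); eps <- runif(1, 1, 10)
    D <- solve_outer_diameter(Z, d, eps)
    expect_equal(coax_impedance(D, d, eps), Z, tolerance = 1e-9)
  }
  ratio <- solve_outer_diameter(50, c(2.2, 3.5, 4.3), 2.1) / c(2.2, 3.5, 4.3)
  expect_equal(ratio, rep(ratio[1], 3), tolerance = 1e-12)
  expect_equal(ratio[1], 3.35, tolerance = 1e-3)
})

test_that("geometry invariants are enforced", {
  g <- prototype_geometry()
  expect_s3_class(g, "applicator_geometry")
  expect_equal(g$tube_wall, 0.25)
  expect_error(applicator_geometry(d = 3.5, D = 3.0), "D > d")
  expect_error(applicator_geometry(w = 8, h = 8), "w < h")
  expect_error(applicator_geometry(w = -1), "positive")
  expect_error(applicator_geometry(phantom_diameter = 4), "tube_outer_diameter")
})

test_that("material table carries the simulation properties", {
  m <- default_materials()
  expect_equal(material_lookup(m, "agar gel")$sigma, 0.755)
  expect_equal(material_lookup(m, "agar gel")$eps_r, 74)
  expect_equal(material_lookup(m, "HDPE")$eps_r, 2.1)
  expect_equal(material_lookup(m, "HDPE")$rho, 950)
  expect_equal(material_lookup(m, "PVC")$k, 0.2)
  expect_true(material_lookup(m, "brass")$is_pec)
  expect_error(material_lookup(m, "wood"), "unknown material")
  expect_error(material_properties("x", rho = -1, 0, 1, 1, 1), "rho")
})

test_that("material tables round-trip through CSV", {
  m <- default_materials()
  p <- withr::local_tempfile(fileext = ".csv")
  write_materials_csv(m, p)
  m2 <- read_materials_csv(p)
  expect_equal(m2$name, m$name)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$is_pec, m$is_pec)
})
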