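test_that("rasterized map has the expected structure and conductor outline", {
  map <- build_material_map(prototype_geometry(domain_padding = 8),
                            resolution_spec(fine_mm = 1))
  expect_true(all(diff(map$r_edges) > 0))
  expect_true(all(diff(map$z_edges) > 0))
  expect_equal(map$r_edges[1], 0)
  expect_true(all(map$cell_material >= 1 &
                  map$cell_material <= nrow(map$materials)))

  # inner-conductor sheet is broken only along the aperture and feed gap
  ie_d <- which(abs(map$r_edges - 0.0175) < 1e-9)
  on_sheet <- map$pec_ez[ie_d, ]
  zc <- map$zc
  inside <- zc > -0.04 & zc < 0.04
  gaps <- which(inside & !on_sheet)
  feed_js <- vapply(map$ports, function(p) p$j, integer(1))
  aperture <- abs(zc[gaps]) < 0.0085 + 1e-9
  expect_true(all(aperture | gaps %in% feed_js))
  expect_equal(sum(aperture), sum(abs(zc) < 0.0085))
  # outer conductor continuous over the full height
  ie_D <- which(abs(map$r_edges - 0.0585) < 1e-9)
  expect_true(all(map$pec_ez[ie_D, inside]))

  # phantom cell count matches the grid arithmetic (fine radially, at worst
  # mid spacing axially away from the aperture band)
  agar <- sum(map$materials$name[map$cell_material] == "agar gel")
  expect_gte(agar, round(0.015 / 1e-3) * round(0.10 / 2e-3))
})

test_that("under-resolved layers trigger a resolution error", {
  expect_error(build_material_map(prototype_geometry(),
                                  resolution_spec(fine_mm = 2)),
               "resolution error")
  expect_silent(build_material_map(prototype_geometry(domain_padding = 8),
                                   resolution_spec(fine_mm = 2),
                                   strict = FALSE))
})

test_that("rasterized material volumes converge to the analytic volumes", {
  geom <- prototype_geometry(domain_padding = 6)
  cm3 <- 1e-6
  analytic <- c(
    "agar gel" = pi * 1.5^2 * 10 * cm3,
    "PVC" = pi * (1.75^2 - 1.5^2) * 10 * cm3,
    "HDPE" = pi * (5.85^2 - 1.75^2) * 8 * cm3)
  err <- sapply(c(2, 1), function(fm) {
    v <- map_volumes(build_material_map(geom, resolution_spec(fine_mm = fm),
                                        strict = FALSE))
    max(abs(v[names(analytic)] - analytic) / analytic)
  })
  expect_lt(err[2], 0.02)
  expect_lte(err[2], err[1] + 1e-12)
})

test_that("cell volumes integrate the cylinder exactly", {
  map <- build_material_map(prototype_geometry(domain_padding = 6),
                            resolution_spec(fine_mm = 2), strict = FALSE)
  expect_equal(sum(cell_volumes(map)),
               pi * max(map$r_edges)^2 * diff(range(map$z_edges)),
               tolerance = 1e-12)
})
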