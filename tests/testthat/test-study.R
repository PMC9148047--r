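test_that("single-combination sweep derives the prototype outer diameter", {
  sw <- run_sweep(sweep_spec(d_values = 3.5, w_values = 1.7),
                  resolution_spec(fine_mm = 2), domain_padding = 8)
  expect_equal(nrow(sw), 1)
  expect_equal(round(sw$D, 1), 11.7)
  expect_true(sw$converged)
  expect_true(is.finite(sw$eta_P) && sw$eta_P >= 0 && sw$eta_P < 1)
  expect_true(sw$alpha > 0 && sw$alpha < 100)
  # deterministic: a rerun reproduces the row exactly
  sw2 <- run_sweep(sweep_spec(d_values = 3.5, w_values = 1.7),
                   resolution_spec(fine_mm = 2), domain_padding = 8)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  # single-row selection returns that row
  expect_equal(select_design(sw)$w, 1.7)
})

test_that("selection rule rejects an empty feasible set", {
  row <- data.frame(d = 3.5, w = 0.7, D = 11.7, eta_P = 0.1, alpha = 5,
                    focus_r_cm = 0, focus_z_cm = 0, center_to_max = 1,
                    delivered_W = 1e-3, converged = TRUE)
  sw <- rbind(row, transform(row, w = 0.9))
  class(sw) <- c("sweep_result", class(sw))
  expect_error(select_design(sw), "empty feasible set")
  none <- transform(row, converged = FALSE)
  class(none) <- c("sweep_result", class(none))
  expect_error(select_design(none), "no converged")
})

test_that("transient experiment scales with power and is flat at zero power", {
  fp <- fast_proto()
  ex <- experiment_transients(power_levels = c(0, 1, 2), heat_duration = 240,
                              cool_duration = 60, em = fp, dt = 2,
                              noise = noise_model(fiber_sd = 0, seed = 1))
  s0 <- ex$summary[ex$summary$power_W == 0, ]
  expect_true(all(abs(s0$peak_C - 21.5) < 1e-9))
  p3 <- sapply(c(0, 1, 2), function(P)
    ex$summary$peak_C[ex$summary$power_W == P & ex$summary$point_id == 3])
  expect_true(all(diff(p3) > 0))
  # conduction is linear in the deposited power
  expect_equal(p3[3] - 21.5, 2 * (p3[2] - 21.5), tolerance = 1e-6)
})

test_that("temperature reduction conventions are both exposed", {
  expect_equal(temp_reduction(46.7, 43.2, type = "absolute"), 7.494647,
               tolerance = 1e-6)
  expect_equal(temp_reduction(46.7, 43.2, T_ext = 21.5, type = "rise"),
               100 * 3.5 / 25.2, tolerance = 1e-6)
  expect_equal(temp_reduction(40, 40), 0)
})

test_that("focus experiment at zero power gives a uniform ambient image", {
  fp <- fast_proto()
  ex <- experiment_focus(power = 0, heat_duration = 60, delay = 30, em = fp,
                         dt = 5, noise = noise_model(ir_sd = 0, seed = 1))
  expect_equal(ex$eta_T, 0, tolerance = 1e-9)
  expect_true(all(abs(ex$image$image - 21.5) < 1e-9))
  expect_equal(ex$center_C, 21.5, tolerance = 1e-9)
})
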