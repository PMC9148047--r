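test_that("loss rescaling is exact and linear", {
  fp <- fast_proto()
  l5 <- scale_loss(fp$loss, 5)
  expect_equal(l5$total_absorbed, 5, tolerance = 1e-12)
  V <- cell_volumes(fp$map)
  expect_equal(sum(l5$p_loss * V), 5, tolerance = 1e-9)
  l0 <- scale_loss(fp$loss, 0)
  expect_true(all(l0$p_loss == 0))
  l1 <- scale_loss(fp$loss, 1)
  expect_equal(scale_loss(l1, 3.6)$p_loss, 3.6 * l1$p_loss, tolerance = 1e-12)
  expect_error(scale_loss(l0, 2), "zero total absorbed")
})

test_that("zero power from a uniform ambient state stays at ambient", {
  fp <- fast_proto()
  ser <- run_transient(fp$map, fp$loss, power_schedule(0, 60),
                       T_ext = 21.5, dt = 5, duration = 60)
  expect_true(all(abs(ser$probe - 21.5) < 1e-9))
  expect_true(all(abs(ser$final_field - 21.5) < 1e-9))
})

test_that("steady heated cylinder matches the analytic parabolic profile", {
  hc <- heated_cylinder()
  Ts <- thermal_steady(hc$map, hc$loss, power = hc$loss$total_absorbed,
                       T_ext = 21.5)
  jmid <- which.min(abs(hc$map$zc))
  analytic <- 21.5 + hc$q * (hc$R^2 - hc$map$rc^2) / (4 * hc$k)
  relerr <- abs(Ts[, jmid] - analytic) / (analytic - 21.5)
  expect_lt(max(relerr), 0.01)
})

test_that("per-step energy balance closes to solver precision", {
  fp <- fast_proto()
  ser <- run_transient(fp$map, fp$loss, power_schedule(3.6, 300),
                       dt = 2, duration = 300)
  expect_lt(abs(ser$diag$balance_residual) / ser$diag$energy_in, 0.005)
  expect_equal(ser$diag$energy_in, 3.6 * 300, tolerance = 1e-9)
})

test_that("cooling obeys the maximum principle", {
  fp <- fast_proto()
  ser <- run_transient(fp$map, fp$loss, power_schedule(5, 300),
                       dt = 2, duration = 300, save_every = 20)
  cool <- cooling_phase(ser, 300, save_every = 20)
  after_off <- cool$snap_times > cool$power_off_time
  maxes <- vapply(cool$snapshots[after_off], max, numeric(1))
  expect_true(all(diff(maxes) <= 1e-9))
  expect_lt(max(cool$final_field), max(ser$final_field))
  # cooling from a uniform ambient state changes nothing
  flat <- run_transient(fp$map, fp$loss, power_schedule(0, 40), dt = 5,
                        duration = 40)
  flat2 <- cooling_phase(flat, 40)
  expect_true(all(abs(flat2$final_field - 21.5) < 1e-9))
})

test_that("the transient is insensitive to halving the time step", {
  fp <- fast_proto()
  a <- run_transient(fp$map, fp$loss, power_schedule(3.6, 2400),
                     dt = 2, duration = 2400)
  b <- run_transient(fp$map, fp$loss, power_schedule(3.6, 2400),
                     dt = 1, duration = 2400)
  expect_lt(max(abs(a$final_field - b$final_field)), 0.05)
})

test_that("peak temperature rise is spatially converged", {
  fp <- fast_proto()
  em1 <- char_proto()
  a <- run_transient(fp$map, fp$loss, power_schedule(3.6, 600), dt = 2,
                     duration = 600)
  b <- run_transient(em1$map, em1$loss, power_schedule(3.6, 600), dt = 2,
                     duration = 600)
  ids <- a$probe_points$id
  dTa <- max(a$probe[, ids == 3]) - 21.5
  dTb <- max(b$probe[, ids == 3]) - 21.5
  expect_equal(dTa, dTb, tolerance = 0.02)
})

test_that("schedules validate and evaluate piecewise", {
  s <- power_schedule(data.frame(start = c(0, 120), end = c(120, 720),
                                 power = c(18, 3.2)))
  expect_equal(schedule_power(s, c(0, 60, 119, 120, 700, 800)),
               c(18, 18, 18, 3.2, 3.2, 0))
  expect_error(power_schedule(data.frame(start = 0, end = 0, power = 1)),
               "end > start")
  expect_error(power_schedule(data.frame(start = c(0, 50), end = c(100, 150),
                                         power = c(1, 1))), "non-overlapping")
  expect_error(power_schedule(-1, duration = 10), "powers must be >= 0")
})

test_that("controller holds the target and a trivial target needs no power", {
  fp <- fast_proto()
  idle <- run_controlled(fp$map, fp$loss,
                         temperature_controller(target = 21.5, preheat_time = 0),
                         dt = 5, duration = 100)
  expect_true(all(idle$power <= 1e-9))
  expect_true(all(abs(idle$probe - 21.5) < 1e-9))

  hold <- run_controlled(fp$map, fp$loss,
                         temperature_controller(target = 43),
                         dt = 2, duration = 720)
  ids <- hold$probe_points$id
  last10 <- hold$times >= 120
  expect_equal(mean(hold$probe[last10, ids == 3]), 43, tolerance = 0.5 / 43)
  expect_false(hold$unstable)
  expect_true(all(hold$power <= 20 + 1e-9 & hold$power >= 0))
})

test_that("scripted waveform replays preheat then hold", {
  fp <- fast_proto()
  ser <- run_controlled(fp$map, fp$loss,
                        temperature_controller(target = 43, mode = "scripted",
                                               preheat_power = 18,
                                               preheat_time = 120,
                                               hold_power = 3.2),
                        dt = 2, duration = 300)
  expect_equal(unique(ser$power[ser$times < 120]), 18)
  expect_equal(unique(ser$power[ser$times >= 120 & ser$times < 298]), 3.2)
})
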