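test_that("simulated breath follows the closed-form equation of motion", {
  br <- example_breath()
  # constant inspiratory flow V_T / T_I = 0.4 / 1.0 L/s over the limb
  insp <- br$insp_start:(br$insp_end - 1)
  expect_equal(unique(br$flow[insp]), 0.4)
  # end-inspiratory pressure approaches PEEP + V_T/C_RS + R_RS * flow
  # = 5 + 400/30 + 4 cmH2O; discretisation leaves one elastic sample step
  expect_equal(max(br$paw), 5 + 400 / 30 + 0.4 * 10, tolerance = 0.1 / 22)
  # pressure at the first sample carries only PEEP and the resistive step
  expect_equal(br$paw[1], 5 + 0.4 * 10)
})

test_that("zero resistance gives a linear pressure ramp from PEEP", {
  br <- example_breath(r_rs = 0)
  insp <- br$insp_start:(br$insp_end - 1)
  expect_equal(br$paw[1], 5)
  expect_lt(max(abs(diff(diff(br$paw[insp])))), 1e-12)  # constant slope
  expect_equal(max(br$paw[insp]), 5 + 400 / 30 * (1 - 1 / 200),
               tolerance = 1e-10)
})

test_that("pressure during a hold is the static plateau when purely elastic", {
  br <- example_breath(hold = 0.5)
  hold <- br$hold_start:br$hold_end
  expect_true(br$has_hold)
  expect_equal(unique(br$flow[hold]), 0)
  expect_equal(br$paw[hold], rep(5 + 400 / 30, length(hold)), tolerance = 1e-12)
})

test_that("volume is the trapezoidal integral of flow and reaches V_T", {
  for (br in list(example_breath(), example_breath(hold = 2),
                  example_breath(c_rs = 15, r_rs = 22))) {
    dt <- 1 / br$sample_rate
    ref <- cumsum(c(0, (br$flow[-length(br$flow)] + br$flow[-1]) * dt / 2))
    expect_lt(max(abs(br$volume - ref)), 1e-9)
    expect_equal(max(br$volume), 0.4, tolerance = 1e-9)
    expect_true(all(diff(br$time) - dt < 1e-12))
  }
})

test_that("plateau pressure after a long hold matches PEEP + V_T/C_RS", {
  for (crs in c(12, 30, 38)) {
    br <- example_breath(hold = 2, c_rs = crs)
    p_plat <- mean(br$paw[(br$hold_end - 39):br$hold_end])
    expect_equal(p_plat, 5 + 400 / crs, tolerance = 0.01 / (5 + 400 / crs))
  }
})

test_that("viscoelastic pressure exceeds the plateau and relaxes during hold", {
  br <- example_breath(hold = 2, viscoelastic_fraction = 0.15)
  clean <- example_breath(hold = 2)
  expect_gt(max(br$paw), max(clean$paw))
  hold <- br$hold_start:br$hold_end
  expect_true(all(diff(br$paw[hold]) <= 0))          # monotone relaxation
  # after 2 s the Kelvin-body remnant is exp(-2) of its end-inspiratory value
  remnant <- br$paw[br$hold_end] - (5 + 400 / 30)
  expect_gt(remnant, 0)
  expect_lt(remnant, 0.2)
})

test_that("invalid parameters and too-coarse sampling are rejected", {
  expect_error(mechanics_params(-5, 10, 5), class = "ventrobust_invalid_parameter")
  expect_error(mechanics_params(30, 10, 5, viscoelastic_fraction = 1),
               class = "ventrobust_invalid_parameter")
  expect_error(ventilator_settings(tidal_volume = 0),
               class = "ventrobust_invalid_parameter")
  expect_error(
    simulate_breath(default_params(),
                    ventilator_settings(sample_rate = 20)),  # 20 insp samples
    class = "ventrobust_resolution_error")
})

test_that("pool generation is seed-deterministic and honours ranges", {
  p1 <- generate_pool(10, seed = 3)
  p2 <- generate_pool(10, seed = 3)
  expect_identical(p1, p2)
  p3 <- generate_pool(10, seed = 4)
  expect_false(identical(
    vapply(p1, function(r) r$truth$c_rs, numeric(1)),
    vapply(p3, function(r) r$truth$c_rs, numeric(1))))
  # each record pairs regular and hold breaths from identical parameters
  for (rec in p1[1:3]) {
    expect_false(rec$regular$has_hold)
    expect_true(rec$hold$has_hold)
    expect_identical(rec$regular$meta$truth, rec$hold$meta$truth)
  }
  # degenerate range pins the parameter
  pd <- generate_pool(10, pool_sampler_config(c_rs = c(30, 30)), seed = 5)
  expect_equal(vapply(pd, function(r) r$truth$c_rs, numeric(1)), rep(30, 10))
})

test_that("sampled compliance matches its uniform distribution", {
  pool <- generate_pool(1000, seed = 21)
  crs <- vapply(pool, function(r) r$truth$c_rs, numeric(1))
  # uniform on [10, 40]: mean 25, SE = 30/sqrt(12)/sqrt(n)
  se <- 30 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(crs) - 25), 3 * se)
  expect_true(all(crs >= 10 & crs <= 40))
})

test_that("degenerate sampler configurations are rejected", {
  expect_error(pool_sampler_config(c_rs = c(40, 10)),
               class = "ventrobust_invalid_configuration")
  expect_error(pool_sampler_config(v_t = c(0, 0.4)),
               class = "ventrobust_invalid_configuration")
  expect_error(generate_pool(0), class = "ventrobust_invalid_configuration")
})
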