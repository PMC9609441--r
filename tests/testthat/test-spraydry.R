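test_that("dryer_config validates positivity and derives the residence time", {
  cfg <- dryer_config()
  expect_equal(cfg$residence_time_s, 5 / 800 * 3600)   # 22.5 s
  expect_error(dryer_config(air_flow_Lh = -1), "positive")
  expect_error(dryer_config(droplet_gsd = 0.5), "gsd")
})

test_that("lognormal droplet classes have uniform weights and ordered sizes", {
  d <- lognormal_droplets(20e-6, 1.8, 5)
  expect_equal(sum(d$weight), 1)
  expect_equal(d$weight, rep(0.2, 5))
  expect_true(all(diff(d$size) > 0))
  # gsd = 1 collapses onto the median
  d1 <- lognormal_droplets(20e-6, 1, 3)
  expect_equal(d1$size, rep(20e-6, 3), tolerance = 1e-12)
})

test_that("saturation pressure matches anchor points of the Magnus law", {
  expect_equal(saturation_pressure(273.15), 610.94)
  expect_equal(saturation_pressure(373.15), 101325, tolerance = 0.02 * 101325)
  expect_true(all(diff(saturation_pressure(seq(280, 350, 5))) > 0))
  expect_error(saturation_pressure(500), "validity")
})

test_that("relative humidity is 1 at saturation", {
  T <- 305
  ps <- saturation_pressure(T)
  y_sat <- 0.622 * ps / (101325 - ps)
  expect_equal(relative_humidity(T, y_sat), 1, tolerance = 1e-12)
  expect_lt(relative_humidity(T, y_sat / 2), 1)
})

test_that("wet bulb lies below dry bulb and closes the adiabatic balance", {
  twb <- wet_bulb(383.15, 0.005)
  expect_lt(twb, 383.15)
  expect_gt(twb, 273.15)
  # the returned root satisfies the saturation balance
  ps <- saturation_pressure(twb)
  ysat <- 0.622 * ps / (101325 - ps)
  lhs <- (1006 + 0.005 * 1880) * (383.15 - twb)
  rhs <- 2.4e6 * (ysat - 0.005)
  expect_equal(lhs, rhs, tolerance = 1e-4 * abs(lhs))
  # saturated air: wet bulb equals dry bulb
  expect_equal(wet_bulb(305, 1), 305)
  # wetter air has a higher wet bulb
  expect_gt(wet_bulb(383.15, 0.02), twb)
})

test_that("drying-rate laws behave at their edges", {
  expect_equal(unhindered_rate(50, 2.4e6, 1e-6, 380, 320),
               50 / 2.4e6 * 1e-6 * 60)
  expect_equal(unhindered_rate(50, 2.4e6, 1e-6, 320, 320), 0)
  expect_error(unhindered_rate(50, 0, 1, 2, 1), "lambda")
  expect_equal(relative_drying_rate(2, 1), 1)     # above critical: unhindered
  expect_equal(relative_drying_rate(0.5, 1), 0.5) # falling rate: linear
  expect_equal(relative_drying_rate(0, 1), 0)     # dry particle stops drying
  expect_error(relative_drying_rate(-0.1, 1), "moisture")
})

test_that("spray drying conserves water and enthalpy to machine precision", {
  for (solver in c("bdf", "lsoda")) {
    res <- simulate_spraydry(dryer_config(), solver = solver)
    expect_lt(abs(res$closure$water), 1e-6)
    expect_lt(abs(res$closure$enthalpy), 1e-6)
  }
})

test_that("both solvers agree on the drying trajectory", {
  r1 <- simulate_spraydry(dryer_config(), solver = "bdf")
  r2 <- simulate_spraydry(dryer_config(), solver = "lsoda")
  expect_equal(r1$mean_final_moisture, r2$mean_final_moisture,
               tolerance = 5e-3)
})

test_that("droplets dry, heat up, and humidify/cool the gas", {
  res <- simulate_spraydry(dryer_config())
  n_end <- nrow(res$moisture)
  expect_true(all(res$moisture[n_end, ] < res$moisture[1, ]))
  # evaporation humidifies the gas above the inlet level; the humidity may
  # peak and relax back toward the inlet value once the droplets dry out,
  # but never drops below it
  expect_gt(max(res$outlet_humidity), res$outlet_humidity[1])
  expect_true(all(res$outlet_humidity >= dryer_config()$inlet_humidity - 1e-12))
  # evaporative load pulls the well-mixed gas below the inlet temperature
  expect_lt(res$gas_temperature[n_end], res$gas_temperature[1])
  # droplets heat up from the feed temperature but stay below the gas
  expect_gt(min(res$particle_temperature[n_end, ]), 298.15)
  expect_lt(max(res$particle_temperature[n_end, ]), max(res$gas_temperature))
})

test_that("smaller droplets dry further in the same residence time", {
  res <- simulate_spraydry(dryer_config())
  # droplet classes are ordered fine -> coarse within each solids class
  expect_true(all(diff(res$final_moisture) >= -1e-12))
})

test_that("a milled PSD is collapsed into the configured solids classes", {
  p <- psd_lognormal(default_grid(), 0.3e-6, 1.4)
  res <- simulate_spraydry(dryer_config(n_solids_bins = 3), psd = p)
  expect_equal(res$setup$n_i, 3)
  expect_equal(sum(res$setup$M_s), dryer_config()$feed_solids_kg / 3600 * 22.5,
               tolerance = 1e-12)
  expect_lt(abs(res$closure$enthalpy), 1e-6)
})

test_that("zero residence time returns the feed state unchanged", {
  res <- simulate_spraydry(dryer_config(residence_time_s = 0))
  expect_equal(nrow(res$moisture), 1)
  expect_equal(res$mean_final_moisture, 9 / 1.75, tolerance = 1e-12)
})

test_that("design space response is monotone in temperature and flow", {
  ds <- cached("design_space",
               design_space(dryer_config(), t_range = c(90, 110, 130),
                            flow_range = c(600, 800, 1000)))
  expect_s3_class(ds, "design_space")
  expect_equal(nrow(ds), 9)
  expect_false(any(ds$failed))
  m <- matrix(ds$final_moisture[order(ds$flow_Lh, ds$T_C)], 3, 3)
  # hotter air dries further at fixed flow
  for (j in 1:3) expect_true(all(diff(m[, j]) < 0))
  # more air per droplet (residence time held fixed) dries further
  for (i in 1:3) expect_true(all(diff(m[i, ]) < 0))
})
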