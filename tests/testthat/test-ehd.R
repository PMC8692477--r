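test_that("force scales reproduce hand-evaluated magnitudes", {
  fs <- force_scales(fluid_properties(), operating_conditions(15e3))
  # hand evaluations of eps0*phi^2, Do*gamma, rho*Q^2/Di^2, rho*Do^3*g
  expect_equal(fs$f_electric, 1.9922e-3, tolerance = 1e-3)
  expect_equal(fs$f_surface_tension, 8.890e-5, tolerance = 1e-3)
  expect_equal(fs$p_inertial, 1.582e-8, tolerance = 1e-3)
  expect_equal(fs$f_gravity, 2.009e-5, tolerance = 1e-3)
  expect_equal(unname(fs$ratios[["electric"]]),
               fs$f_electric / fs$f_surface_tension, tolerance = 1e-12)
})

test_that("force scales are homogeneous in their drivers", {
  set.seed(5)
  for (i in 1:5) {
    phi <- runif(1, 2e3, 20e3)
    q <- runif(1, 50, 500)
    geom <- device_geometry()
    base <- force_scales(op = operating_conditions(phi, flow_ul_min = q))
    phi2 <- force_scales(op = operating_conditions(2 * phi, flow_ul_min = q))
    q2 <- force_scales(op = operating_conditions(phi, flow_ul_min = 2 * q))
    expect_equal(phi2$f_electric, 4 * base$f_electric)   # ~ phi^2
    expect_equal(q2$p_inertial, 4 * base$p_inertial)     # ~ Q^2
    big <- device_geometry(needle_outer_diameter = 2 * geom$needle_outer_diameter,
                           domain_half_width = 60e-3)
    d2 <- force_scales(op = operating_conditions(phi, flow_ul_min = q,
                                                 geometry = big))
    expect_equal(d2$f_gravity, 8 * base$f_gravity)       # ~ Do^3
  }
})

test_that("both study operating points classify as micro-dripping", {
  m15 <- classify_mode(force_scales(op = operating_conditions(15e3)))
  m10 <- classify_mode(force_scales(op = operating_conditions(10e3)))
  expect_equal(m15$mode, "micro-dripping")
  expect_equal(m10$mode, "micro-dripping")
  expect_equal(m15$ratio, 22, tolerance = 0.05)
  expect_equal(m10$ratio, 10, tolerance = 0.05)
  expect_match(m15$rationale, "ratio")
})

test_that("mode classification is monotone in the applied potential", {
  ratios <- vapply(seq(1e3, 20e3, by = 1e3), function(v)
    classify_mode(force_scales(op = operating_conditions(v)))$ratio,
    numeric(1))
  expect_true(all(diff(ratios) > 0))
  low <- classify_mode(force_scales(op = operating_conditions(2e3)))
  expect_equal(low$mode, "dripping")  # ratio < 1 at 2 kV
  osc <- classify_mode(force_scales(op = operating_conditions(15e3)),
                       oscillating_threshold = 20)
  expect_equal(osc$mode, "oscillating micro-dripping")
})

test_that("droplet bounds scale with the nozzle and stay below it", {
  b <- droplet_diameter_bounds(device_geometry())
  expect_equal(b * 1e6, c(63.5, 1079.5))
  expect_true(all(c(200e-6, 300e-6) > b[1] & c(200e-6, 300e-6) < b[2]))
  b2 <- droplet_diameter_bounds(device_geometry(needle_outer_diameter = 1e-3))
  expect_equal(b2 * 1e6, c(50, 850))
  expect_lt(b2[2], 1e-3)
})

test_that("exposure metrics follow the flow geometry", {
  fm <- small_field()
  geom <- small_geometry()
  op <- operating_conditions(15e3, flow_ul_min = 200, geometry = geom)
  ex <- exposure_report(op, fm)
  bore_area <- pi * (geom$needle_inner_diameter / 2)^2
  expect_equal(ex$mean_exit_velocity, op$flow_rate / bore_area)
  expect_equal(ex$mean_exit_velocity, 6.04e-3, tolerance = 1e-3)
  expect_gte(ex$peak_field_on_path, ex$field_at_exit_center)
  # doubling the flow halves the residence time exactly
  ex2 <- exposure_report(operating_conditions(15e3, flow_ul_min = 400,
                                              geometry = geom), fm)
  expect_equal(ex2$needle_residence_time, ex$needle_residence_time / 2)
  # mismatched geometry or potential must refuse
  other <- operating_conditions(15e3, geometry = device_geometry())
  expect_error(exposure_report(other, fm), "different geometry")
  expect_error(exposure_report(operating_conditions(10e3, geometry = geom),
                               fm), "10000 V")
})

test_that("a uniform field exposes the cell to its exit-centre value only", {
  g <- parallel_plate_grid(20e-3, operating_potential(10e3), spacing = 1e-3,
                           half_width = 5e-3)
  fm <- compute_field(solve_poisson(g))
  op <- operating_conditions(10e3, geometry = small_geometry())
  ex <- exposure_report(op, fm)
  expect_equal(ex$peak_field_on_path, ex$field_at_exit_center,
               tolerance = 1e-9)
})
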