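test_that("lossless baseline equals the outlet pressure exactly", {
  sc <- pediatric_scenario()
  base <- solve_circulation(sc, NULL, loss_model(k_ivc = 0, k_svc = 0),
                            mode = "BASELINE")
  expect_equal(base$p_ivc, 10)
  expect_equal(base$p_svc, 10)
  expect_equal(base$q_p, 2.1)
  expect_equal(base$co, 2.1)
})

test_that("calibrated baseline reproduces the reference venous pressures", {
  base <- solve_circulation(pediatric_scenario(), NULL, calibrated_1do(),
                            mode = "BASELINE")
  expect_equal(base$p_ivc, 10.850, tolerance = 1e-6)
  expect_equal(base$p_svc, 10.868, tolerance = 1e-6)
})

test_that("baseline matches the closed-form two-resistor network", {
  sc <- pediatric_scenario()
  k <- 4.7
  lm <- loss_model(k_ivc = k, k_svc = k)
  base <- solve_circulation(sc, NULL, lm, "BASELINE")
  #  closed form: P = P_out + K * 1/2 rho v^2
  rho <- 1060
  a <- pi * 0.006^2
  v_ivc <- (1.26 / 60000) / a
  v_svc <- (0.84 / 60000) / a
  expect_equal(base$p_ivc, 10 + k * 0.5 * rho * v_ivc^2 / 133.322,
               tolerance = 1e-12)
  expect_equal(base$p_svc, 10 + k * 0.5 * rho * v_svc^2 / 133.322,
               tolerance = 1e-12)
})

test_that("mode constraints pin the shunt flows", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  geom <- selected_design()

  ff <- solve_circulation(sc, geom, lm, "FULL_FAILURE")
  expect_equal(ff$q_aog, 0)
  expect_equal(ff$q_ad, 0)
  expect_equal(ff$q_p, sc$q_caval_total)

  occ <- solve_circulation(sc, geom, lm, "AOG_OCCLUSION")
  expect_equal(occ$q_aog, 0)
  expect_equal(occ$q_p, sc$q_caval_total - occ$q_ad, tolerance = 1e-12)
  #  throat above atrial pressure drives a positive discharge flow
  expect_gt(occ$p_throat, sc$p_atrium)
  expect_gt(occ$q_ad, 0)
})

test_that("apply_mode describes the constraint set", {
  expect_false(apply_mode("BASELINE")$device_present)
  expect_true(apply_mode("FULL_ASSIST")$jet_active)
  expect_false(apply_mode("AOG_OCCLUSION")$jet_active)
  expect_true(apply_mode("AOG_OCCLUSION")$ad_active)
  expect_false(apply_mode("FULL_FAILURE")$ad_active)
  expect_error(apply_mode("HALF_ASSIST"))
})

test_that("solver is independent of initialization", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  geom <- selected_design()
  a <- solve_circulation(sc, geom, lm, "FULL_ASSIST", p_init = -20)
  b <- solve_circulation(sc, geom, lm, "FULL_ASSIST", p_init = 60)
  expect_lt(abs(a$p_throat - b$p_throat), 1e-6)
  expect_lt(abs(a$p_ivc - b$p_ivc), 1e-6)
})

test_that("fixed point matches an exhaustive throat-pressure grid search", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  geom <- selected_design()
  sol <- solve_circulation(sc, geom, lm, "FULL_ASSIST")

  #  oracle: scan throat pressures at 1e-4 mmHg resolution and take the
  #  self-consistency argmin of the three-node network (graft orifice,
  #  discharge orifice, momentum balance)
  grid <- seq(2, 10, by = 1e-4)
  resid <- vapply(grid, function(p) {
    q_aog <- orifice_flow(sc$p_aorta - p, geom$d_nozzle,
                          nozzle_cd(lm, geom$d_nozzle))
    q_ad <- orifice_flow(p - sc$p_atrium, geom$d_discharge,
                         lm$cd_discharge)
    abs(ejector_throat_pressure(q_aog, 1.26 - q_ad, geom,
                                sc$p_pa_outlet, lm) - p)
  }, numeric(1))
  p_grid <- grid[which.min(resid)]
  expect_lt(abs(sol$p_throat - p_grid), 1e-4)
})

test_that("mass is conserved in every mode", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  geom <- selected_design()
  for (mode in c("BASELINE", "FULL_ASSIST", "AOG_OCCLUSION",
                 "FULL_FAILURE")) {
    st <- solve_circulation(sc, if (mode == "BASELINE") NULL else geom,
                            lm, mode)
    expect_lt(st$mass_residual, 1e-9)
    expect_equal(st$q_p, st$q_ivc + st$q_svc + st$q_aog - st$q_ad,
                 tolerance = 1e-12)
    expect_equal(st$co, sc$q_caval_total + st$q_aog, tolerance = 1e-12)
  }
})

test_that("assist decompresses the IVC; changes are zero against itself", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  base <- solve_circulation(sc, NULL, lm, "BASELINE")
  fa <- solve_circulation(sc, selected_design(), lm, "FULL_ASSIST")

  d0 <- pressure_change_vs_baseline(base, base)
  expect_equal(d0$dp_ivc, 0)
  expect_equal(d0$dp_svc, 0)
  expect_equal(d0$dq_p_pct, 0)

  d <- pressure_change_vs_baseline(fa, base)
  expect_gt(d$dp_ivc, 0)
  expect_gt(d$dq_p_pct, 0)

  other <- solve_circulation(scenario(q_caval_total = 2.5), NULL, lm,
                             "BASELINE")
  expect_error(pressure_change_vs_baseline(fa, other), "different scenarios")
})

test_that("full failure elevates the IVC by at most the preservation tolerance", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  base <- solve_circulation(sc, NULL, lm, "BASELINE")
  for (dt in c(6, 8, 10, 12)) {
    ff <- solve_circulation(sc, device_geometry(2.5, dt, 4), lm,
                            "FULL_FAILURE")
    elev <- ff$p_ivc - base$p_ivc
    expect_gte(elev, 0)
    expect_lte(elev, 0.6)
    expect_lte(ff$p_svc, base$p_svc + 1e-9)
  }
})

test_that("assist IVC drop grows with nozzle size", {
  sc <- pediatric_scenario()
  lm <- calibrated_1do()
  base <- solve_circulation(sc, NULL, lm, "BASELINE")
  drops <- vapply(c(1.5, 2, 2.5, 3), function(dn) {
    fa <- solve_circulation(sc, device_geometry(dn, 8, 4), lm,
                            "FULL_ASSIST")
    base$p_ivc - fa$p_ivc
  }, numeric(1))
  expect_true(all(diff(drops) > 0))
})

test_that("invalid geometry is rejected by the solver", {
  expect_error(
    solve_circulation(pediatric_scenario(), device_geometry(2.5, 5, 4),
                      calibrated_1do(), "FULL_ASSIST"),
    "invalid device geometry")
})

test_that("state JSON export carries the solved fields", {
  st <- solve_circulation(pediatric_scenario(), selected_design(),
                          calibrated_1do(), "FULL_ASSIST")
  path <- withr::local_tempfile(fileext = ".json")
  write_state_json(st, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$mode, "FULL_ASSIST")
  expect_equal(x$p_ivc, st$p_ivc, tolerance = 1e-12)
  expect_equal(x$q_aog, st$q_aog, tolerance = 1e-12)
})
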