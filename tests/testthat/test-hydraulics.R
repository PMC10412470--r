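test_that("orifice flow matches the closed-form Bernoulli oracle", {
  expect_equal(orifice_flow(0, 2.5, 1), 0)
  #  ideal 2.5 mm orifice at the 55 mmHg reference head:
  #  v = sqrt(2*55*133.322/1060) = 3.7196 m/s over 4.9087e-6 m^2
  expect_equal(orifice_flow(55, 2.5, 1), 1.095, tolerance = 1e-3)
  expect_equal(orifice_flow(55, 2.5, 1), oracle_orifice(55, 2.5, 1),
               tolerance = 1e-12)
  expect_error(orifice_flow(10, -1, 0.9), "positive")
  expect_error(orifice_flow(10, 2, 1.2), "Cd")
})

test_that("orifice flow is antisymmetric, monotone, and scales as D^2", {
  dps <- c(0.3, 1, 5, 20, 55, 80)
  for (dp in dps) {
    expect_equal(orifice_flow(-dp, 3, 0.8), -orifice_flow(dp, 3, 0.8))
  }
  q <- vapply(dps, orifice_flow, numeric(1), d_mm = 3, cd = 0.8)
  expect_true(all(diff(q) > 0))
  q_d <- vapply(c(1, 2, 4, 8), orifice_flow, numeric(1),
                dP_mmHg = 20, cd = 0.8)
  expect_true(all(diff(q_d) > 0))
  expect_equal(orifice_flow(20, 6, 0.8) / orifice_flow(20, 3, 0.8), 4)
})

test_that("jet state reproduces hand-computed velocity and Reynolds number", {
  z <- jet_state(0, 2.5)
  expect_equal(z$v_jet, 0)
  expect_equal(z$re, 0)
  expect_equal(z$momentum_flux, 0)

  #  1 L/min through 2.5 mm: v = (1/60000)/4.9087e-6 = 3.395 m/s,
  #  Re = 1060*3.395*0.0025/0.0035 = 2571
  z1 <- jet_state(1, 2.5)
  expect_equal(z1$v_jet, 3.395, tolerance = 1e-3)
  expect_equal(z1$re, 2571, tolerance = 1e-3)
  expect_error(jet_state(1, 0), "positive")
})

test_that("calibrated 2.5 mm assist jet sits near the turbulent-jet Reynolds regime", {
  lm <- calibrated_1do()
  fa <- solve_circulation(pediatric_scenario(), selected_design(), lm,
                          "FULL_ASSIST")
  re <- jet_state(fa$q_aog, 2.5)$re
  expect_lt(abs(re - 2600) / 2600, 0.15)
})

test_that("pathway loss is quadratic with the right magnitude", {
  expect_equal(pathway_loss(0, 6.2, 12), 0)
  #  K=6.2, Q=1.26 L/min, D=12 mm: v = 0.1857 m/s, K*q = 113.3 Pa
  expect_equal(pathway_loss(1.26, 6.2, 12), 0.85, tolerance = 1e-2)
  expect_equal(pathway_loss(2.52, 6.2, 12) / pathway_loss(1.26, 6.2, 12), 4)
  expect_error(pathway_loss(1, -1, 12), ">= 0")
})

test_that("ejector closure reduces to pathway loss with the jet off", {
  geom <- device_geometry(2.5, 12, 4)
  lm <- loss_model(k_ivc = 6.2)
  p <- ejector_throat_pressure(0, 1.26, geom, p_downstream = 10,
                               losses = lm)
  expect_equal(p, 10 + pathway_loss(1.26, 6.2, 12), tolerance = 1e-12)
})

test_that("throat depression matches a brute-force 1D momentum balance", {
  #  independent oracle: constant-area momentum balance in raw SI
  #  arithmetic for Q_AoG = 0.9, Q_IVC = 1.26 L/min, D_N 2.5 / D_T 12 mm
  rho <- 1060
  qj <- 0.9 / 60000
  qs <- 1.26 / 60000
  qm <- qj + qs
  a_n <- pi * 0.00125^2
  a_t <- pi * 0.006^2
  rise_pa <- rho * (qj * qj / a_n + qs * qs / a_t - qm * qm / a_t) / a_t
  depression <- rise_pa / 133.322

  geom <- device_geometry(2.5, 12, 4)
  lm <- loss_model(eta_diffuser = 1, k_ivc = 0)
  p <- ejector_throat_pressure(0.9, 1.26, geom, p_downstream = 10,
                               losses = lm)
  expect_equal(10 - p, depression, tolerance = 1e-10)
  #  depression of order 3 mmHg on this instance
  expect_gt(10 - p, 2)
  expect_lt(10 - p, 4)
})

test_that("throat pressure is strictly decreasing in jet flow", {
  #  scanned over the jet-dominant regime (nozzle velocity above the mixed
  #  stream's); below it a momentum closure has a negligible (~0.01 mmHg)
  #  non-monotonic dip while the slow jet is being dragged by the stream
  geom <- device_geometry(2.5, 12, 4)
  lm <- loss_model(k_ivc = 6.2)
  p0 <- ejector_throat_pressure(0, 1.26, geom, 10, lm)
  p_dip <- vapply(seq(0, 0.1, by = 0.01), function(qj) {
    ejector_throat_pressure(qj, 1.26, geom, 10, lm)
  }, numeric(1))
  expect_lt(max(p_dip) - p0, 0.02)

  q <- seq(0.1, 2, by = 0.05)
  p <- vapply(q, function(qj) {
    ejector_throat_pressure(qj, 1.26, geom, 10, lm)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_true(all(is.finite(p)))
})

test_that("suction vanishes as the throat widens at fixed flows", {
  lm <- loss_model(k_ivc = 0)
  dep <- vapply(c(12, 24, 60, 2000), function(dt) {
    #  keep the outlet port at the throat size so the depression isolates
    #  the momentum-exchange term
    geom <- device_geometry(2.5, dt, 4, d_pa = dt)
    10 - ejector_throat_pressure(0.9, 1.26, geom, 10, lm)
  }, numeric(1))
  expect_true(all(diff(dep) < 0))
  expect_lt(dep[length(dep)], 1e-2)
})

test_that("nozzle Cd calibration inverts the printed flow anchors", {
  cd <- calibrate_nozzle_cd(c("1.5" = 0.315, "3" = 1.555))
  #  oracle: Cd = anchor / ideal Bernoulli flow at 55 mmHg
  expect_equal(unname(cd[["1.5"]]), 0.315 / oracle_orifice(55, 1.5, 1),
               tolerance = 1e-12)
  expect_equal(unname(cd[["3"]]), 1.555 / oracle_orifice(55, 3, 1),
               tolerance = 1e-12)
  expect_equal(unname(cd[["1.5"]]), 0.80, tolerance = 2e-2)
  expect_equal(unname(cd[["3"]]), 0.99, tolerance = 1e-2)
  rep <- attr(cd, "report")
  expect_true(all(abs(rep$residual_lmin) < 1e-12))
})

test_that("Cd calibration round-trips a known coefficient exactly", {
  d <- c(1.5, 2, 2.5, 3)
  synth <- vapply(d, oracle_orifice, numeric(1), dP_mmHg = 55, cd = 0.85)
  names(synth) <- d
  cd <- calibrate_nozzle_cd(synth)
  expect_equal(as.numeric(cd), rep(0.85, 4), tolerance = 1e-9)
})

test_that("Cd calibration rejects anchors demanding Cd > 1", {
  expect_error(calibrate_nozzle_cd(c("1.5" = 2)), "outside \\(0, 1\\]")
  expect_error(calibrate_nozzle_cd(c("1.5" = -0.1)), "positive")
  expect_error(calibrate_nozzle_cd(numeric(0)), "anchor")
})

test_that("Cd interpolation is linear in diameter and clamped", {
  lm <- loss_model(cd_nozzle = c("1.5" = 0.8, "3" = 0.95))
  expect_equal(nozzle_cd(lm, 2.25), 0.875)
  expect_equal(nozzle_cd(lm, 1.5), 0.8)
  expect_equal(nozzle_cd(lm, 1.0), 0.8)   # clamped below the anchor range
  expect_equal(nozzle_cd(lm, 4.0), 0.95)  # clamped above
})

test_that("pathway-loss calibration reproduces baseline fixtures", {
  sc <- pediatric_scenario()
  lm <- calibrate_pathway_losses(10.850, 10.868, sc)
  base <- solve_circulation(sc, NULL, lm, "BASELINE")
  expect_equal(base$p_ivc, 10.850, tolerance = 1e-3)
  expect_equal(base$p_svc, 10.868, tolerance = 1e-3)
  expect_true(lm$k_ivc > 0 && lm$k_svc > 0)

  flat <- calibrate_pathway_losses(10, 10, sc)
  expect_equal(flat$k_ivc, 0)
  expect_equal(flat$k_svc, 0)

  expect_error(calibrate_pathway_losses(9.5, 10.2, sc), "negative loss")
})

test_that("smoother junctions calibrate to smaller losses", {
  sc <- pediatric_scenario()
  fx <- load_fixtures()
  k_psc1 <- calibrated_loss_model("PSC1", sc, fx)
  k_0do <- calibrated_loss_model("0-DO", sc, fx)
  expect_lt(k_psc1$k_ivc, k_0do$k_ivc)
  expect_lt(k_psc1$k_svc, k_0do$k_svc)
})

test_that("loss-model YAML round-trips the calibration bit-for-bit", {
  lm <- calibrated_1do()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_loss_model_yaml(lm, path)
  back <- read_loss_model_yaml(path)
  expect_identical(as.numeric(back$cd_nozzle), as.numeric(lm$cd_nozzle))
  expect_identical(back$k_ivc, lm$k_ivc)
  expect_identical(back$k_svc, lm$k_svc)
  expect_identical(back$eta_diffuser, lm$eta_diffuser)
})

test_that("loss-model constructor enforces coefficient ranges", {
  expect_error(loss_model(cd_nozzle = c("2.5" = 1.2)), "\\(0, 1\\]")
  expect_error(loss_model(cd_discharge = 0), "\\(0, 1\\]")
  expect_error(loss_model(k_ivc = -1), ">= 0")
  expect_error(loss_model(eta_diffuser = 1.5), "\\[0, 1\\]")
})
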