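#' Blood properties
#'
#' Newtonian blood, density 1060 kg/m^3 and dynamic viscosity 0.0035 Pa.s.
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa.s.
#' @return object of class `vep_fluid`.
#' @export
fluid_properties <- function(rho = 1060, mu = 0.0035) {
  if (rho <= 0 || mu <= 0) stop("fluid properties must be positive",
                                call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "vep_fluid")
}

#' Loss model: the reduced-order model's free coefficients
#'
#' The 0D surrogate has four kinds of coefficients standing in for the 3D
#' dissipation the lumped model cannot resolve:
#' * `cd_nozzle`: discharge coefficient of the aortic nozzle per nozzle
#'   diameter (named numeric vector, values in (0,1]); calibrated to the
#'   published operating graft flows with [calibrate_nozzle_cd()].
#' * `cd_discharge`: discharge coefficient of the atrial-discharge orifice;
#'   default 0.61, the classical sharp-edged-orifice value.
#' * `k_ivc`, `k_svc`: lumped loss coefficients of the caval pathways
#'   through the junction (dimensionless, >= 0), calibrated to baseline
#'   venous pressures with [calibrate_pathway_losses()].
#' * `eta_diffuser`: pressure-recovery efficiency of the throat-to-outlet
#'   expansion, in [0,1] (default 0.8, classical conical-diffuser range).
#' * `k_svc_interaction`: optional SVC pressure rise per L/min of
#'   jet-boosted pulmonary flow (mmHg per L/min, default 0); the caval
#'   impingement effect seen in 3D is only approximated by this term.
#'
#' @param cd_nozzle named numeric vector, names are nozzle diameters in mm.
#' @param cd_discharge scalar in (0,1].
#' @param k_ivc,k_svc scalars >= 0.
#' @param eta_diffuser scalar in [0,1].
#' @param k_svc_interaction scalar >= 0, mmHg per L/min.
#' @return object of class `vep_loss_model`.
#' @export
loss_model <- function(cd_nozzle = c("2.5" = 0.92),
                       cd_discharge = 0.61,
                       k_ivc = 0, k_svc = 0,
                       eta_diffuser = 0.8,
                       k_svc_interaction = 0) {
  if (any(cd_nozzle <= 0) || any(cd_nozzle > 1)) {
    stop("cd_nozzle values must lie in (0, 1]", call. = FALSE)
  }
  if (cd_discharge <= 0 || cd_discharge > 1) {
    stop("cd_discharge must lie in (0, 1]", call. = FALSE)
  }
  if (k_ivc < 0 || k_svc < 0 || k_svc_interaction < 0) {
    stop("loss coefficients must be >= 0", call. = FALSE)
  }
  if (eta_diffuser < 0 || eta_diffuser > 1) {
    stop("eta_diffuser must lie in [0, 1]", call. = FALSE)
  }
  structure(list(cd_nozzle = cd_nozzle, cd_discharge = cd_discharge,
                 k_ivc = k_ivc, k_svc = k_svc,
                 eta_diffuser = eta_diffuser,
                 k_svc_interaction = k_svc_interaction),
            class = "vep_loss_model")
}

#' @export
print.vep_loss_model <- function(x, ...) {
  cat("<vep_loss_model>\n")
  cat("  Cd nozzle:", paste(sprintf("%s mm=%.4f", names(x$cd_nozzle),
                                    x$cd_nozzle), collapse = ", "), "\n")
  cat(sprintf("  Cd discharge: %.3f | K_ivc %.4g | K_svc %.4g | eta %.2f\n",
              x$cd_discharge, x$k_ivc, x$k_svc, x$eta_diffuser))
  invisible(x)
}

#' Nozzle discharge coefficient for a given diameter
#'
#' Anchored diameters return their calibrated value; others are linearly
#' interpolated in diameter between anchors, clamped to the anchor range.
#'
#' @param losses a [loss_model()].
#' @param d_mm nozzle diameter, mm.
#' @return discharge coefficient in (0,1].
#' @export
nozzle_cd <- function(losses, d_mm) {
  cd <- losses$cd_nozzle
  dn <- as.numeric(names(cd))
  if (length(cd) == 1L) return(unname(cd))
  o <- order(dn)
  stats::approx(dn[o], cd[o], xout = d_mm, rule = 2)$y
}

#' Signed orifice flow
#'
#' Bernoulli orifice law with discharge coefficient:
#' `Q = sign(dP) * Cd * A * sqrt(2 |dP| / rho)`, antisymmetric in the
#' driving pressure.
#'
#' @param dP_mmHg driving pressure difference, mmHg (signed).
#' @param d_mm orifice diameter, mm.
#' @param cd discharge coefficient in (0,1].
#' @param fluid a [fluid_properties()].
#' @return flow in L/min (signed; positive in the direction of positive dP).
#' @examples
#' orifice_flow(55, 2.5, 1)  # ~1.095 L/min, the ideal 2.5 mm nozzle at
#'                           # the 65-10 mmHg reference head
#' @export
orifice_flow <- function(dP_mmHg, d_mm, cd, fluid = fluid_properties()) {
  if (d_mm <= 0) stop("orifice diameter must be positive", call. = FALSE)
  if (cd <= 0 || cd > 1) stop("Cd must lie in (0, 1]", call. = FALSE)
  v <- sqrt(2 * abs(mmHg_to_Pa(dP_mmHg)) / fluid$rho)
  m3s_to_lmin(sign(dP_mmHg) * cd * port_area(d_mm) * v)
}

#' Jet state at the nozzle exit
#'
#' @param q_aog graft flow, L/min (>= 0).
#' @param d_nozzle nozzle diameter, mm.
#' @param fluid a [fluid_properties()].
#' @return list with `v_jet` (m/s), `re` (nozzle Reynolds number) and
#'   `momentum_flux` (N, `rho * Q * v`).
#' @export
jet_state <- function(q_aog, d_nozzle, fluid = fluid_properties()) {
  if (d_nozzle <= 0) stop("nozzle diameter must be positive", call. = FALSE)
  if (q_aog < 0) stop("graft flow must be >= 0", call. = FALSE)
  q <- lmin_to_m3s(q_aog)
  v <- q / port_area(d_nozzle)
  list(q_aog = q_aog,
       v_jet = v,
       re = fluid$rho * v * (d_nozzle / 1000) / fluid$mu,
       momentum_flux = fluid$rho * q * v)
}

#' Quadratic pathway loss
#'
#' `dP = K * 1/2 rho v^2` with `v = Q / A(D)`: the lumped resistance of a
#' caval pathway through the junction, quadratic in flow.
#'
#' @param q flow, L/min.
#' @param k dimensionless loss coefficient, >= 0.
#' @param d_mm reference diameter for the velocity scale, mm.
#' @param fluid a [fluid_properties()].
#' @return pressure loss, mmHg (>= 0).
#' @export
pathway_loss <- function(q, k, d_mm, fluid = fluid_properties()) {
  if (k < 0) stop("loss coefficient must be >= 0", call. = FALSE)
  v <- lmin_to_m3s(abs(q)) / port_area(d_mm)
  Pa_to_mmHg(k * 0.5 * fluid$rho * v^2)
}

#  One-dimensional ejector closure at the mixing throat.
#
#  Stations: the jet leaves the nozzle at throat static pressure with
#  velocity Q_j/A_N; the venous secondary stream is taken at the full
#  throat area (so the closure reduces exactly to a plain conduit when the
#  jet is off); a single constant-area momentum balance over the throat
#  gives the pressure recovered by momentum exchange; the mixed stream then
#  expands (or contracts) to the pulmonary outlet port with recovery
#  efficiency eta_diffuser on the expansion.
#
#  Returns the individual pressure terms in mmHg for reuse by the solver.
ejector_terms <- function(q_aog, q_sec, geom, losses, fluid) {
  a_n <- port_area(geom$d_nozzle)
  a_t <- port_area(geom$d_throat)
  a_e <- port_area(geom$d_pa)
  qj <- lmin_to_m3s(q_aog)
  qs <- lmin_to_m3s(q_sec)
  qm <- qj + qs
  v_j <- qj / a_n
  v_s <- qs / a_t
  v_m <- qm / a_t
  v_e <- qm / a_e
  #  momentum-exchange pressure rise across the mixing section
  suction <- Pa_to_mmHg(fluid$rho * (qj * v_j + qs * v_s - qm * v_m) / a_t)
  #  diffuser recovery (throat -> outlet); ideal Bernoulli if contracting
  if (v_m >= v_e) {
    diffuser <- Pa_to_mmHg(losses$eta_diffuser * 0.5 * fluid$rho *
                             (v_m^2 - v_e^2))
  } else {
    diffuser <- Pa_to_mmHg(0.5 * fluid$rho * (v_m^2 - v_e^2))
  }
  list(suction = suction, diffuser = diffuser, v_s = v_s, v_m = v_m,
       v_e = v_e)
}

#' Throat static pressure of the ejector
#'
#' One-dimensional constant-area momentum balance over the mixing throat
#' followed by diffuser recovery to the pulmonary outlet port, plus the
#' calibrated IVC pathway loss. The high-velocity aortic jet deposits
#' momentum into the venous stream; the resulting pressure rise through the
#' mixing section depresses the throat static pressure below the
#' downstream value (Venturi suction). With the jet off the closure reduces
#' exactly to `P_downstream + pathway loss` (no suction term).
#'
#' @param q_aog aortic graft (jet) flow, L/min, >= 0.
#' @param q_ivc venous secondary flow carried through the throat, L/min.
#' @param geom a validated [device_geometry()].
#' @param p_downstream pulmonary outlet pressure, mmHg.
#' @param losses a [loss_model()].
#' @param fluid a [fluid_properties()].
#' @return throat static pressure, mmHg.
#' @export
ejector_throat_pressure <- function(q_aog, q_ivc, geom,
                                    p_downstream = 10,
                                    losses = loss_model(),
                                    fluid = fluid_properties()) {
  val <- validate_device(geom)
  if (!val$ok) {
    stop("invalid device geometry: ",
         paste(val$violations, collapse = "; "), call. = FALSE)
  }
  if (q_aog < 0) stop("jet flow must be >= 0", call. = FALSE)
  et <- ejector_terms(q_aog, q_ivc, geom, losses, fluid)
  p_downstream - et$diffuser - et$suction +
    pathway_loss(q_ivc, losses$k_ivc, geom$d_ivc, fluid)
}

#' Calibrate nozzle discharge coefficients to published operating flows
#'
#' For each anchored nozzle diameter, solves
#' `orifice_flow(dP, D, Cd) = anchored flow` for `Cd` at the reference
#' driving head (aortic minus reference downstream pressure). Unanchored
#' diameters are later interpolated linearly in diameter by [nozzle_cd()],
#' clamped to the anchor range.
#'
#' @param anchors named numeric vector: names are nozzle diameters (mm),
#'   values the anchored graft flows (L/min).
#' @param p_aorta aortic pressure, mmHg.
#' @param p_reference reference downstream pressure, mmHg.
#' @param fluid a [fluid_properties()].
#' @return named numeric vector of discharge coefficients (same names),
#'   with attribute `report`: data.frame of anchor, target flow, fitted Cd
#'   and residual.
#' @examples
#' calibrate_nozzle_cd(c("1.5" = 0.315, "3" = 1.555))
#' @export
calibrate_nozzle_cd <- function(anchors, p_aorta = 65, p_reference = 10,
                                fluid = fluid_properties()) {
  if (length(anchors) == 0) stop("no anchors supplied", call. = FALSE)
  if (any(anchors <= 0)) stop("anchored flows must be positive",
                              call. = FALSE)
  dP <- p_aorta - p_reference
  if (dP <= 0) stop("aortic pressure must exceed the reference downstream pressure",
                    call. = FALSE)
  d_mm <- as.numeric(names(anchors))
  ideal <- vapply(d_mm, function(d) orifice_flow(dP, d, 1, fluid),
                  numeric(1))
  cd <- as.numeric(anchors) / ideal
  bad <- cd <= 0 | cd > 1
  if (any(bad)) {
    stop(sprintf(
      "calibration error: anchor %s mm requires Cd = %.3f outside (0, 1]",
      names(anchors)[bad][1], cd[bad][1]), call. = FALSE)
  }
  residual <- vapply(seq_along(cd), function(i) {
    orifice_flow(dP, d_mm[i], cd[i], fluid) - anchors[i]
  }, numeric(1))
  out <- stats::setNames(cd, names(anchors))
  attr(out, "report") <- data.frame(
    d_nozzle = d_mm, target_lmin = as.numeric(anchors), cd = cd,
    residual_lmin = as.numeric(residual))
  out
}

#' Calibrate caval pathway losses to baseline venous pressures
#'
#' Chooses `k_ivc`/`k_svc` so that the no-device baseline circulation
#' reproduces the fixture IVC and SVC pressures. The baseline venous
#' pressure is `P_outlet + K * 1/2 rho v^2`, so each K follows in closed
#' form; the result is verified by re-solving the baseline.
#'
#' @param p_ivc,p_svc fixture baseline pressures, mmHg.
#' @param scenario a [pediatric_scenario()]-style scenario giving caval
#'   flows and the outlet pressure.
#' @param losses starting [loss_model()] whose `k_ivc`/`k_svc` are replaced.
#' @param d_ivc,d_svc pathway reference diameters, mm.
#' @param tol verification tolerance, mmHg.
#' @return the input `losses` with calibrated `k_ivc`, `k_svc`.
#' @export
calibrate_pathway_losses <- function(p_ivc, p_svc, scenario,
                                     losses = loss_model(),
                                     d_ivc = 12, d_svc = 12,
                                     tol = 1e-3) {
  p_out <- scenario$p_pa_outlet
  if (p_ivc < p_out || p_svc < p_out) {
    stop("fixture pressure below outlet pressure: negative loss impossible",
         call. = FALSE)
  }
  q_ivc <- scenario$q_caval_total * scenario$ivc_fraction
  q_svc <- scenario$q_caval_total * (1 - scenario$ivc_fraction)
  unit_ivc <- pathway_loss(q_ivc, 1, d_ivc, scenario$fluid)
  unit_svc <- pathway_loss(q_svc, 1, d_svc, scenario$fluid)
  losses$k_ivc <- (p_ivc - p_out) / unit_ivc
  losses$k_svc <- (p_svc - p_out) / unit_svc
  chk <- solve_circulation(scenario, geom = NULL, losses = losses,
                           mode = "BASELINE")
  if (abs(chk$p_ivc - p_ivc) > tol || abs(chk$p_svc - p_svc) > tol) {
    stop("pathway-loss calibration failed verification", call. = FALSE)
  }
  losses
}

#' Serialize / restore a loss model as YAML
#'
#' Calibrations are reproducible artifacts: the fitted coefficients can be
#' written to YAML and reloaded bit-for-bit.
#'
#' @param losses a [loss_model()].
#' @param path file path.
#' @export
write_loss_model_yaml <- function(losses, path) {
  stopifnot(inherits(losses, "vep_loss_model"))
  x <- unclass(losses)
  x$cd_nozzle <- as.list(x$cd_nozzle)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_loss_model_yaml
#' @export
read_loss_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  loss_model(cd_nozzle = unlist(x$cd_nozzle),
             cd_discharge = x$cd_discharge,
             k_ivc = x$k_ivc, k_svc = x$k_svc,
             eta_diffuser = x$eta_diffuser,
             k_svc_interaction = x$k_svc_interaction)
}

#' Calibrated loss model for a TCPC fixture
#'
#' Convenience wrapper chaining [calibrate_nozzle_cd()] on the packaged
#' graft-flow anchors and [calibrate_pathway_losses()] on the packaged
#' baseline pressures for one junction model.
#'
#' @param tcpc_label fixture row to calibrate against.
#' @param scenario boundary conditions; defaults to [pediatric_scenario()].
#' @param fixtures a [load_fixtures()] set.
#' @param ... further arguments to [loss_model()].
#' @return calibrated [loss_model()].
#' @export
calibrated_loss_model <- function(tcpc_label = "1-DO",
                                  scenario = pediatric_scenario(),
                                  fixtures = load_fixtures(), ...) {
  losses <- loss_model(...)
  losses$cd_nozzle <- calibrate_nozzle_cd(
    fixtures$nozzle_flow_anchors,
    p_aorta = scenario$p_aorta,
    p_reference = scenario$p_pa_outlet,
    fluid = scenario$fluid)
  row <- fixtures$table1[fixtures$table1$label == tcpc_label, ]
  if (nrow(row) != 1L) stop("unknown TCPC label: ", tcpc_label, call. = FALSE)
  calibrate_pathway_losses(row$p_ivc, row$p_svc, scenario, losses)
}
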