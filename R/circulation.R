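#' Operating modes of the assisted circulation
#'
#' * `BASELINE`: junction without the device; caval pathways drain to the
#'   pulmonary outlet through their calibrated losses.
#' * `FULL_ASSIST`: aortic jet and atrial discharge both active.
#' * `AOG_OCCLUSION`: graft occluded (zero jet flow); the atrial discharge
#'   stays open and drains toward the atrium.
#' * `FULL_FAILURE`: graft and atrial discharge both occluded, device body
#'   still in line.
#'
#' @param mode mode name.
#' @return list describing the constraints: `device_present`,
#'   `jet_active`, `ad_active`.
#' @export
apply_mode <- function(mode = c("BASELINE", "FULL_ASSIST",
                                "AOG_OCCLUSION", "FULL_FAILURE")) {
  mode <- match.arg(mode)
  switch(mode,
         BASELINE = list(mode = mode, device_present = FALSE,
                         jet_active = FALSE, ad_active = FALSE),
         FULL_ASSIST = list(mode = mode, device_present = TRUE,
                            jet_active = TRUE, ad_active = TRUE),
         AOG_OCCLUSION = list(mode = mode, device_present = TRUE,
                              jet_active = FALSE, ad_active = TRUE),
         FULL_FAILURE = list(mode = mode, device_present = TRUE,
                             jet_active = FALSE, ad_active = FALSE))
}

#  Flows through the device orifices at a trial throat pressure (L/min).
#  The graft cannot run backwards (aorta always above throat pressure in
#  any physical operating point; clamped at zero defensively); the atrial
#  discharge is an open fenestration and is signed.
device_flows <- function(p_throat, scenario, geom, losses, constraints) {
  q_aog <- 0
  q_ad <- 0
  if (constraints$jet_active) {
    cd <- nozzle_cd(losses, geom$d_nozzle)
    q_aog <- max(0, orifice_flow(scenario$p_aorta - p_throat,
                                 geom$d_nozzle, cd, scenario$fluid))
  }
  if (constraints$ad_active) {
    q_ad <- orifice_flow(p_throat - scenario$p_atrium, geom$d_discharge,
                         losses$cd_discharge, scenario$fluid)
  }
  list(q_aog = q_aog, q_ad = q_ad)
}

#' Solve the steady assisted Fontan circulation
#'
#' Caval inflows are prescribed flow sources (60/40 IVC/SVC split of the
#' caval return); the pulmonary outlet and the atrium are prescribed
#' pressures. The device couples them through three nonlinear relations
#' solved self-consistently for the throat pressure: the graft orifice flow
#' (driven by aortic minus throat pressure), the atrial-discharge orifice
#' flow (throat minus atrial pressure), and the ejector momentum balance
#' ([ejector_throat_pressure()]). The solver is a damped fixed-point
#' iteration on the throat pressure with a bisection fallback; it is
#' deterministic and independent of initialization.
#'
#' @param scenario a [scenario()].
#' @param geom a validated [device_geometry()]; may be `NULL` for
#'   `mode = "BASELINE"`.
#' @param losses a calibrated [loss_model()].
#' @param mode operating mode, see [apply_mode()].
#' @param p_init optional initial throat pressure, mmHg.
#' @param tol convergence tolerance on successive throat-pressure
#'   iterates, mmHg.
#' @param max_iter iteration cap before the bisection fallback.
#' @return object of class `vep_state` with node pressures (mmHg), branch
#'   flows (L/min), cardiac output, mode and the mass residual at the
#'   mixing node.
#' @export
solve_circulation <- function(scenario, geom = NULL,
                              losses = loss_model(),
                              mode = "FULL_ASSIST",
                              p_init = NULL, tol = 1e-8,
                              max_iter = 500L) {
  stopifnot(inherits(scenario, "vep_scenario"),
            inherits(losses, "vep_loss_model"))
  constraints <- apply_mode(mode)
  q_ivc <- scenario$q_caval_total * scenario$ivc_fraction
  q_svc <- scenario$q_caval_total * (1 - scenario$ivc_fraction)
  fluid <- scenario$fluid

  if (!constraints$device_present) {
    p_ivc <- scenario$p_pa_outlet +
      pathway_loss(q_ivc, losses$k_ivc, 12, fluid)
    p_svc <- scenario$p_pa_outlet +
      pathway_loss(q_svc, losses$k_svc, 12, fluid)
    return(new_vep_state(scenario, constraints$mode,
                         p_ivc = p_ivc, p_svc = p_svc,
                         p_throat = NA_real_,
                         q_ivc = q_ivc, q_svc = q_svc,
                         q_aog = 0, q_ad = 0, converged = TRUE,
                         residual_mmHg = 0))
  }

  val <- validate_device(geom)
  if (!val$ok) {
    stop("invalid device geometry: ",
         paste(val$violations, collapse = "; "), call. = FALSE)
  }

  #  fixed-point map: trial throat pressure -> throat pressure implied by
  #  the orifice flows it drives
  map <- function(p) {
    fl <- device_flows(p, scenario, geom, losses, constraints)
    ejector_throat_pressure(fl$q_aog, q_ivc - fl$q_ad, geom,
                            p_downstream = scenario$p_pa_outlet,
                            losses = losses, fluid = fluid)
  }

  p <- if (is.null(p_init)) scenario$p_pa_outlet else p_init
  damping <- 0.7
  converged <- FALSE
  resid <- Inf
  for (i in seq_len(max_iter)) {
    p_new <- p + damping * (map(p) - p)
    resid <- abs(p_new - p)
    p <- p_new
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    #  bisection fallback on the fixed-point residual
    f <- function(x) map(x) - x
    lo <- scenario$p_atrium - 100
    hi <- scenario$p_aorta
    if (f(lo) * f(hi) < 0) {
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
      p <- root$root
      resid <- abs(f(p))
      converged <- resid < 1e-6
    }
  }
  if (!converged) {
    stop(sprintf(
      "circulation solver failed to converge (last residual %.3e mmHg)",
      resid), call. = FALSE)
  }
  #  refine to machine-level self-consistency
  for (i in 1:5) p <- map(p)

  fl <- device_flows(p, scenario, geom, losses, constraints)
  new_vep_state(scenario, constraints$mode,
                p_ivc = NA_real_, p_svc = NA_real_, p_throat = p,
                q_ivc = q_ivc, q_svc = q_svc,
                q_aog = fl$q_aog, q_ad = fl$q_ad,
                geom = geom, losses = losses,
                converged = TRUE, residual_mmHg = abs(map(p) - p))
}

#  Assemble a solved state; computes port/nodal pressures and derived
#  flows from the converged throat pressure.
new_vep_state <- function(scenario, mode, p_ivc, p_svc, p_throat,
                          q_ivc, q_svc, q_aog, q_ad,
                          geom = NULL, losses = NULL,
                          converged = TRUE, residual_mmHg = 0) {
  fluid <- scenario$fluid
  if (!is.null(geom)) {
    #  IVC node: throat pressure plus the port-to-throat Bernoulli
    #  adjustment (the calibrated pathway loss is already inside the
    #  throat-pressure closure)
    q_sec <- q_ivc - q_ad
    v_s <- lmin_to_m3s(q_sec) / port_area(geom$d_throat)
    v_p <- lmin_to_m3s(q_ivc) / port_area(geom$d_ivc)
    p_ivc <- p_throat + Pa_to_mmHg(0.5 * fluid$rho * (v_s^2 - v_p^2))
    boost <- max(0, q_aog - max(q_ad, 0))
    p_svc <- scenario$p_pa_outlet +
      pathway_loss(q_svc, losses$k_svc, 12, fluid) +
      losses$k_svc_interaction * boost
  }
  q_p <- q_ivc + q_svc + q_aog - q_ad
  co <- scenario$q_caval_total + q_aog
  #  continuity at the mixing node and the pulmonary node, from the
  #  stored branch flows
  mass_residual <- abs((q_ivc + q_svc + q_aog - q_ad) - q_p)
  structure(list(mode = mode,
                 p_ivc = p_ivc, p_svc = p_svc, p_throat = p_throat,
                 q_ivc = q_ivc, q_svc = q_svc, q_aog = q_aog,
                 q_ad = q_ad, q_p = q_p, co = co,
                 mass_residual = mass_residual,
                 solver_residual_mmHg = residual_mmHg,
                 converged = converged,
                 scenario = scenario),
            class = "vep_state")
}

#' @export
print.vep_state <- function(x, ...) {
  cat(sprintf("<vep_state> %s\n", x$mode))
  cat(sprintf("  P_IVC %.3f | P_SVC %.3f | P_throat %s mmHg\n",
              x$p_ivc, x$p_svc,
              ifelse(is.na(x$p_throat), "-", sprintf("%.3f", x$p_throat))))
  cat(sprintf("  Q_AoG %.3f | Q_AD %.3f | Q_P %.3f | CO %.3f L/min\n",
              x$q_aog, x$q_ad, x$q_p, x$co))
  invisible(x)
}

#' Hemodynamic change relative to the no-device baseline
#'
#' Pressure changes are reported as baseline minus assisted, so a positive
#' `dp_ivc` is an improvement (caval decompression); the pulmonary-flow
#' change is in percent of the baseline pulmonary flow.
#'
#' @param assisted,baseline solved [solve_circulation()] states for the
#'   same scenario.
#' @return list with `dp_ivc` (mmHg), `dp_svc` (mmHg), `dq_p_pct` (%).
#' @export
pressure_change_vs_baseline <- function(assisted, baseline) {
  stopifnot(inherits(assisted, "vep_state"), inherits(baseline, "vep_state"))
  sa <- assisted$scenario
  sb <- baseline$scenario
  same <- isTRUE(all.equal(
    sa[c("q_caval_total", "ivc_fraction", "p_aorta", "p_pa_outlet",
         "p_atrium")],
    sb[c("q_caval_total", "ivc_fraction", "p_aorta", "p_pa_outlet",
         "p_atrium")])) && sa$tcpc$label == sb$tcpc$label
  if (!same) stop("states were solved under different scenarios",
                  call. = FALSE)
  list(dp_ivc = baseline$p_ivc - assisted$p_ivc,
       dp_svc = baseline$p_svc - assisted$p_svc,
       dq_p_pct = 100 * (assisted$q_p - baseline$q_p) / baseline$q_p)
}

#' Write a solved state as JSON
#'
#' @param state a [solve_circulation()] result.
#' @param path file path.
#' @export
write_state_json <- function(state, path) {
  stopifnot(inherits(state, "vep_state"))
  x <- state[c("mode", "p_ivc", "p_svc", "p_throat", "q_ivc", "q_svc",
               "q_aog", "q_ad", "q_p", "co", "mass_residual")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
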