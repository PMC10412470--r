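#' Boundary-condition scenario for one circulation solve
#'
#' @param q_caval_total total systemic venous (caval) return, L/min.
#' @param ivc_fraction IVC share of the caval return (0,1).
#' @param p_aorta mean aortic pressure, mmHg (static head driving the
#'   graft).
#' @param p_pa_outlet pulmonary outlet pressure, mmHg (both lungs, lumped).
#' @param p_atrium atrial pressure, mmHg (atrial-discharge sink).
#' @param fluid a [fluid_properties()].
#' @param tcpc a [tcpc_geometry()].
#' @param innominate_split innominate-vein flow fraction per side
#'   (patient-specific bookkeeping only).
#' @return object of class `vep_scenario`.
#' @export
scenario <- function(q_caval_total = 2.1, ivc_fraction = 0.6,
                     p_aorta = 65, p_pa_outlet = 10, p_atrium = 5,
                     fluid = fluid_properties(),
                     tcpc = tcpc_geometry("1-DO"),
                     innominate_split = 0.2) {
  if (ivc_fraction <= 0 || ivc_fraction >= 1) {
    stop("ivc_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!(p_aorta > p_pa_outlet && p_pa_outlet > 0)) {
    stop("need p_aorta > p_pa_outlet > 0", call. = FALSE)
  }
  if (q_caval_total <= 0) stop("caval return must be positive", call. = FALSE)
  structure(list(q_caval_total = q_caval_total,
                 ivc_fraction = ivc_fraction,
                 p_aorta = p_aorta, p_pa_outlet = p_pa_outlet,
                 p_atrium = p_atrium, fluid = fluid, tcpc = tcpc,
                 innominate_split = innominate_split),
            class = "vep_scenario")
}

#' @export
print.vep_scenario <- function(x, ...) {
  cat(sprintf(
    "<vep_scenario> Q_caval %.3g L/min (IVC %.0f%%) | Pao %.3g, Ppa %.3g, Pat %.3g mmHg | TCPC %s\n",
    x$q_caval_total, 100 * x$ivc_fraction, x$p_aorta, x$p_pa_outlet,
    x$p_atrium, x$tcpc$label))
  invisible(x)
}

#' Postoperative pediatric Fontan boundary conditions
#'
#' The reference operating point: 2.1 L/min total caval return with a 60/40
#' IVC/SVC split, 65 mmHg mean aortic pressure at the graft inlet, 10 mmHg
#' pulmonary outlet pressure (a hypertensive venous condition) and 5 mmHg
#' atrial pressure; blood at 1060 kg/m^3 and 0.0035 Pa.s.
#'
#' @param tcpc a [tcpc_geometry()] (default the one-diameter-offset
#'   idealized junction used for design selection).
#' @return a [scenario()].
#' @export
pediatric_scenario <- function(tcpc = tcpc_geometry("1-DO")) {
  scenario(q_caval_total = 2.1, ivc_fraction = 0.6, p_aorta = 65,
           p_pa_outlet = 10, p_atrium = 5, fluid = fluid_properties(),
           tcpc = tcpc)
}

#' Randomized boundary-condition scenarios
#'
#' Perturbs each continuous field of the pediatric scenario independently
#' and uniformly within +/- `spread` (fractional), for robustness/property
#' testing. Uniform perturbation keeps bounded support, so scenario
#' invariants hold by construction at the default spread; scenarios
#' violating them are nonetheless resampled. Deterministic for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param n number of scenarios (>= 1).
#' @param seed integer seed.
#' @param spread fractional half-width of the uniform perturbation
#'   (default 0.15).
#' @param tcpc junction passed to each scenario.
#' @return list of [scenario()] objects.
#' @export
randomized_scenarios <- function(n, seed = 1, spread = 0.15,
                                 tcpc = tcpc_geometry("1-DO")) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  base <- pediatric_scenario(tcpc)
  fields <- c("q_caval_total", "ivc_fraction", "p_aorta", "p_pa_outlet",
              "p_atrium")
  one <- function() {
    for (attempt in 1:100) {
      vals <- lapply(fields, function(f) {
        base[[f]] * stats::runif(1, 1 - spread, 1 + spread)
      })
      names(vals) <- fields
      fl <- fluid_properties(
        rho = base$fluid$rho * stats::runif(1, 1 - spread, 1 + spread),
        mu = base$fluid$mu * stats::runif(1, 1 - spread, 1 + spread))
      ok <- vals$ivc_fraction > 0 && vals$ivc_fraction < 1 &&
        vals$p_aorta > vals$p_pa_outlet && vals$p_pa_outlet > 0 &&
        vals$q_caval_total > 0
      if (ok) {
        return(scenario(q_caval_total = vals$q_caval_total,
                        ivc_fraction = vals$ivc_fraction,
                        p_aorta = vals$p_aorta,
                        p_pa_outlet = vals$p_pa_outlet,
                        p_atrium = vals$p_atrium,
                        fluid = fl, tcpc = tcpc))
      }
    }
    stop("could not generate a valid scenario in 100 attempts",
         call. = FALSE)
  }
  lapply(seq_len(n), function(i) one())
}

#' Published calibration fixtures
#'
#' Returns the packaged reference values used to pin the model's free
#' coefficients: the baseline (no device) IVC/SVC pressures for the five
#' junction models (`0-DO`, `0.5-DO`, `1-DO`, `PSC1`, `PSC2`) and the
#' operating graft-flow anchors for the 1.5 and 3.0 mm nozzles.
#'
#' @return list with `table1` (data.frame: `label`, `p_ivc`, `p_svc` in
#'   mmHg) and `nozzle_flow_anchors` (named numeric, L/min by nozzle
#'   diameter in mm).
#' @export
load_fixtures <- function() {
  path <- system.file("extdata", "baseline_pressures.csv",
                      package = "vepsim", mustWork = TRUE)
  table1 <- utils::read.csv(path, stringsAsFactors = FALSE)
  apath <- system.file("extdata", "nozzle_flow_anchors.csv",
                       package = "vepsim", mustWork = TRUE)
  a <- utils::read.csv(apath, stringsAsFactors = FALSE)
  anchors <- stats::setNames(a$q_aog_lmin, a$d_nozzle_mm)
  list(table1 = table1, nozzle_flow_anchors = anchors)
}

#' Serialize / restore a scenario as YAML
#'
#' @param scen a [scenario()].
#' @param path file path.
#' @export
write_scenario_yaml <- function(scen, path) {
  stopifnot(inherits(scen, "vep_scenario"))
  x <- list(q_caval_total = scen$q_caval_total,
            ivc_fraction = scen$ivc_fraction,
            p_aorta = scen$p_aorta, p_pa_outlet = scen$p_pa_outlet,
            p_atrium = scen$p_atrium,
            rho = scen$fluid$rho, mu = scen$fluid$mu,
            tcpc_label = scen$tcpc$label,
            innominate_split = scen$innominate_split)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario(q_caval_total = x$q_caval_total, ivc_fraction = x$ivc_fraction,
           p_aorta = x$p_aorta, p_pa_outlet = x$p_pa_outlet,
           p_atrium = x$p_atrium,
           fluid = fluid_properties(rho = x$rho, mu = x$mu),
           tcpc = tcpc_geometry(x$tcpc_label),
           innominate_split = x$innominate_split)
}
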