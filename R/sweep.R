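#' Design selection criteria configuration
#'
#' The four selection criteria, with thresholds exposed rather than
#' hard-coded (the published criteria are 80% saturation floors even
#' though reported outcomes run 84-90%):
#' 1. aortic graft flow criterion `Q_AoG/Q_S < qp_qs_limit - 1`
#'    (equivalently `Q_P/Q_S < qp_qs_limit`) during full assist;
#' 2. systemic arterial saturation at least `min_sat_assist_pct` during
#'    full assist;
#' 3. saturation at least `min_sat_occlusion_pct` during graft occlusion;
#' 4. full device failure preserves the pre-device baseline: IVC pressure
#'    within `baseline_preservation_tol_mmHg` of baseline and no SVC
#'    elevation.
#'
#' @param qp_qs_limit pulmonary-to-systemic flow ratio limit (default 1.5).
#' @param min_sat_assist_pct,min_sat_occlusion_pct saturation floors, %.
#' @param baseline_preservation_tol_mmHg full-failure IVC tolerance, mmHg
#'   (default 0.6, bracketing the reference full-failure rises of
#'   0.18-0.59 mmHg).
#' @return object of class `vep_criteria`.
#' @export
criteria_config <- function(qp_qs_limit = 1.5,
                            min_sat_assist_pct = 80,
                            min_sat_occlusion_pct = 80,
                            baseline_preservation_tol_mmHg = 0.6) {
  if (qp_qs_limit <= 0 || min_sat_assist_pct <= 0 ||
      min_sat_occlusion_pct <= 0 || baseline_preservation_tol_mmHg <= 0) {
    stop("criteria thresholds must be positive", call. = FALSE)
  }
  structure(list(qp_qs_limit = qp_qs_limit,
                 min_sat_assist_pct = min_sat_assist_pct,
                 min_sat_occlusion_pct = min_sat_occlusion_pct,
                 baseline_preservation_tol_mmHg =
                   baseline_preservation_tol_mmHg),
            class = "vep_criteria")
}

#  Solve all four modes and the oxygen bookkeeping for one design.
solve_design <- function(geom, scenario, losses, c_pv = 0.95) {
  modes <- c("BASELINE", "FULL_ASSIST", "AOG_OCCLUSION", "FULL_FAILURE")
  states <- lapply(modes, function(m) {
    tryCatch(
      solve_circulation(scenario, geom = if (m == "BASELINE") NULL else geom,
                        losses = losses, mode = m),
      error = function(e) {
        stop(sprintf("design D_N=%g D_T=%g D_AD=%g, mode %s: %s",
                     geom$d_nozzle, geom$d_throat, geom$d_discharge, m,
                     conditionMessage(e)), call. = FALSE)
      })
  })
  names(states) <- modes
  oxy <- lapply(states, oxygen_state, c_pv = c_pv)
  list(states = states, oxygen = oxy)
}

#' Evaluate the four selection criteria for one solved design
#'
#' @param solved output of the per-design solve inside [run_sweep()]
#'   (list with `states` and `oxygen` per mode).
#' @param scenario the [scenario()] the design was solved under.
#' @param criteria a [criteria_config()].
#' @return list with logical flags `c1`..`c4`, `all_pass` and the assist
#'   IVC pressure drop used for tie-breaking.
#' @export
evaluate_criteria <- function(solved, scenario,
                              criteria = criteria_config()) {
  st <- solved$states
  ox <- solved$oxygen
  q_s <- scenario$q_caval_total
  c1 <- qp_qs_check(st$FULL_ASSIST$q_aog, q_s)$ratio < criteria$qp_qs_limit
  c2 <- ox$FULL_ASSIST$c_sa_pct >= criteria$min_sat_assist_pct
  c3 <- ox$AOG_OCCLUSION$c_sa_pct >= criteria$min_sat_occlusion_pct
  d_failure <- pressure_change_vs_baseline(st$FULL_FAILURE, st$BASELINE)
  c4 <- abs(d_failure$dp_ivc) <= criteria$baseline_preservation_tol_mmHg &&
    d_failure$dp_svc >= -1e-9  # no SVC elevation under full failure
  d_assist <- pressure_change_vs_baseline(st$FULL_ASSIST, st$BASELINE)
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
       all_pass = c1 && c2 && c3 && c4,
       dp_ivc_assist = d_assist$dp_ivc)
}

#' Run the design sweep
#'
#' Solves every design of the space in all four operating modes under one
#' scenario, evaluates the selection criteria and flags the selected
#' design (all criteria passed; ties broken by the largest full-assist IVC
#' pressure drop). Rows are sorted internally (nozzle, throat, discharge
#' ascending) so the output is invariant under permutation of the input
#' design list.
#'
#' @param space a [design_space()], or a data.frame from
#'   [enumerate_design_space()].
#' @param scenario a [scenario()].
#' @param losses a calibrated [loss_model()].
#' @param criteria a [criteria_config()].
#' @param c_pv pulmonary-vein saturation, fraction.
#' @return data.frame of class `vep_sweep`, one row per design, with
#'   per-mode pressures/flows, oxygen summaries, criteria flags and the
#'   `selected` flag. The full per-design solves are kept in attribute
#'   `solves`.
#' @export
run_sweep <- function(space = design_space(),
                      scenario = pediatric_scenario(),
                      losses, criteria = criteria_config(),
                      c_pv = 0.95) {
  designs <- if (inherits(space, "vep_design_space")) {
    enumerate_design_space(space)
  } else {
    d <- space[order(space$d_nozzle, space$d_throat, space$d_discharge), ,
               drop = FALSE]
    rownames(d) <- NULL
    attr(d, "geometries") <- lapply(seq_len(nrow(d)), function(i) {
      device_geometry(d$d_nozzle[i], d$d_throat[i], d$d_discharge[i])
    })
    d
  }
  geoms <- attr(designs, "geometries")
  solves <- lapply(geoms, solve_design, scenario = scenario,
                   losses = losses, c_pv = c_pv)
  evals <- lapply(solves, evaluate_criteria, scenario = scenario,
                  criteria = criteria)

  row_of <- function(i) {
    s <- solves[[i]]
    e <- evals[[i]]
    base <- s$states$BASELINE
    fa <- s$states$FULL_ASSIST
    occ <- s$states$AOG_OCCLUSION
    ff <- s$states$FULL_FAILURE
    d_fa <- pressure_change_vs_baseline(fa, base)
    d_ff <- pressure_change_vs_baseline(ff, base)
    data.frame(
      d_nozzle = designs$d_nozzle[i], d_throat = designs$d_throat[i],
      d_discharge = designs$d_discharge[i], study = designs$study[i],
      p_ivc_baseline = base$p_ivc, p_svc_baseline = base$p_svc,
      p_ivc_assist = fa$p_ivc, p_svc_assist = fa$p_svc,
      p_throat_assist = fa$p_throat,
      dp_ivc_assist = d_fa$dp_ivc, dp_svc_assist = d_fa$dp_svc,
      q_aog_assist = fa$q_aog, q_ad_assist = fa$q_ad,
      q_p_assist = fa$q_p, dq_p_assist_pct = d_fa$dq_p_pct,
      qp_qs_assist = qp_qs_check(fa$q_aog, scenario$q_caval_total)$ratio,
      c_sa_assist_pct = s$oxygen$FULL_ASSIST$c_sa_pct,
      m_assist = s$oxygen$FULL_ASSIST$m,
      q_ad_occlusion = occ$q_ad,
      c_sa_occlusion_pct = s$oxygen$AOG_OCCLUSION$c_sa_pct,
      dp_ivc_failure = -d_ff$dp_ivc,  # positive = IVC elevation
      dp_svc_failure = -d_ff$dp_svc,
      c1 = e$c1, c2 = e$c2, c3 = e$c3, c4 = e$c4,
      all_pass = e$all_pass,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(designs)), row_of))
  out$selected <- FALSE
  if (any(out$all_pass)) {
    cand <- which(out$all_pass)
    out$selected[cand[which.max(out$dp_ivc_assist[cand])]] <- TRUE
  }
  attr(out, "solves") <- solves
  attr(out, "scenario") <- scenario
  class(out) <- c("vep_sweep", "data.frame")
  out
}

#  full-precision CSV: utils::write.csv truncates doubles to 15
#  significant digits, which breaks the round-trip contract
write_csv_full <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  cols <- lapply(df, fmt)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write sweep reports
#'
#' Emits three artifacts under `dir`: `sweep.csv` (one row per design,
#' fixed column order, full numeric precision), `sweep.json` (per-design
#' records) and `summary.txt` (human-readable table marking the selected
#' design). Re-running on identical inputs produces byte-identical files.
#'
#' @param rows a [run_sweep()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_reports <- function(rows, dir) {
  stopifnot(inherits(rows, "vep_sweep"), nrow(rows) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- as.data.frame(rows)
  attr(df, "solves") <- NULL
  attr(df, "scenario") <- NULL
  csv <- file.path(dir, "sweep.csv")
  write_csv_full(df, csv)
  js <- file.path(dir, "sweep.json")
  jsonlite::write_json(df, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- file.path(dir, "summary.txt")
  lines <- c(
    "Design sweep summary (per-design criteria and assist performance)",
    sprintf("%-6s %-6s %-6s  %8s %8s %8s  %-4s %-4s %-4s %-4s %s",
            "D_N", "D_T", "D_AD", "dP_IVC", "Csa%", "Qp/Qs",
            "c1", "c2", "c3", "c4", "selected"),
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("%-6g %-6g %-6g  %8.3f %8.2f %8.3f  %-4s %-4s %-4s %-4s %s",
              df$d_nozzle[i], df$d_throat[i], df$d_discharge[i],
              df$dp_ivc_assist[i], df$c_sa_assist_pct[i],
              df$qp_qs_assist[i],
              df$c1[i], df$c2[i], df$c3[i], df$c4[i],
              if (df$selected[i]) "<== selected" else "")
    }, character(1)))
  writeLines(lines, txt)
  invisible(c(csv = csv, json = js, summary = txt))
}

#' Reload a sweep CSV
#'
#' @param path a `sweep.csv` written by [write_reports()].
#' @return data.frame with the numeric fields restored to full precision.
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
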