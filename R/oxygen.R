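#' Mixing coefficient of the atrial discharge
#'
#' Fraction of the atrial-discharge oxygen content attributable to aortic
#' (arterial) blood. The 0D closure assumes perfect mixing of the jet and
#' the venous stream at the throat, so the coefficient equals the jet's
#' share of the throat mixture: `m = Q_AoG / (Q_AoG + Q_IVC)`, clamped to
#' [0,1]. `m = 0` means a purely venous discharge, `m = 1` purely arterial.
#'
#' @param q_aog aortic graft flow, L/min (>= 0).
#' @param q_ivc IVC flow entering the device, L/min (>= 0).
#' @return mixing coefficient in [0,1].
#' @export
mixing_coefficient <- function(q_aog, q_ivc) {
  if (q_aog < 0 || q_ivc < 0) stop("flows must be >= 0", call. = FALSE)
  if (q_aog + q_ivc == 0) {
    stop("mixing coefficient undefined when both flows are zero",
         call. = FALSE)
  }
  min(1, max(0, q_aog / (q_aog + q_ivc)))
}

#' Systemic arterial oxygen saturation
#'
#' Closed form of the atrial oxygen balance: oxygenated pulmonary-vein
#' blood (`Q_P * C_PV`) and the recirculated atrial-discharge stream mix in
#' the atrium and leave as cardiac output at saturation
#' `C_sa = Q_P C_PV / (CO - (0.6 + 0.4 m) Q_AD)`,
#' using the Fontan venous-arterial relation `C_sv = 0.6 C_sa` and the
#' discharge saturation `C_AD = C_sv + m (C_sa - C_sv)`.
#'
#' @param q_p pulmonary flow, L/min.
#' @param q_ad atrial-discharge (right-to-left shunt) flow, L/min (>= 0).
#' @param co cardiac output, L/min; atrial mass balance requires
#'   `co = q_p + q_ad`.
#' @param m mixing coefficient in [0,1].
#' @param c_pv pulmonary-vein saturation, fraction (default 0.95, chosen
#'   low to avoid overestimation).
#' @return systemic arterial saturation, fraction in (0, c_pv].
#' @export
systemic_saturation <- function(q_p, q_ad, co, m, c_pv = 0.95) {
  if (co <= 0) stop("cardiac output must be positive", call. = FALSE)
  if (m < 0 || m > 1) stop("m must lie in [0, 1]", call. = FALSE)
  denom <- co - (0.6 + 0.4 * m) * q_ad
  if (denom <= 0) {
    stop("unphysical flow set: oxygen-balance denominator <= 0",
         call. = FALSE)
  }
  q_p * c_pv / denom
}

#' Venous saturation from arterial saturation
#'
#' Fontan venous-arterial relation `C_sv = 0.6 C_sa`.
#'
#' @param c_sa arterial saturation, fraction in (0,1].
#' @return venous saturation, fraction.
#' @export
venous_saturation <- function(c_sa) {
  if (c_sa <= 0 || c_sa > 1) {
    stop("arterial saturation must lie in (0, 1]", call. = FALSE)
  }
  0.6 * c_sa
}

#' Atrial-discharge saturation
#'
#' Convex combination `C_AD = C_sv + m (C_sa - C_sv)`: purely venous at
#' `m = 0`, purely arterial at `m = 1`.
#'
#' @param c_sa,c_sv arterial and venous saturations, fractions.
#' @param m mixing coefficient in [0,1].
#' @return discharge saturation, fraction.
#' @export
ad_saturation <- function(c_sa, c_sv, m) {
  if (m < 0 || m > 1) stop("m must lie in [0, 1]", call. = FALSE)
  c_sv + m * (c_sa - c_sv)
}

#' Pulmonary-to-systemic flow ratio check
#'
#' With the graft as the only shunt, `Q_P = Q_S + Q_shunt`, so
#' `Q_P/Q_S = 1 + Q_shunt/Q_S`. Ratios of 1.5 or above indicate a harmful
#' left-to-right shunt load (ventricular volume overload); the criterion
#' passes iff `Q_shunt/Q_S < 0.5`, strictly.
#'
#' @param q_shunt shunt (graft) flow, L/min (>= 0).
#' @param q_s systemic flow, L/min (> 0).
#' @return list with `ratio` (`Q_P/Q_S`) and `pass` (logical).
#' @export
qp_qs_check <- function(q_shunt, q_s) {
  if (q_s <= 0) stop("systemic flow must be positive", call. = FALSE)
  if (q_shunt < 0) stop("shunt flow must be >= 0", call. = FALSE)
  ratio <- 1 + q_shunt / q_s
  list(ratio = ratio, pass = ratio < 1.5)
}

#' Oxygen state of a solved circulation
#'
#' Applies the shunt mixing model to a solved hemodynamic state. When the
#' atrial discharge carries no right-to-left flow (occluded, or reversed
#' into the device under strong throat suction) there is no venous
#' admixture and the arterial saturation equals the pulmonary-vein
#' saturation.
#'
#' @param state a [solve_circulation()] result.
#' @param c_pv pulmonary-vein saturation, fraction.
#' @return object of class `vep_oxygen`: `c_sa`, `c_sv`, `c_ad`, `c_pv`
#'   (fractions), `m`, and the same saturations in percent
#'   (`c_sa_pct`, ...).
#' @export
oxygen_state <- function(state, c_pv = 0.95) {
  stopifnot(inherits(state, "vep_state"))
  if (state$q_ad <= 0) {
    m <- if (state$q_aog + state$q_ivc > 0) {
      mixing_coefficient(state$q_aog, state$q_ivc)
    } else {
      NA_real_
    }
    c_sa <- c_pv
    c_ad <- NA_real_
  } else {
    m <- mixing_coefficient(state$q_aog, state$q_ivc)
    c_sa <- systemic_saturation(state$q_p, state$q_ad, state$co, m, c_pv)
    c_ad <- ad_saturation(c_sa, venous_saturation(c_sa), m)
  }
  c_sv <- venous_saturation(c_sa)
  structure(list(c_sa = c_sa, c_sv = c_sv, c_ad = c_ad, c_pv = c_pv,
                 m = m,
                 c_sa_pct = 100 * c_sa, c_sv_pct = 100 * c_sv,
                 c_ad_pct = 100 * c_ad, c_pv_pct = 100 * c_pv),
            class = "vep_oxygen")
}

#' @export
print.vep_oxygen <- function(x, ...) {
  cat(sprintf(
    "<vep_oxygen> C_sa %.1f%% | C_sv %.1f%% | C_AD %s | m %s\n",
    x$c_sa_pct, x$c_sv_pct,
    ifelse(is.na(x$c_ad_pct), "-", sprintf("%.1f%%", x$c_ad_pct)),
    ifelse(is.na(x$m), "-", sprintf("%.3f", x$m))))
  invisible(x)
}
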