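#  Calibration is deterministic and cheap but used by many files; memoize.
calibrated_1do <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrated_loss_model("1-DO", pediatric_scenario())
    }
    cache
  }
})

selected_design <- function() device_geometry(2.5, 12, 4)

#  Independent closed-form Bernoulli orifice oracle (L/min)
oracle_orifice <- function(dP_mmHg, d_mm, cd, rho = 1060) {
  a <- pi * (d_mm / 2000)^2
  v <- sqrt(2 * abs(dP_mmHg) * 133.322 / rho)
  sign(dP_mmHg) * cd * a * v * 60000
}
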