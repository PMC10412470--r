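#' Venous ejector pump geometry
#'
#' The device has four ports: an IVC inlet and a pulmonary outlet (12 mm,
#' the typical idealized pediatric caval size), an aortic-graft inlet (4 mm,
#' the common systemic-to-pulmonary shunt size) that is restricted by a
#' nozzle of diameter `d_nozzle`, and an atrial-discharge opening
#' (`d_discharge`) acting as a fenestration from the device body to the
#' atrium. The jet exits the nozzle into the mixing throat of diameter
#' `d_throat`.
#'
#' @param d_nozzle aortic nozzle diameter, mm.
#' @param d_throat mixing-throat diameter, mm.
#' @param d_discharge atrial-discharge diameter, mm.
#' @param d_ivc IVC inlet port diameter, mm (default 12).
#' @param d_aog aortic-graft inlet diameter, mm (default 4).
#' @param d_pa pulmonary outlet port diameter, mm (default 12).
#' @return an object of class `vep_geometry`.
#' @seealso [validate_device()], [enumerate_design_space()]
#' @export
device_geometry <- function(d_nozzle, d_throat, d_discharge,
                            d_ivc = 12, d_aog = 4, d_pa = 12) {
  geom <- structure(
    list(d_nozzle = as.numeric(d_nozzle),
         d_throat = as.numeric(d_throat),
         d_discharge = as.numeric(d_discharge),
         d_ivc = as.numeric(d_ivc),
         d_aog = as.numeric(d_aog),
         d_pa = as.numeric(d_pa)),
    class = "vep_geometry")
  geom
}

#' @export
print.vep_geometry <- function(x, ...) {
  cat(sprintf(
    "<vep_geometry> D_N %.3g | D_T %.3g | D_AD %.3g mm (IVC %.3g, AoG %.3g, PA %.3g)\n",
    x$d_nozzle, x$d_throat, x$d_discharge, x$d_ivc, x$d_aog, x$d_pa))
  invisible(x)
}

#' Validate device geometry against design constraints
#'
#' Constraint violations are returned as data, not raised: every diameter
#' must be positive, the nozzle must restrict the aortic graft
#' (`d_nozzle < d_aog`), the throat may not be narrower than half the IVC
#' diameter (narrower throats put too much resistance on the systemic
#' venous return and are excluded from the design space), and the atrial
#' discharge may not exceed the throat.
#'
#' @param geom a [device_geometry()].
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_device <- function(geom) {
  stopifnot(inherits(geom, "vep_geometry"))
  v <- character()
  dia <- unlist(geom[c("d_nozzle", "d_throat", "d_discharge",
                       "d_ivc", "d_aog", "d_pa")])
  if (any(!is.finite(dia)) || any(dia <= 0)) {
    v <- c(v, "non-positive diameter")
  } else {
    if (geom$d_nozzle >= geom$d_aog) {
      v <- c(v, "nozzle does not restrict aortic graft (d_nozzle >= d_aog)")
    }
    if (geom$d_throat < geom$d_ivc / 2) {
      v <- c(v, "throat below half IVC diameter")
    }
    if (geom$d_discharge > geom$d_throat) {
      v <- c(v, "atrial discharge wider than throat")
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' TCPC junction geometry
#'
#' Idealized total cavopulmonary connections are double-inlet double-outlet
#' junctions with 12 mm caval inlets, 9 mm pulmonary outlets, 3 mm fillets
#' and a caval offset of 0, 0.5 or 1 inlet diameters. Patient-specific
#' models (labels `PSC1`, `PSC2`) are carried as labels plus their baseline
#' pressure fixtures only; no surface geometry is modelled.
#'
#' @param label one of `"0-DO"`, `"0.5-DO"`, `"1-DO"`, `"PSC1"`, `"PSC2"`.
#' @param inlet_mm,outlet_mm,fillet_mm idealized junction dimensions, mm.
#' @param offset caval offset in inlet diameters (idealized models only).
#' @return object of class `vep_tcpc`.
#' @export
tcpc_geometry <- function(label = "1-DO", inlet_mm = 12, outlet_mm = 9,
                          fillet_mm = 3, offset = NULL) {
  labels <- c("0-DO", "0.5-DO", "1-DO", "PSC1", "PSC2")
  label <- match.arg(label, labels)
  idealized <- label %in% c("0-DO", "0.5-DO", "1-DO")
  if (is.null(offset)) {
    offset <- switch(label, "0-DO" = 0, "0.5-DO" = 0.5, "1-DO" = 1, NA_real_)
  }
  if (idealized && !offset %in% c(0, 0.5, 1)) {
    stop("idealized TCPC offset must be 0, 0.5 or 1 inlet diameters",
         call. = FALSE)
  }
  if (inlet_mm <= 0 || outlet_mm <= 0) {
    stop("TCPC diameters must be positive", call. = FALSE)
  }
  structure(list(label = label, inlet_mm = inlet_mm, outlet_mm = outlet_mm,
                 fillet_mm = fillet_mm, offset = offset,
                 idealized = idealized),
            class = "vep_tcpc")
}

#' Device design space
#'
#' The design-of-experiments sweep varies three parameters: nozzle diameter
#' (1.5, 2, 2.5, 3 mm), throat diameter (6, 8, 10, 12 mm) and atrial
#' discharge diameter (4, 5, 6 mm). Nozzle size dominates the graft flow,
#' so it is studied separately at a reference throat of 8 mm and discharge
#' of 4 mm; throat and discharge are then crossed at the 2.5 mm nozzle.
#' This yields 15 unique geometries (the 2.5/8/4 case appears once, in the
#' nozzle study).
#'
#' @param nozzles,throats,discharges candidate diameters, mm.
#' @param ref_throat,ref_discharge reference throat/discharge for the
#'   nozzle study, mm.
#' @param ref_nozzle nozzle used in the throat-by-discharge study, mm.
#' @return object of class `vep_design_space`.
#' @export
design_space <- function(nozzles = c(1.5, 2, 2.5, 3),
                         throats = c(6, 8, 10, 12),
                         discharges = c(4, 5, 6),
                         ref_throat = 8, ref_discharge = 4,
                         ref_nozzle = 2.5) {
  if (length(nozzles) == 0 || length(throats) == 0 || length(discharges) == 0) {
    stop("design_space(): all diameter sets must be non-empty", call. = FALSE)
  }
  structure(list(nozzles = sort(unique(nozzles)),
                 throats = sort(unique(throats)),
                 discharges = sort(unique(discharges)),
                 ref_throat = ref_throat, ref_discharge = ref_discharge,
                 ref_nozzle = ref_nozzle),
            class = "vep_design_space")
}

#' Enumerate the device design space
#'
#' Emits the nozzle-study cases (every nozzle at the reference
#' throat/discharge) followed by the throat-by-discharge cases at the
#' reference nozzle, with the duplicate reference case emitted once and
#' attributed to the nozzle study. Ordering is deterministic: nozzle
#' ascending, then throat, then discharge.
#'
#' @param space a [design_space()].
#' @return data.frame with columns `d_nozzle`, `d_throat`, `d_discharge`,
#'   `study` (`"nozzle"` or `"throat_discharge"`); attribute
#'   `geometries` holds the corresponding list of [device_geometry()].
#' @export
enumerate_design_space <- function(space = design_space()) {
  stopifnot(inherits(space, "vep_design_space"))
  nozzle_study <- data.frame(
    d_nozzle = space$nozzles,
    d_throat = space$ref_throat,
    d_discharge = space$ref_discharge,
    study = "nozzle",
    stringsAsFactors = FALSE)
  td <- expand.grid(d_discharge = space$discharges,
                    d_throat = space$throats,
                    KEEP.OUT.ATTRS = FALSE)
  td <- data.frame(d_nozzle = space$ref_nozzle,
                   d_throat = td$d_throat,
                   d_discharge = td$d_discharge,
                   study = "throat_discharge",
                   stringsAsFactors = FALSE)
  #  drop cases already covered by the nozzle study
  dup <- td$d_nozzle %in% nozzle_study$d_nozzle &
    td$d_throat == space$ref_throat &
    td$d_discharge == space$ref_discharge
  out <- rbind(nozzle_study, td[!dup, , drop = FALSE])
  out <- out[order(out$d_nozzle, out$d_throat, out$d_discharge), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "geometries") <- lapply(seq_len(nrow(out)), function(i) {
    device_geometry(out$d_nozzle[i], out$d_throat[i], out$d_discharge[i])
  })
  out
}

#' Read/write device geometry as JSON
#'
#' @param geom a [device_geometry()].
#' @param path file path.
#' @return `read_geometry_json` returns a `vep_geometry`;
#'   `write_geometry_json` returns `path` invisibly.
#' @export
write_geometry_json <- function(geom, path) {
  stopifnot(inherits(geom, "vep_geometry"))
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  device_geometry(x$d_nozzle, x$d_throat, x$d_discharge,
                  d_ivc = x$d_ivc, d_aog = x$d_aog, d_pa = x$d_pa)
}

#' Export an enumerated design space as CSV
#'
#' One row per case with columns `D_N`, `D_T`, `D_AD` (mm).
#'
#' @param designs output of [enumerate_design_space()].
#' @param path file path.
#' @export
write_design_space_csv <- function(designs, path) {
  out <- data.frame(D_N = designs$d_nozzle, D_T = designs$d_throat,
                    D_AD = designs$d_discharge)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
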