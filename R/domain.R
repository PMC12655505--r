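#' Typed parameter records
#'
#' Constructors for the shared records used throughout the pipeline. Each
#' constructor builds a classed list and (by default) stops if any invariant
#' of the type is violated; [validate_record()] returns the violation report
#' without stopping.
#'
#' @name records
NULL

new_record <- function(x, class, check = TRUE) {
  structure(x, class = c(class, "pbk_record", "list"))
}

finish_record <- function(x, check) {
  if (check) {
    v <- validate_record(x)
    if (length(v) > 0)
      stop("invalid ", class(x)[1], ": ", paste(v, collapse = "; "), call. = FALSE)
  }
  x
}

#' @param name chemical name.
#' @param mw molar mass, g/mol.
#' @param logp octanol-water log10 partition coefficient.
#' @param pka acid dissociation constant (NA for neutrals without one).
#' @param sw aqueous solubility, mg/mL.
#' @param fup fraction unbound in plasma, (0, 1].
#' @param rbp blood/plasma concentration ratio.
#' @param clint_hep hepatocyte intrinsic clearance, uL/min/mg protein.
#' @param clint_skin skin S9 intrinsic clearance, uL/min/mg protein (optional).
#' @param check validate invariants and stop on violation (default TRUE).
#' @return a `chemical_properties` record.
#' @rdname records
#' @export
chemical_properties <- function(name, mw, logp, pka = NA_real_, sw,
                                fup, rbp, clint_hep = 0,
                                clint_skin = NA_real_, check = TRUE) {
  x <- new_record(list(name = name, mw = mw, logp = logp, pka = pka, sw = sw,
                       fup = fup, rbp = rbp, clint_hep = clint_hep,
                       clint_skin = clint_skin),
                  "chemical_properties")
  finish_record(x, check)
}

#' @param active_fraction mass fraction of solute in the formulation, (0, 1).
#' @param form_type `"solution"` or `"lotion"`.
#' @param dose_per_area applied formulation mass per area, mg/cm^2.
#' @param solubility_in_vehicle solute concentration at application, mg/mL
#'   (finite-dose products are formulated at their solubility limit, so the
#'   dissolved concentration is capped here as the vehicle dries down).
#' @param residual_fraction fraction of vehicle volume remaining after
#'   dry-down, [0, 1].
#' @param evaporation_rate vehicle volume loss rate, mL/h, as measured on
#'   `measured_area`.
#' @param density formulation density, g/mL.
#' @param measured_area area (cm^2) on which `evaporation_rate` was measured;
#'   simulators rescale the rate proportionally to the applied area.
#' @rdname records
#' @export
formulation_spec <- function(name, active_fraction,
                             form_type = c("solution", "lotion"),
                             dose_per_area = 2, solubility_in_vehicle,
                             residual_fraction, evaporation_rate,
                             density = 1, measured_area = 2, check = TRUE) {
  form_type <- match.arg(form_type)
  x <- new_record(list(name = name, active_fraction = active_fraction,
                       form_type = form_type, dose_per_area = dose_per_area,
                       solubility_in_vehicle = solubility_in_vehicle,
                       residual_fraction = residual_fraction,
                       evaporation_rate = evaporation_rate,
                       density = density, measured_area = measured_area),
                  "formulation_spec")
  finish_record(x, check)
}

#' @param thickness_sc stratum corneum thickness, um.
#' @param thickness_ve viable epidermis thickness, um.
#' @param thickness_de dermis thickness, um.
#' @param area exposed area, cm^2.
#' @param temperature skin surface temperature, degrees C.
#' @rdname records
#' @export
skin_stack <- function(thickness_sc, thickness_ve, thickness_de,
                       area = 2, temperature = 32, check = TRUE) {
  x <- new_record(list(thickness_sc = thickness_sc,
                       thickness_ve = thickness_ve,
                       thickness_de = thickness_de,
                       area = area, temperature = temperature),
                  "skin_stack")
  finish_record(x, check)
}

#' @param d_vh,d_sc,d_ve,d_de layer diffusivities, cm^2/s.
#' @param k_vh_w,k_sc_w,k_ve_w,k_de_w water-referenced partition
#'   coefficients K_x/w. Layer-to-layer coefficients are derived as
#'   K_a/b = K_a/w / K_b/w.
#' @param application_time exposure duration, h (the time after which
#'   solute can no longer leave the vehicle for the skin).
#' @rdname records
#' @export
dermal_parameters <- function(d_vh, k_vh_w, d_sc, k_sc_w, d_ve, k_ve_w,
                              d_de, k_de_w, application_time, check = TRUE) {
  x <- new_record(list(d_vh = d_vh, k_vh_w = k_vh_w, d_sc = d_sc,
                       k_sc_w = k_sc_w, d_ve = d_ve, k_ve_w = k_ve_w,
                       d_de = d_de, k_de_w = k_de_w,
                       application_time = application_time),
                  "dermal_parameters")
  finish_record(x, check)
}

#' @param q_liver hepatic blood flow, L/h.
#' @param gfr glomerular filtration rate, L/h.
#' @param ksys first-order systemic absorption rate from dermis, 1/h.
#' @param tissue_set data.frame with columns `tissue`, `volume_l`,
#'   `flow_l_h`, `kp` (tissue/plasma partition coefficient).
#' @param body_weight kg.
#' @param age years.
#' @param sex `"male"` or `"female"`.
#' @rdname records
#' @export
systemic_parameters <- function(q_liver, gfr, ksys, tissue_set,
                                body_weight, age, sex = c("male", "female"),
                                check = TRUE) {
  sex <- match.arg(sex)
  x <- new_record(list(q_liver = q_liver, gfr = gfr, ksys = ksys,
                       tissue_set = tissue_set, body_weight = body_weight,
                       age = age, sex = sex),
                  "systemic_parameters")
  finish_record(x, check)
}

#' @param events data.frame with columns `time_h`, `mass_mg` (formulation
#'   mass), `volume_ml` (formulation volume), `area_cm2` (applied area).
#' @param occlusive logical; occlusive application suppresses evaporation.
#' @rdname records
#' @export
dose_regimen <- function(events, occlusive = FALSE, check = TRUE) {
  x <- new_record(list(events = events, occlusive = occlusive),
                  "dose_regimen")
  finish_record(x, check)
}

# ---------------------------------------------------------------------------

#' Validate a domain record
#'
#' Returns a character vector of invariant violations (empty if the record is
#' valid); each violation names the offending field and the rule broken. It
#' never raises an error, so it can be used to build validation reports for
#' user-supplied configuration.
#'
#' @param record any record built by the constructors in this package.
#' @return character vector of violations (length 0 if valid).
#' @export
validate_record <- function(record) UseMethod("validate_record")

#' @export
validate_record.default <- function(record) {
  character(0)
}

chk <- function(cond, msg) if (isTRUE(cond)) character(0) else msg

num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

#' @export
validate_record.chemical_properties <- function(record) {
  c(chk(num_ok(record$mw) && record$mw > 0, "mw: must be > 0"),
    chk(num_ok(record$fup) && record$fup > 0 && record$fup <= 1,
        "fup: must be in (0, 1]"),
    chk(num_ok(record$rbp) && record$rbp > 0, "rbp: must be > 0"),
    chk(num_ok(record$sw) && record$sw > 0, "sw: must be > 0"),
    chk(num_ok(record$clint_hep) && record$clint_hep >= 0,
        "clint_hep: must be >= 0"),
    chk(is.na(record$clint_skin) ||
          (num_ok(record$clint_skin) && record$clint_skin >= 0),
        "clint_skin: must be >= 0 or NA"))
}

#' @export
validate_record.formulation_spec <- function(record) {
  c(chk(num_ok(record$active_fraction) && record$active_fraction > 0 &&
          record$active_fraction < 1, "active_fraction: must be in (0, 1)"),
    chk(num_ok(record$residual_fraction) && record$residual_fraction >= 0 &&
          record$residual_fraction <= 1,
        "residual_fraction: must be in [0, 1]"),
    chk(num_ok(record$evaporation_rate) && record$evaporation_rate >= 0,
        "evaporation_rate: must be >= 0"),
    chk(num_ok(record$dose_per_area) && record$dose_per_area > 0,
        "dose_per_area: must be > 0"),
    chk(num_ok(record$solubility_in_vehicle) &&
          record$solubility_in_vehicle > 0,
        "solubility_in_vehicle: must be > 0"),
    chk(num_ok(record$density) && record$density > 0, "density: must be > 0"),
    chk(num_ok(record$measured_area) && record$measured_area > 0,
        "measured_area: must be > 0"))
}

#' @export
validate_record.skin_stack <- function(record) {
  c(chk(num_ok(record$thickness_sc) && record$thickness_sc > 0,
        "thickness_sc: must be > 0"),
    chk(num_ok(record$thickness_ve) && record$thickness_ve > 0,
        "thickness_ve: must be > 0"),
    chk(num_ok(record$thickness_de) && record$thickness_de > 0,
        "thickness_de: must be > 0"),
    chk(num_ok(record$area) && record$area > 0, "area: must be > 0"))
}

#' @export
validate_record.dermal_parameters <- function(record) {
  d <- c("d_vh", "d_sc", "d_ve", "d_de")
  k <- c("k_vh_w", "k_sc_w", "k_ve_w", "k_de_w")
  c(unlist(lapply(d, function(f)
    chk(num_ok(record[[f]]) && record[[f]] > 0,
        paste0(f, ": diffusivity must be > 0")))),
    unlist(lapply(k, function(f)
      chk(num_ok(record[[f]]) && record[[f]] > 0,
          paste0(f, ": partition coefficient must be > 0")))),
    chk(num_ok(record$application_time) && record$application_time > 0,
        "application_time: must be > 0"))
}

#' @export
validate_record.systemic_parameters <- function(record) {
  ts <- record$tissue_set
  c(chk(num_ok(record$q_liver) && record$q_liver > 0, "q_liver: must be > 0"),
    chk(num_ok(record$gfr) && record$gfr > 0, "gfr: must be > 0"),
    chk(num_ok(record$ksys) && record$ksys > 0, "ksys: must be > 0"),
    chk(num_ok(record$body_weight) && record$body_weight > 0,
        "body_weight: must be > 0"),
    chk(is.data.frame(ts) &&
          all(c("tissue", "volume_l", "flow_l_h", "kp") %in% names(ts)),
        "tissue_set: must have columns tissue, volume_l, flow_l_h, kp"),
    if (is.data.frame(ts) && all(c("volume_l", "flow_l_h", "kp") %in% names(ts))) {
      c(chk(all(ts$volume_l > 0), "tissue_set$volume_l: all must be > 0"),
        chk(all(ts$flow_l_h > 0), "tissue_set$flow_l_h: all must be > 0"),
        chk(all(ts$kp > 0), "tissue_set$kp: all must be > 0"))
    } else character(0))
}

#' @export
validate_record.dose_regimen <- function(record) {
  ev <- record$events
  c(chk(is.data.frame(ev) &&
          all(c("time_h", "mass_mg", "volume_ml", "area_cm2") %in% names(ev)),
        "events: must have columns time_h, mass_mg, volume_ml, area_cm2"),
    if (is.data.frame(ev) && all(c("time_h", "mass_mg", "area_cm2") %in% names(ev))) {
      c(chk(!is.unsorted(ev$time_h), "events$time_h: must be non-decreasing"),
        chk(all(ev$mass_mg > 0), "events$mass_mg: all must be > 0"),
        chk(all(ev$area_cm2 > 0), "events$area_cm2: all must be > 0"))
    } else character(0))
}

#' @export
print.pbk_record <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- x[!vapply(x, is.data.frame, logical(1))]
  str(flat, give.attr = FALSE, no.list = TRUE)
  dfs <- x[vapply(x, is.data.frame, logical(1))]
  for (nm in names(dfs)) {
    cat(nm, ": ", nrow(dfs[[nm]]), " rows\n", sep = "")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Skin layer thickness from tissue mass
#'
#' Converts a weighed tissue sample into a thickness, assuming the sample
#' covers the stated area uniformly. Mass is converted to volume through the
#' density (skin is taken as 1 g/mL) and divided by the area.
#'
#' @param mass tissue mass, mg.
#' @param area sample area, cm^2.
#' @param density tissue density, g/mL (default 1).
#' @return thickness in micrometres.
#' @examples
#' thickness_from_mass(181.4, 2) # a 907-um full-thickness sample
#' @export
thickness_from_mass <- function(mass, area, density = 1) {
  if (!num_ok(area) || area <= 0)
    stop("invalid-geometry: area must be > 0", call. = FALSE)
  if (!num_ok(density) || density <= 0)
    stop("invalid-geometry: density must be > 0", call. = FALSE)
  if (!is.numeric(mass) || any(mass < 0))
    stop("mass must be >= 0", call. = FALSE)
  volume_ml <- (mass / 1000) / density   # mg -> g -> cm^3
  cm_to_um(volume_ml / area)
}

#' Layer-to-layer partition coefficients from layer concentrations
#'
#' Derives the adjacent-compartment partition coefficients measured in a
#' skin-distribution experiment from the solute concentration in each
#' compartment at a stated (near-equilibrium) time. Orientation follows the
#' experimental convention: K_sc/vh, K_ve/sc, K_ve/de, K_rf/de.
#'
#' @param conc named numeric vector with elements `vh`, `sc`, `ve`, `de`,
#'   `rf`: solute concentration per compartment volume (ug/mL).
#' @return named numeric vector `k_sc_vh`, `k_ve_sc`, `k_ve_de`, `k_rf_de`.
#' @export
partitions_from_layer_ratios <- function(conc) {
  need <- c("vh", "sc", "ve", "de", "rf")
  if (!all(need %in% names(conc)))
    stop("conc must be named with: ", paste(need, collapse = ", "),
         call. = FALSE)
  conc <- conc[need]
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  den <- c(vh = conc[["vh"]], sc = conc[["sc"]], de = conc[["de"]])
  if (any(den == 0))
    stop("undefined-partition: zero concentration in denominator compartment (",
         paste(names(den)[den == 0], collapse = ", "), ")", call. = FALSE)
  c(k_sc_vh = conc[["sc"]] / conc[["vh"]],
    k_ve_sc = conc[["ve"]] / conc[["sc"]],
    k_ve_de = conc[["ve"]] / conc[["de"]],
    k_rf_de = conc[["rf"]] / conc[["de"]])
}
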