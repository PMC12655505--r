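#' Oxybenzone chemical record
#'
#' Physicochemical and ADME constants of oxybenzone (benzophenone-3, CAS
#' 131-57-7) as used throughout the worked examples: molar mass 228.2
#' g/mol, measured logP 3.38, strongest acid pKa 10.11, aqueous solubility
#' 0.071 mg/mL, plasma unbound fraction 0.01, measured blood/plasma ratio
#' 0.693, and a skin S9 intrinsic clearance of 0.40 uL/min/mg protein
#' (negligible; the dermal model ignores skin metabolism by default). The
#' hepatocyte intrinsic clearance is a package default chosen so that,
#' after IVIVE scaling, hepatic elimination is essentially flow-limited -
#' the regime reported for this solute; it can be overridden.
#'
#' @param clint_hep hepatocyte intrinsic clearance, uL/min/mg protein.
#' @return a [chemical_properties()] record.
#' @export
oxybenzone_properties <- function(clint_hep = 40) {
  chemical_properties(name = "oxybenzone", mw = 228.2, logp = 3.38,
                      pka = 10.11, sw = 0.071, fup = 0.01, rbp = 0.693,
                      clint_hep = clint_hep, clint_skin = 0.40)
}

#' Sunscreen formulation fixtures
#'
#' Four oxybenzone formulations matching the strengths of the clinical
#' products (6% aerosol spray, 4% lotion, 6% spray, 5% spray), applied at
#' 2 mg formulation per cm^2. Evaporation behaviour (residual fraction and
#' volume-loss rate on a 2 cm^2 film) is not published per product; the
#' values here are realistic laboratory dry-down figures - sprays dry
#' faster and more completely than the lotion - and serve as the ground
#' truth of the synthetic in vitro study.
#'
#' @return named list of [formulation_spec()] records (`F1`..`F4`).
#' @export
formulation_fixtures <- function() {
  list(
    F1 = formulation_spec("F1_spray_6pct", 0.06, "solution",
                          dose_per_area = 2, solubility_in_vehicle = 60,
                          residual_fraction = 0.05,
                          evaporation_rate = 0.008),
    F2 = formulation_spec("F2_lotion_4pct", 0.04, "lotion",
                          dose_per_area = 2, solubility_in_vehicle = 40,
                          residual_fraction = 0.15,
                          evaporation_rate = 0.004),
    F3 = formulation_spec("F3_spray_6pct", 0.06, "solution",
                          dose_per_area = 2, solubility_in_vehicle = 60,
                          residual_fraction = 0.08,
                          evaporation_rate = 0.006),
    F4 = formulation_spec("F4_spray_5pct", 0.05, "solution",
                          dose_per_area = 2, solubility_in_vehicle = 50,
                          residual_fraction = 0.06,
                          evaporation_rate = 0.007))
}

#' Skin stacks for the in vitro and in vivo modules
#'
#' In vitro: dermatomed abdominal skin of 907 um mean full thickness
#' (stratum corneum 15 um by optical coherence tomography, viable epidermis
#' 125 um, dermis 767 um) on a 2 cm^2 Franz cell at 32 degrees C. In vivo:
#' default body-site thicknesses with the dermis depth set to the
#' effective diffusion distance to the dermal microvasculature (500 um,
#' mid-dermis: capillary uptake is distributed through the vascular
#' plexuses rather than concentrated at the papillary tips, so the
#' effective path to the absorbing boundary is deeper than the papillary
#' plexus itself); exposed area 14,250 cm^2 (75% of body surface, the
#' sunscreen maximal-use scenario).
#'
#' @name skin_stacks
#' @return a [skin_stack()] record.
NULL

#' @rdname skin_stacks
#' @export
skin_stack_invitro <- function() {
  skin_stack(thickness_sc = 15, thickness_ve = 125, thickness_de = 767,
             area = 2, temperature = 32)
}

#' @rdname skin_stacks
#' @export
skin_stack_invivo <- function(area = 14250) {
  skin_stack(thickness_sc = 15, thickness_ve = 80, thickness_de = 500,
             area = area, temperature = 32)
}

#' Ground-truth dermal parameters of the synthetic in vitro study
#'
#' The parameter sets from which the packaged synthetic Franz-cell fixture
#' is generated. Chemical-specific values (viable epidermis and dermis) are
#' shared across formulations; the dermis diffusivity is the measured
#' isolated-dermis value 1.27e-7 cm^2/s and the vehicle diffusivity the
#' aqueous default 7.5e-6 cm^2/s. Formulation-specific values (vehicle
#' partitioning, stratum corneum transport, exposure time = evaporation
#' time) are chosen so the simulated study reproduces the reported
#' magnitudes of finite-dose oxybenzone absorption: a strongly
#' solute-retaining vehicle, stratum corneum as the main barrier, a few
#' percent of the dose in the receptor fluid by 24 h.
#'
#' @return named list (`F1`..`F4`) of [dermal_parameters()] records.
#' @export
dermal_truth_params <- function() {
  shared <- list(d_vh = 7.5e-6, d_ve = 5e-8, k_ve_w = 8,
                 d_de = 1.27e-7, k_de_w = 3)
  spec <- list(
    F1 = list(k_vh_w = 2000, d_sc = 8e-10, k_sc_w = 220,
              application_time = 0.475),
    F2 = list(k_vh_w = 1800, d_sc = 1.0e-9, k_sc_w = 230,
              application_time = 0.85),
    F3 = list(k_vh_w = 1800, d_sc = 9e-10, k_sc_w = 230,
              application_time = 0.6133333),
    F4 = list(k_vh_w = 1600, d_sc = 1e-9, k_sc_w = 240,
              application_time = 0.5371429))
  lapply(spec, function(s)
    do.call(dermal_parameters, c(shared, s)))
}

#' Dose regimens of the clinical application scenarios
#'
#' Single dose: one application of 28.5 mL formulation (28.5 g at unit
#' density) to 14,250 cm^2 of skin on day 1. Multiple dose: the single
#' application on day 1, then four applications per day at 2-h intervals on
#' days 2-4 (application times 24, 26, 28, 30 h and so on).
#'
#' @param volume_ml formulation volume per application.
#' @param area_cm2 treated area.
#' @param density formulation density, g/mL.
#' @name regimens
#' @return a [dose_regimen()] record.
NULL

#' @rdname regimens
#' @export
regimen_single <- function(volume_ml = 28.5, area_cm2 = 14250, density = 1) {
  dose_regimen(data.frame(time_h = 0, mass_mg = volume_ml * density * 1000,
                          volume_ml = volume_ml, area_cm2 = area_cm2))
}

#' @rdname regimens
#' @export
regimen_repeated <- function(volume_ml = 28.5, area_cm2 = 14250,
                             density = 1) {
  t <- c(0, as.vector(outer(c(0, 2, 4, 6), c(24, 48, 72), `+`)))
  dose_regimen(data.frame(time_h = sort(t),
                          mass_mg = volume_ml * density * 1000,
                          volume_ml = volume_ml, area_cm2 = area_cm2))
}

#' Clinical subjects of the validation scenarios
#'
#' Demographics of the single male subject simulated per formulation:
#' 41 years / 76 kg (formulation 1) and 45 years / 76.3 kg (formulation 2).
#'
#' @return named list with `F1` and `F2` demographic lists.
#' @export
clinical_subjects <- function() {
  list(F1 = list(age = 41, body_weight = 76, sex = "male"),
       F2 = list(age = 45, body_weight = 76.3, sex = "male"))
}

#' Observed clinical PK metrics used for external validation
#'
#' Mean observed plasma PK metrics of the single-dose (day-1) clinical
#' scenario per formulation: Cmax 0.0894 / 0.0800 ug/mL and AUC0-23
#' 1.29 / 1.26 ug*h/mL for formulations 1 and 2.
#'
#' @return named list with `F1` and `F2`, each holding `cmax` and
#'   `auc_0_t`.
#' @export
observed_clinical_metrics <- function() {
  list(F1 = list(cmax = 0.0894, auc_0_t = 1.29),
       F2 = list(cmax = 0.0800, auc_0_t = 1.26))
}
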