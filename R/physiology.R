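#' Reference human physiology table
#'
#' Perfusion-limited compartment volumes, regional blood flows and tissue
#' composition fractions (water, neutral lipid, phospholipid) for a
#' reference 70-kg adult, assembled from standard physiology compilations
#' (Brown et al. 1997, ICRP 89) and the tissue-composition tables of the
#' Kp-prediction literature (Poulin & Theil; Rodgers & Rowland). Shipped as
#' a versioned CSV under `inst/extdata`.
#'
#' Liver receives its arterial flow plus the portal venous outflow of gut
#' and spleen (19 + 60 + 11 = 90 L/h total hepatic flow at reference size);
#' the `lung` row carries total cardiac output (390 L/h). Scaling to a
#' subject: volumes proportional to body weight, flows (and GFR) to body
#' weight to the 3/4 power. Sex and age are carried for reporting; the
#' simplified physiology does not differentiate them further.
#'
#' @param body_weight subject body weight, kg.
#' @param sex `"male"` or `"female"` (recorded, not used for scaling).
#' @return data.frame with columns `tissue`, `volume_l`, `flow_l_h`, `fw`,
#'   `fnl`, `fph`, plus attributes `blood_volume_l` (named arterial/venous),
#'   `gfr_l_h`, `cardiac_output_l_h`.
#' @export
human_physiology <- function(body_weight = 70, sex = c("male", "female")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", "physiology_human.csv", package = "dermalpbk")
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  sv <- body_weight / 70
  sq <- sv^0.75
  ref$volume_l <- ref$volume_l * sv
  ref$flow_l_h <- ref$flow_l_h * sq
  attr(ref, "blood_volume_l") <- c(arterial = 1.7 * sv, venous = 3.5 * sv)
  attr(ref, "gfr_l_h") <- 7.2 * sq
  attr(ref, "cardiac_output_l_h") <- ref$flow_l_h[ref$tissue == "lung"]
  attr(ref, "sex") <- sex
  ref
}

#' Plasma composition constants used by the Kp method
#' @keywords internal
.plasma_composition <- list(fw = 0.945, fnl = 0.0023, fph = 0.0013)

#' Tissue/plasma partition coefficient from tissue composition
#'
#' A documented tissue-composition method in the Poulin/Rodgers family for
#' neutral lipophilic solutes: the tissue affinity per unit unbound plasma
#' concentration is
#'
#' \deqn{Kpu = f_w + P \cdot f_{nl} + (0.3 P + 0.7) f_{ph} + B}
#'
#' with \eqn{P = 10^{logP}} the octanol-water partition coefficient,
#' \eqn{f_w, f_{nl}, f_{ph}} the tissue fractions of water, neutral lipid
#' and phospholipid, and \eqn{B} an optional explicit tissue-binding
#' capacity (default 0). Plasma binding enters through the measured
#' unbound fraction (plasma affinity is 1/fup by definition), giving
#' `Kp = fup * Kpu`. Kp is strictly increasing in logP for any tissue with
#' lipid content.
#'
#' @param chem a [chemical_properties()] record (`logp`, `fup` required).
#' @param tissue list or one-row data.frame with `fw`, `fnl`, `fph` and
#'   optionally `binding` (affinity per unit unbound concentration).
#' @return tissue/plasma partition coefficient (dimensionless, > 0).
#' @export
kp_estimate <- function(chem, tissue) {
  stopifnot(inherits(chem, "chemical_properties"))
  need <- c("fw", "fnl", "fph")
  if (!all(need %in% names(tissue)))
    stop("configuration: tissue record must have fields fw, fnl, fph",
         call. = FALSE)
  p <- 10^chem$logp
  b <- if (!is.null(tissue[["binding"]]) && !is.na(tissue[["binding"]]))
    tissue[["binding"]] else 0
  kpu <- tissue[["fw"]] + p * tissue[["fnl"]] +
    (0.3 * p + 0.7) * tissue[["fph"]] + b
  chem$fup * kpu
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = V_plasma + sum(V_t * Kp_t)` (plasma-referenced; red-cell
#' partitioning is subsumed in the Rbp used at output).
#'
#' @param tissue_set data.frame with `volume_l` and `kp`.
#' @param v_plasma plasma volume, L.
#' @return Vss in L.
#' @export
vss_from_kp <- function(tissue_set, v_plasma = 3) {
  v_plasma + sum(tissue_set$volume_l * tissue_set$kp)
}

#' Assemble systemic parameters for a subject
#'
#' Builds the [systemic_parameters()] record for the whole-body model:
#' scales the reference physiology to the subject, computes every tissue Kp
#' with [kp_estimate()], derives total hepatic flow (liver + portal), GFR
#' and the first-order dermis uptake rate.
#'
#' @param chem a [chemical_properties()] record.
#' @param body_weight,age,sex subject demographics.
#' @param dermal_params,stack used for [ksys_from_dermis()] when `ksys` is
#'   not given directly.
#' @param ksys optional explicit systemic absorption rate, 1/h.
#' @return a [systemic_parameters()] record.
#' @export
build_systemic_parameters <- function(chem, body_weight = 70, age = 40,
                                      sex = "male", dermal_params = NULL,
                                      stack = NULL, ksys = NULL) {
  phys <- human_physiology(body_weight, sex)
  ts <- phys[phys$tissue != "lung", ]
  kp <- vapply(seq_len(nrow(phys)), function(i) kp_estimate(chem, phys[i, ]),
               numeric(1))
  phys$kp <- kp
  tissue_set <- phys[, c("tissue", "volume_l", "flow_l_h", "kp")]
  q_liver <- sum(tissue_set$flow_l_h[tissue_set$tissue %in%
                                       c("liver", "gut", "spleen")])
  if (is.null(ksys)) {
    ksys <- if (!is.null(dermal_params) && !is.null(stack))
      ksys_from_dermis(dermal_params, stack) else 1
  }
  sp <- systemic_parameters(q_liver = q_liver,
                            gfr = attr(phys, "gfr_l_h"),
                            ksys = ksys,
                            tissue_set = tissue_set,
                            body_weight = body_weight, age = age, sex = sex)
  attr(sp, "blood_volume_l") <- attr(phys, "blood_volume_l")
  attr(sp, "cardiac_output_l_h") <- attr(phys, "cardiac_output_l_h")
  sp
}
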