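#' Run the complete bottom-up L2 validation study on synthetic data
#'
#' One-call version of the package's headline workflow. It (1) generates
#' the synthetic four-formulation Franz-cell study and the isolated-dermis
#' permeation curves from the packaged ground truth, (2) estimates the
#' dermis diffusivity from the dermis curves, (3) runs the two-stage
#' refinement (chemical-specific parameters jointly over all four
#' formulations, then formulation-specific parameters for the two clinical
#' formulations), (4) simulates the single-dose clinical scenario for each
#' formulation with its subject demographics, and (5) compares predicted
#' Cmax and AUC0-23 against the observed clinical values with the 2-fold
#' rule.
#'
#' @param seed integer seed driving all synthetic-data generation.
#' @param noise_cv measurement noise CV of the synthetic in vitro study.
#' @param n_replicates donors per formulation.
#' @param dermis_noise_cv,dermis_n noise and replication of the synthetic
#'   isolated-dermis experiment.
#' @param regimen dose regimen (default single application).
#' @return the [run_pipeline()] result, plus `max_fold` (the maximum fold
#'   deviation over both formulations' Cmax and AUC0-23) and `fixture`
#'   (the generated datasets and their truth).
#' @export
l2_validation_study <- function(seed, noise_cv = 0.2, n_replicates = 8,
                                dermis_noise_cv = 0.05, dermis_n = 8,
                                regimen = regimen_single()) {
  chem <- oxybenzone_properties()
  forms <- formulation_fixtures()
  truth <- dermal_truth_params()
  stack_vitro <- skin_stack_invitro()

  fix <- lapply(seq_along(forms), function(i)
    gen_franz_dataset(chem, forms[[i]], truth[[i]], noise_cv = noise_cv,
                      n_replicates = n_replicates, seed = seed + i))
  names(fix) <- names(forms)

  # isolated dermis: saturated aqueous donor (C_d = Sw), measured truth
  # D_de = 1.27e-7 cm^2/s, K_de/veh = k_de_w (aqueous vehicle)
  c_d <- chem$sw * 1000
  l_cm <- um_to_cm(stack_vitro$thickness_de)
  m2 <- cm2s_to_cm2h(truth$F1$d_de) / l_cm^2
  m1 <- c_d * truth$F1$k_de_w * l_cm
  gd <- gen_dermis_permeation(m1, m2, noise_cv = dermis_noise_cv,
                              n = dermis_n, seed = seed + 100)
  ag <- stats::aggregate(q_rf_ug_per_cm2 ~ time_h, data = gd$data,
                         FUN = mean)

  cfg <- list(level = "L2", chem = chem,
              formulations = forms[c("F1", "F2")],
              stack_invitro = stack_vitro,
              stack_invivo = skin_stack_invivo(),
              subjects = clinical_subjects(),
              regimen = regimen,
              observed = observed_clinical_metrics(),
              franz_datasets = lapply(fix, `[[`, "dataset"),
              dermis_curve = ag,
              dermis_c_d = c_d)
  res <- run_pipeline(cfg, seed = seed)
  res$max_fold <- max(unlist(lapply(res$validation,
                                    function(v) v$fold_deviation)))
  res$fixture <- fix
  res
}
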