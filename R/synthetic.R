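#' Multiplicative log-normal noise
#'
#' Concentrations and amounts are positive and their spread is reported as
#' a CV, so all generators perturb the noiseless value multiplicatively by
#' a log-normal factor with median 1 (`sigma^2 = ln(1 + CV^2)`).
#' @keywords internal
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma))
}

#' Generate replicate isolated-dermis permeation curves
#'
#' Evaluates the membrane series [qrf_series()] at the sampling design of
#' the isolated-dermis experiment (default: 1.5, 3, 5, 7, 9, 12, 14, 16,
#' 20, 24 h) and applies multiplicative noise per replicate.
#'
#' @param m1,m2 series parameters (see [qrf_series()]).
#' @param times sampling times, h.
#' @param noise_cv multiplicative noise CV (fraction).
#' @param n number of replicate donors.
#' @param seed integer seed (mandatory; generation is bit-reproducible).
#' @return list with `data` (data.frame `time_h`, `q_rf_ug_per_cm2`,
#'   `replicate_id`), `truth` (m1, m2), `seed`.
#' @export
gen_dermis_permeation <- function(m1, m2,
                                  times = c(1.5, 3, 5, 7, 9, 12, 14, 16,
                                            20, 24),
                                  noise_cv = 0, n = 1, seed) {
  stopifnot(m2 > 0, !missing(seed))
  set.seed(as.integer(seed))
  q0 <- qrf_series(m1, m2, times)
  data <- do.call(rbind, lapply(seq_len(n), function(r)
    data.frame(time_h = times,
               q_rf_ug_per_cm2 = q0 * .ln_noise(length(times), noise_cv),
               replicate_id = r)))
  list(data = data, truth = list(m1 = m1, m2 = m2), seed = seed)
}

#' Generate a formulation weight-loss (evaporation) curve
#'
#' Linear dry-down to the residual plateau by default, or an exponential
#' approach to the plateau whose initial slope matches the stated rate.
#'
#' @param initial_mass_mg applied formulation mass.
#' @param residual_fraction plateau mass fraction.
#' @param evaporation_rate volume loss rate, mL/h.
#' @param times recording times, h.
#' @param profile `"linear"` or `"exponential"`.
#' @param noise_cv,seed noise CV and seed (noise optional here; balances
#'   are precise).
#' @param density formulation density, g/mL.
#' @return list with `data` (`time_h`, `mass_mg`), `truth`, `seed`.
#' @export
gen_evaporation_curve <- function(initial_mass_mg = 4,
                                  residual_fraction = 0.1,
                                  evaporation_rate = 0.008,
                                  times = seq(0, 4, by = 1 / 12),
                                  profile = c("linear", "exponential"),
                                  noise_cv = 0, seed = 1, density = 1) {
  profile <- match.arg(profile)
  set.seed(as.integer(seed))
  m_res <- initial_mass_mg * residual_fraction
  slope <- 1000 * density * evaporation_rate   # mg/h
  m <- if (profile == "linear") {
    pmax(initial_mass_mg - slope * times, m_res)
  } else {
    k <- slope / (initial_mass_mg - m_res)
    m_res + (initial_mass_mg - m_res) * exp(-k * times)
  }
  m <- m * .ln_noise(length(m), noise_cv)
  list(data = data.frame(time_h = times, mass_mg = m),
       truth = list(residual_fraction = residual_fraction,
                    evaporation_rate = evaporation_rate),
       seed = seed)
}

#' Generate a synthetic Franz-cell skin-absorption study
#'
#' Emulates the in vitro protocol that parameterizes the dermal model:
#' per-donor full-thickness skin (mean 907 um, SD 246 um, truncated at
#' +/- 2 SD; stratum corneum fixed, deeper layers scaled), finite dose of
#' 2 mg/cm^2 on 2 cm^2, 3 mL receptor sampled (300 uL replaced) at 15
#' timepoints over 24 h, and wash/termination arms at 4, 16 and 24 h, with
#' multiplicative log-normal measurement noise.
#'
#' @param chem a [chemical_properties()] record.
#' @param formulation a [formulation_spec()] record.
#' @param truth_params ground-truth [dermal_parameters()].
#' @param cell_config a [franz_cell_config()].
#' @param base_stack the mean-thickness [skin_stack()].
#' @param thickness_mean,thickness_sd full-thickness distribution across
#'   donors, um.
#' @param noise_cv measurement noise CV (fraction).
#' @param n_replicates number of donors.
#' @param seed integer seed (mandatory).
#' @param grid_spec Franz grid for the generating simulations.
#' @return list with `layer_data` (`replicate_id`, `time_h`, `compartment`,
#'   `amount_ug` at the wash times), `receptor_data` (`replicate_id`,
#'   `time_h`, `amount_ug` cumulative), `dataset` (a [franz_dataset()] of
#'   the replicate means, ready for fitting), `truth`, `seed`.
#' @export
gen_franz_dataset <- function(chem, formulation, truth_params,
                              cell_config = franz_cell_config(),
                              base_stack = skin_stack_invitro(),
                              thickness_mean = 907, thickness_sd = 246,
                              noise_cv = 0.2, n_replicates = 8, seed,
                              grid_spec = franz_grid(n_per_layer = 10,
                                                     rtol = 1e-6,
                                                     atol = 1e-8)) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  deep_ratio <- base_stack$thickness_de /
    (base_stack$thickness_ve + base_stack$thickness_de)

  draw_thickness <- function() {
    repeat {
      x <- stats::rnorm(1, thickness_mean, thickness_sd)
      if (abs(x - thickness_mean) <= 2 * thickness_sd &&
          x > base_stack$thickness_sc + 50) return(x)
    }
  }

  layer_rows <- list(); receptor_rows <- list()
  for (r in seq_len(n_replicates)) {
    tot <- if (n_replicates == 1 && noise_cv == 0) thickness_mean
           else draw_thickness()
    deep <- tot - base_stack$thickness_sc
    st <- skin_stack(base_stack$thickness_sc,
                     deep * (1 - deep_ratio), deep * deep_ratio,
                     area = cell_config$area)
    sim <- simulate_franz(chem, formulation, st, truth_params, cell_config,
                          grid_spec = grid_spec)
    la <- layer_amounts_at(sim, cell_config$wash_times)
    lw <- data.frame(
      replicate_id = r,
      time_h = rep(cell_config$wash_times, 3),
      compartment = rep(c("sc", "ve", "de"), each = length(cell_config$wash_times)),
      amount_ug = c(la[, "sc"], la[, "ve"], la[, "de"]))
    lw$amount_ug <- lw$amount_ug * .ln_noise(nrow(lw), noise_cv)
    rf <- stats::approx(sim$times, sim$receptor_cumulative,
                        xout = cell_config$sampling_times)$y
    rw <- data.frame(replicate_id = r, time_h = cell_config$sampling_times,
                     amount_ug = rf * .ln_noise(length(rf), noise_cv))
    layer_rows[[r]] <- lw; receptor_rows[[r]] <- rw
  }
  layer_data <- do.call(rbind, layer_rows)
  receptor_data <- do.call(rbind, receptor_rows)

  mean_layer <- stats::aggregate(amount_ug ~ time_h + compartment,
                                 data = layer_data, FUN = mean)
  mean_rf <- stats::aggregate(amount_ug ~ time_h, data = receptor_data,
                              FUN = mean)
  obs <- rbind(mean_layer[, c("compartment", "time_h", "amount_ug")],
               data.frame(compartment = "rf", time_h = mean_rf$time_h,
                          amount_ug = mean_rf$amount_ug))
  ds <- franz_dataset(formulation, base_stack, cell_config, obs,
                      truth_params)
  list(layer_data = layer_data, receptor_data = receptor_data,
       dataset = ds, truth = truth_params, seed = seed)
}

#' Generate clinical-like plasma profiles with inter-subject variability
#'
#' Samples per-subject chemical/dermal parameters log-normally around the
#' truth (median at truth), runs the full dermal + whole-body chain per
#' subject, and summarizes Cmax/AUC across subjects. Heavy-tailed
#' log-normal draws with large CVs reproduce the high inter-individual
#' variability (CV above 150%) seen in small clinical studies.
#'
#' @param chem a [chemical_properties()] record (truth).
#' @param dermal_params truth [dermal_parameters()].
#' @param formulation a [formulation_spec()].
#' @param stack in vivo [skin_stack()].
#' @param regimen a [dose_regimen()].
#' @param subject demographics list (`age`, `body_weight`, `sex`).
#' @param inter_subject_cv named CVs (fractions) over any of the dermal
#'   parameter fields and the chemical fields `rbp`, `fup`.
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed (mandatory).
#' @param t_cut AUC cutoff, h.
#' @param n_per_layer skin grid for the per-subject runs.
#' @return list with `profiles` (per subject), `metrics` (data.frame of
#'   per-subject `cmax`, `tmax`, `auc_0_t`), `summary` (mean, CV% per
#'   metric), `truth`, `seed`.
#' @export
gen_clinical_profiles <- function(chem, dermal_params, formulation, stack,
                                  regimen, subject,
                                  inter_subject_cv = c(k_vh_w = 0.5,
                                                       d_sc = 0.5,
                                                       rbp = 0.3),
                                  n_subjects = 12, seed, t_cut = 23,
                                  n_per_layer = 8) {
  stopifnot(n_subjects >= 2, !missing(seed))
  set.seed(as.integer(seed))
  par_names <- names(inter_subject_cv)
  sigma <- sqrt(log(1 + inter_subject_cv^2))
  z <- matrix(stats::rnorm(n_subjects * length(par_names)),
              nrow = n_subjects)
  profiles <- vector("list", n_subjects)
  mets <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ch <- chem; dp <- dermal_params
    for (j in seq_along(par_names)) {
      nm <- par_names[j]
      f <- exp(z[i, j] * sigma[j])
      if (nm %in% names(ch)) ch[[nm]] <- ch[[nm]] * f
      if (nm %in% names(dp)) dp[[nm]] <- dp[[nm]] * f
    }
    sp <- build_systemic_parameters(ch, subject$body_weight, subject$age,
                                    subject$sex, dermal_params = dp,
                                    stack = stack)
    pr <- simulate_plasma(ch, sp,
                          list(formulation = formulation, stack = stack,
                               dermal_params = dp,
                               n_per_layer = n_per_layer),
                          regimen)
    pk <- pk_metrics(pr, t_cut = min(t_cut, max(pr$times)))
    profiles[[i]] <- pr
    mets[[i]] <- data.frame(cmax = pk$cmax, tmax = pk$tmax,
                            auc_0_t = pk$auc_0_t)
  }
  metrics <- do.call(rbind, mets)
  summ <- data.frame(
    metric = names(metrics),
    mean = vapply(metrics, mean, numeric(1)),
    cv_pct = vapply(metrics, function(x)
      if (mean(x) != 0) 100 * stats::sd(x) / mean(x) else 0, numeric(1)))
  list(profiles = profiles, metrics = metrics, summary = summ,
       truth = list(chem = chem, dermal_params = dermal_params),
       seed = seed)
}
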