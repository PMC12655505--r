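#' Cumulative membrane permeation series (Fick's second law)
#'
#' Evaluates the classic lag-time solution for cumulative amount permeated
#' per unit area through a homogeneous membrane held between a constant
#' donor and a perfect-sink receptor:
#'
#' \deqn{Q(t) = m_1 \left( m_2 t - \frac{1}{6}
#'   - \frac{2}{\pi^2} \sum_{n=1}^{N} \frac{(-1)^n}{n^2}
#'   e^{-m_2 n^2 \pi^2 t} \right)}
#'
#' with \eqn{m_2 = D/L^2} (1/h) and \eqn{m_1 = C_d K L} (ug/cm^2), so that
#' the late-time slope \eqn{m_1 m_2 = C_d K D / L} is the steady-state flux
#' and the lag time is \eqn{1/(6 m_2) = L^2/6D}. At t = 0 the alternating
#' series sums to \eqn{-\pi^2/12} exactly and the bracket vanishes; the
#' function returns exactly 0 there rather than the truncated partial sum.
#'
#' @param m1 scale parameter (ug/cm^2), \eqn{C_d K L}.
#' @param m2 rate parameter (1/h), \eqn{D/L^2}.
#' @param t time(s), h (vectorized).
#' @param n_terms number of series terms (default 200). The alternating
#'   series tail is bounded by its first omitted term; a warning is issued
#'   if that bound exceeds `1e-9 * m1` at any requested t > 0.
#' @return cumulative permeated amount per area, ug/cm^2 (same length as t).
#' @export
qrf_series <- function(m1, m2, t, n_terms = 200) {
  stopifnot(m2 > 0, n_terms >= 1, all(t >= 0))
  n <- seq_len(n_terms)
  out <- vapply(t, function(ti) {
    if (ti == 0) return(0)
    s <- sum(((-1)^n / n^2) * exp(-m2 * n^2 * pi^2 * ti))
    m1 * (m2 * ti - 1 / 6 - (2 / pi^2) * s)
  }, numeric(1))
  tp <- t[t > 0]
  if (length(tp) > 0) {
    tail_bound <- abs(m1) * (2 / pi^2) / (n_terms + 1)^2 *
      exp(-m2 * (n_terms + 1)^2 * pi^2 * min(tp))
    if (tail_bound > 1e-9 * abs(m1))
      warning("series truncation tail bound ", format(tail_bound),
              " exceeds 1e-9 * m1; increase n_terms", call. = FALSE)
  }
  out
}

#' Fit the membrane series to an isolated-dermis permeation curve
#'
#' Least-squares estimation of (m1, m2) of [qrf_series()] from a cumulative
#' receptor curve measured on isolated dermis, followed by recovery of the
#' physical parameters: dermis diffusivity `d_de = m2 * L^2` and the
#' dermis/vehicle partition coefficient `k_de_veh = m1 / (C_d * L)` (from
#' the convention m1 = C_d K L of the lag-time solution).
#'
#' Starting values come from the late-time asymptote Q = m1*m2*t - m1/6: a
#' straight line through the second half of the curve gives the slope
#' (m1*m2) and intercept (-m1/6). The fit itself runs on log-parameters to
#' enforce positivity.
#'
#' @param times sampling times, h (>= 6 points spanning lag and linear phases).
#' @param qrf cumulative receptor amount per area, ug/cm^2.
#' @param stack a [skin_stack()] record; `thickness_de` is the membrane
#'   thickness L.
#' @param c_d applied (donor) concentration, ug/mL.
#' @param n_terms series truncation (>= 20).
#' @return object of class `dermis_fit`: list with `m1` (ug/cm^2), `m2`
#'   (1/h), `d_de` (cm^2/s), `k_de_veh`, `covariance` (2x2, on (m1, m2)),
#'   `n_terms`, `residuals`, `fitted`.
#' @export
fit_isolated_dermis <- function(times, qrf, stack, c_d, n_terms = 200) {
  stopifnot(length(times) == length(qrf), n_terms >= 20)
  if (length(times) < 6)
    stop("estimation-failure: need >= 6 timepoints", call. = FALSE)
  if (all(qrf <= 0) || stats::sd(qrf) == 0 || max(qrf) <= 0)
    stop("estimation-failure: flat or all-zero curve gives a non-identifiable fit",
         call. = FALSE)
  ord <- order(times)
  times <- times[ord]; qrf <- qrf[ord]

  late <- times >= stats::median(times)
  lf <- stats::lm(qrf[late] ~ times[late])
  slope <- unname(stats::coef(lf)[2])
  icept <- unname(stats::coef(lf)[1])
  m1_0 <- if (icept < 0) -6 * icept else max(qrf) / 2
  m2_0 <- if (slope > 0 && m1_0 > 0) slope / m1_0 else 1 / max(times)
  m1_0 <- max(m1_0, 1e-8); m2_0 <- max(m2_0, 1e-8)

  resid_fn <- function(p) {
    qrf - qrf_series(exp(p[1]), exp(p[2]), times, n_terms)
  }
  fit <- minpack.lm::nls.lm(par = log(c(m1_0, m2_0)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  m1 <- exp(fit$par[1]); m2 <- exp(fit$par[2])
  if (!is.finite(m1) || !is.finite(m2) || m2 <= 0)
    stop("estimation-failure: fit did not converge to positive parameters",
         call. = FALSE)

  # delta-method covariance on the natural scale from the log-scale hessian
  cov_log <- tryCatch({
    s2 <- fit$deviance / max(1, length(times) - 2)
    s2 * solve(fit$hessian)
  }, error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(m1, m2))
  covariance <- J %*% cov_log %*% J

  L_cm <- um_to_cm(stack$thickness_de)
  structure(list(
    m1 = m1, m2 = m2,
    d_de = cm2h_to_cm2s(m2 * L_cm^2),
    k_de_veh = m1 / (c_d * L_cm),
    covariance = covariance,
    n_terms = n_terms,
    residuals = resid_fn(fit$par),
    fitted = qrf - resid_fn(fit$par),
    times = times
  ), class = "dermis_fit")
}

#' @export
print.dermis_fit <- function(x, ...) {
  cat("<dermis_fit>\n")
  cat(sprintf("  m1 = %.6g ug/cm^2, m2 = %.6g 1/h\n", x$m1, x$m2))
  cat(sprintf("  d_de = %.4g cm^2/s, k_de_veh = %.4g\n", x$d_de, x$k_de_veh))
  cat(sprintf("  RMSE = %.4g ug/cm^2\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Evaporation time of a finite vehicle film
#'
#' Time for the applied vehicle volume to dry down to its residual fraction
#' at a constant volume-loss rate:
#' `evap_time = dose_volume * (1 - residual_fraction) / evaporation_rate`.
#'
#' @param dose_volume applied vehicle volume, mL.
#' @param residual_fraction fraction of volume remaining after dry-down.
#' @param evaporation_rate volume loss rate, mL/h.
#' @return evaporation time in h; 0 when nothing evaporates
#'   (`residual_fraction = 1`), `Inf` (with a warning) when the rate is 0
#'   but evaporation would be required.
#' @export
evaporation_time <- function(dose_volume, residual_fraction, evaporation_rate) {
  stopifnot(dose_volume >= 0, residual_fraction >= 0, residual_fraction <= 1,
            evaporation_rate >= 0)
  if (residual_fraction == 1 || dose_volume == 0) return(0)
  if (evaporation_rate == 0) {
    warning("evaporation_rate = 0 with residual_fraction < 1: ",
            "exposure never ends (Inf)", call. = FALSE)
    return(Inf)
  }
  dose_volume * (1 - residual_fraction) / evaporation_rate
}

#' Fit evaporation kinetics from a weight-loss curve
#'
#' Estimates the residual volume fraction and the (initial, linear-phase)
#' evaporation rate from the recorded mass of an applied formulation film.
#' The residual fraction is the plateau mass over the initial mass; the rate
#' is a robust (Theil-Sen) slope over the first 25% of the total mass loss,
#' converted from mg/h to mL/h through the density.
#'
#' @param times elapsed times, h (>= 5 points, ending in a plateau: last two
#'   masses within 1% of each other).
#' @param mass_mg recorded formulation mass, mg.
#' @param density formulation density, g/mL.
#' @return object of class `evaporation_fit`: list with `residual_fraction`,
#'   `evaporation_rate` (mL/h), `evap_time` (h), `initial_mass_mg`.
#' @export
fit_evaporation <- function(times, mass_mg, density = 1) {
  stopifnot(length(times) == length(mass_mg))
  if (length(times) < 5)
    stop("need >= 5 timepoints", call. = FALSE)
  ord <- order(times)
  times <- times[ord]; mass_mg <- mass_mg[ord]
  n <- length(mass_mg)
  m0 <- mass_mg[1]; mend <- mass_mg[n]
  if (m0 <= 0) stop("initial mass must be > 0", call. = FALSE)
  if (abs(mass_mg[n] - mass_mg[n - 1]) > 0.01 * abs(mass_mg[n - 1]) + 1e-12)
    stop("no-plateau: last two points differ by more than 1%", call. = FALSE)

  residual_fraction <- min(1, max(0, mend / m0))
  total_loss <- m0 - mend
  if (total_loss <= 0) {
    rate <- 0
  } else {
    early <- which((m0 - mass_mg) <= 0.25 * total_loss)
    if (length(early) < 2) early <- 1:2
    tt <- times[early]; mm <- mass_mg[early]
    pairs <- utils::combn(length(tt), 2)
    dt <- tt[pairs[2, ]] - tt[pairs[1, ]]
    keep <- dt > 0
    slopes <- (mm[pairs[2, ]][keep] - mm[pairs[1, ]][keep]) / dt[keep]
    slope <- stats::median(slopes)                 # mg/h, negative
    rate <- max(0, -slope) / (1000 * density)      # mL/h
  }
  dose_volume <- (m0 / 1000) / density
  structure(list(residual_fraction = residual_fraction,
                 evaporation_rate = rate,
                 evap_time = evaporation_time(dose_volume, residual_fraction, rate),
                 initial_mass_mg = m0),
            class = "evaporation_fit")
}

#' In silico (L1) dermal parameter set from physicochemical properties
#'
#' First-tier dermal parameters from published property correlations, used
#' when no in vitro skin data are available:
#'
#' * Stratum corneum: the Potts & Guy (1992, Pharm Res 9:663) permeability
#'   correlation `log10 kp[cm/h] = -2.7 + 0.71 logP - 0.0061 MW`, split into
#'   a partition term `K_sc/w = 10^(0.71 logP)` (lipophilicity-driven, cf.
#'   Cleek & Bunge 1995) and a diffusion term
#'   `D_sc/L_sc = 10^(-2.7 - 0.0061 MW) cm/h` (size-driven).
#' * Free aqueous diffusivity from the molecular-weight correlation
#'   `log10 D_aq[cm^2/s] = -4.15 - 0.655 log10 MW` (Kasting et al.).
#' * Viable epidermis and dermis: aqueous diffusivity reduced by fixed
#'   hindrance factors for viable tissue (Robinson-style treatment of the
#'   epidermis/dermis as a water-like gel; factors 3.9 and 5 respectively),
#'   with two-phase water/lipid partition coefficients
#'   `K_x/w = f_w + f_lip * 10^(0.7 logP)` using effective lipid fractions
#'   of 3.2% (viable epidermis) and 1% (dermis).
#' * Vehicle: aqueous diffusivity default 7.5e-6 cm^2/s; `k_vh_w` from the
#'   formulation (solute concentration over aqueous solubility) when one is
#'   supplied, else 1 (aqueous vehicle).
#'
#' @param chem a [chemical_properties()] record (`mw` and `logp` required).
#' @param stack a [skin_stack()] record (the stratum corneum thickness sets
#'   the D/L split).
#' @param formulation optional [formulation_spec()]; sets `k_vh_w` and the
#'   default application time (its evaporation time).
#' @param application_time exposure duration, h; defaults to the
#'   formulation's evaporation time, or 24 h without a formulation.
#' @return a [dermal_parameters()] record, with attribute
#'   `"applicability_warning"` when logP lies outside the correlation's
#'   stated domain (roughly -3 to 6).
#' @export
l1_insilico_dermal <- function(chem, stack, formulation = NULL,
                               application_time = NULL) {
  stopifnot(inherits(chem, "chemical_properties"),
            inherits(stack, "skin_stack"))
  mw <- chem$mw; logp <- chem$logp
  k_sc_w <- 10^(0.71 * logp)
  dl_sc <- 10^(-2.7 - 0.0061 * mw)                 # cm/h
  d_sc <- cm2h_to_cm2s(dl_sc * um_to_cm(stack$thickness_sc))
  d_aq <- 10^(-4.15 - 0.655 * log10(mw))           # cm^2/s
  lip_term <- 10^(0.7 * logp)
  k_ve_w <- 0.68 + 0.032 * lip_term
  k_de_w <- 0.68 + 0.010 * lip_term

  k_vh_w <- 1
  if (!is.null(formulation)) {
    k_vh_w <- formulation$solubility_in_vehicle / chem$sw
    if (is.null(application_time)) {
      dose_vol <- formulation$dose_per_area * stack$area / (1000 * formulation$density)
      application_time <- evaporation_time(dose_vol,
                                           formulation$residual_fraction,
                                           formulation$evaporation_rate)
      if (!is.finite(application_time)) application_time <- 24
    }
  }
  if (is.null(application_time)) application_time <- 24

  out <- dermal_parameters(
    d_vh = 7.5e-6, k_vh_w = k_vh_w,
    d_sc = d_sc, k_sc_w = k_sc_w,
    d_ve = d_aq / 3.9, k_ve_w = k_ve_w,
    d_de = d_aq / 5, k_de_w = k_de_w,
    application_time = application_time)
  if (logp < -3 || logp > 6)
    attr(out, "applicability_warning") <-
      sprintf("logP = %.2f outside the stated applicability of the permeability correlation (-3 to 6)", logp)
  out
}

#' Hepatic plasma clearance (non-restrictive well-stirred equation)
#'
#' `CL_liver = Q_liver * CLint_vivo * Rbp / (Q_liver + CLint_vivo)`. The
#' non-restrictive form (no unbound-fraction correction) is appropriate for
#' highly protein-bound solutes whose hepatic extraction is not limited by
#' plasma binding; the result is bounded above by `q_liver * rbp`.
#'
#' @param q_liver hepatic blood flow, L/h.
#' @param clint_vivo whole-liver in vivo intrinsic clearance, L/h.
#' @param rbp blood/plasma concentration ratio.
#' @return hepatic plasma clearance, L/h.
#' @export
hepatic_clearance <- function(q_liver, clint_vivo, rbp) {
  stopifnot(q_liver > 0, clint_vivo >= 0, rbp > 0)
  q_liver * clint_vivo * rbp / (q_liver + clint_vivo)
}

#' Scale in vitro intrinsic clearance to the whole liver
#'
#' `CLint_vivo [L/h] = clint_invitro [uL/min/mg] * mg protein per g liver *
#' liver mass [g]`, with the unit conversion uL/min -> L/h. The scaling
#' constants are configuration; the defaults (100 mg cellular protein per g
#' liver, 1650 g liver) are typical adult-human values from the IVIVE
#' literature.
#'
#' @param clint_invitro in vitro intrinsic clearance, uL/min/mg protein.
#' @param mg_protein_per_g protein scaling factor, mg/g liver.
#' @param liver_mass_g liver mass, g.
#' @return in vivo intrinsic clearance, L/h.
#' @export
scale_clint <- function(clint_invitro, mg_protein_per_g = 100,
                        liver_mass_g = 1650) {
  stopifnot(clint_invitro >= 0, mg_protein_per_g > 0, liver_mass_g > 0)
  ul_min_mg_to_l_h(clint_invitro) * mg_protein_per_g * liver_mass_g
}

#' Renal clearance from glomerular filtration
#'
#' For a solute cleared only by filtration (no renal transporters),
#' `CL_renal = fup * GFR`.
#'
#' @param fup fraction unbound in plasma.
#' @param gfr glomerular filtration rate, L/h.
#' @return renal plasma clearance, L/h.
#' @export
renal_clearance <- function(fup, gfr) {
  stopifnot(fup >= 0, fup <= 1, gfr > 0)
  fup * gfr
}

#' Intrinsic clearance from an in vitro depletion half-life
#'
#' `CLint = (ln 2 / t_half) * (incubation volume / protein)`, converting a
#' substrate-depletion half-life measured in an S9 or hepatocyte incubation
#' into an intrinsic clearance per mg protein.
#'
#' @param t_half depletion half-life, min.
#' @param incubation_volume incubation volume, uL.
#' @param protein protein in the incubation, mg.
#' @return intrinsic clearance, uL/min/mg protein.
#' @export
halflife_to_clint <- function(t_half, incubation_volume, protein) {
  stopifnot(t_half > 0, incubation_volume > 0, protein > 0)
  (log(2) / t_half) * (incubation_volume / protein)
}
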