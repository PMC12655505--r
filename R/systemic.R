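#' First-order systemic absorption rate from the dermis
#'
#' Default rule for the dermis-to-blood uptake rate constant: the leading
#' eigenmode decay rate of diffusive transport across a dermis slab with a
#' sealed upper face and an absorbing (capillary) lower face,
#' `ksys = (pi^2/4) * D_de / L_de^2`, optionally scaled by a user
#' capillary-uptake factor. This is a declared approximation to integrated
#' dermis-clearance models; the direct flux-coupling mode of
#' [simulate_plasma()] does not use it.
#'
#' @param dermal_params a [dermal_parameters()] record.
#' @param stack a [skin_stack()] record; `thickness_de` is the effective
#'   diffusion depth to the capillary plexus.
#' @param capillary_factor multiplicative adjustment (default 1).
#' @return rate constant, 1/h (always > 0).
#' @export
ksys_from_dermis <- function(dermal_params, stack, capillary_factor = 1) {
  stopifnot(inherits(dermal_params, "dermal_parameters"),
            inherits(stack, "skin_stack"), capillary_factor > 0)
  l_cm <- um_to_cm(stack$thickness_de)
  (pi^2 / 4) * cm2s_to_cm2h(dermal_params$d_de) / l_cm^2 * capillary_factor
}

#' Simulate plasma concentrations after topical application
#'
#' Whole-body perfusion-limited PBK model driven by the mechanistic dermal
#' model at the application site. All tissues are flow-limited; gut and
#' spleen drain through the liver (portal flow); elimination is hepatic
#' (non-restrictive well-stirred clearance in the liver compartment) plus
#' renal filtration (fup x GFR in the kidney compartment). Model states are
#' blood/tissue amounts; plasma concentration is venous blood concentration
#' divided by Rbp.
#'
#' Dermal coupling modes:
#' * `"flux"` (default): the basal boundary of the dermis grid drains into
#'   venous blood as a diffusive sink (capillary blood concentration is
#'   negligible against skin concentrations).
#' * `"ksys"`: the basal boundary is sealed and solute transfers to venous
#'   blood at a first-order rate `ksys` applied to the dermis amount.
#'
#' Each application event resets the vehicle film (amount, volume and
#' evaporation clock) without clearing the skin depots; solute stranded in
#' a dried-down film stays in the mass balance but can no longer penetrate.
#'
#' @param chem a [chemical_properties()] record.
#' @param systemic_params a [systemic_parameters()] record (see
#'   [build_systemic_parameters()]).
#' @param dermal_input list with `formulation` ([formulation_spec()]),
#'   `stack` (in vivo [skin_stack()]), `dermal_params`
#'   ([dermal_parameters()]), optional `mode` (`"flux"` or `"ksys"`) and
#'   `n_per_layer` (default 10).
#' @param regimen a [dose_regimen()] record.
#' @param times output times, h (default 0 to last event + 24 h, step 0.1).
#' @param clint_hepatic whole-liver in vivo intrinsic clearance, L/h
#'   (scaled from the chemical's in vitro value when NULL). Hepatic
#'   elimination proceeds at `clint_hepatic` times the liver venous blood
#'   concentration, so the emergent whole-body hepatic plasma clearance is
#'   exactly the non-restrictive well-stirred value of
#'   [hepatic_clearance()]; passing that lumped value here instead would
#'   apply the flow limitation twice.
#' @param cl_renal renal plasma clearance, L/h (fup x GFR when NULL),
#'   applied to kidney venous plasma.
#' @param iv_bolus_ug optional bolus into venous blood at t = 0 (used for
#'   analytic cross-checks).
#' @param extend_to_steady_state repeat the final-day application pattern
#'   until the daily Cmax changes by < 1% (capped at `max_days`).
#' @param max_days horizon cap for the steady-state extension.
#' @param rtol,atol solver tolerances.
#' @return object of class `plasma_profile`: `times` (h), `concentration`
#'   (ug/mL plasma), `amounts` (matrix of compartment amounts, ug),
#'   `mass_balance`, `absorbed_ug` (cumulative systemic input),
#'   `dose_regimen`, `subject`, `clearances`.
#' @export
simulate_plasma <- function(chem, systemic_params, dermal_input, regimen,
                            times = NULL, clint_hepatic = NULL,
                            cl_renal = NULL, iv_bolus_ug = 0,
                            extend_to_steady_state = FALSE, max_days = 14,
                            rtol = 1e-7, atol = 1e-4) {
  stopifnot(inherits(chem, "chemical_properties"),
            inherits(systemic_params, "systemic_parameters"),
            inherits(regimen, "dose_regimen"))
  sp <- systemic_params
  ts <- sp$tissue_set
  ev <- regimen$events

  if (isTRUE(extend_to_steady_state) && nrow(ev) > 0) {
    t_last <- max(ev$time_h)
    day <- ev[ev$time_h > t_last - 24, , drop = FALSE]
    add <- do.call(rbind, lapply(seq_len(max_days), function(d) {
      x <- day; x$time_h <- x$time_h + 24 * d; x
    }))
    ev <- rbind(ev, add)
  }

  if (is.null(clint_hepatic)) {
    liver_g <- 1650 * sp$body_weight / 70
    clint_hepatic <- scale_clint(chem$clint_hep, liver_mass_g = liver_g)
  }
  if (is.null(cl_renal)) cl_renal <- renal_clearance(chem$fup, sp$gfr)
  cl_hepatic_ws <- hepatic_clearance(sp$q_liver, clint_hepatic, chem$rbp)

  if (is.null(dermal_input)) {
    if (nrow(ev) > 0)
      stop("dermal_input is required when the regimen has application events",
           call. = FALSE)
    dermal_input <- list(
      formulation = formulation_spec("none", 0.5, "solution", 2, 1, 1, 0),
      stack = skin_stack(10, 10, 10, area = 1),
      dermal_params = dermal_parameters(1e-6, 1, 1e-9, 1, 1e-7, 1, 1e-7, 1, 1))
  }
  mode <- dermal_input$mode %||% "flux"
  n_per <- dermal_input$n_per_layer %||% 10
  form <- dermal_input$formulation
  stack <- dermal_input$stack
  dp <- dermal_input$dermal_params

  have_dermal <- nrow(ev) > 0
  area <- if (have_dermal) ev$area_cm2[1] else 0
  if (have_dermal && length(unique(ev$area_cm2)) > 1)
    stop("all application events must use the same area", call. = FALSE)

  # skin grid (activity formulation, as in the Franz engine)
  layers <- data.frame(
    name = c("sc", "ve", "de"),
    d_cm2h = cm2s_to_cm2h(c(dp$d_sc, dp$d_ve, dp$d_de)),
    k = c(dp$k_sc_w, dp$k_ve_w, dp$k_de_w),
    l_cm = um_to_cm(c(stack$thickness_sc, stack$thickness_ve,
                      stack$thickness_de)),
    n = rep(n_per, 3))
  nc <- sum(layers$n)
  h <- rep(layers$l_cm / layers$n, layers$n)
  dk <- rep(layers$d_cm2h * layers$k, layers$n)
  kk <- rep(layers$k, layers$n)
  g_int <- 1 / (h[-nc] / (2 * dk[-nc]) + h[-1] / (2 * dk[-1]))
  g0 <- 1 / (h[1] / (2 * dk[1]))
  gN <- 1 / (h[nc] / (2 * dk[nc]))
  idx_de <- (layers$n[1] + layers$n[2] + 1):nc

  s_ug_ml <- form$solubility_in_vehicle * 1000
  evap_rate <- if (isTRUE(regimen$occlusive)) 0 else
    form$evaporation_rate * area / form$measured_area
  app_time <- dp$application_time
  ksys <- sp$ksys

  ntis <- nrow(ts)
  il <- which(ts$tissue == "lung")
  ili <- which(ts$tissue == "liver")
  igu <- which(ts$tissue == "gut")
  isp <- which(ts$tissue == "spleen")
  iki <- which(ts$tissue == "kidney")
  if (any(lengths(list(il, ili, igu, isp, iki)) != 1))
    stop("tissue_set must contain lung, liver, gut, spleen, kidney",
         call. = FALSE)
  into_ven <- setdiff(seq_len(ntis), c(il, ili, igu, isp))
  bv <- attr(sp, "blood_volume_l")
  if (is.null(bv)) bv <- c(arterial = 1.7, venous = 3.5) * sp$body_weight / 70
  co <- attr(sp, "cardiac_output_l_h")
  if (is.null(co)) co <- ts$flow_l_h[il]
  q_li_tot <- ts$flow_l_h[ili] + ts$flow_l_h[igu] + ts$flow_l_h[isp]
  rbp <- chem$rbp

  # state layout
  i_avh <- 1; i_vvh <- 2; i_vres <- 3; i_tapp <- 4; i_strand <- 5
  i_skin <- 5 + seq_len(nc)
  i_tis <- 5 + nc + seq_len(ntis)
  i_art <- 5 + nc + ntis + 1
  i_ven <- i_art + 1
  i_eh <- i_ven + 1
  i_er <- i_eh + 1
  i_abs <- i_er + 1
  nstate <- i_abs

  derivs <- function(t, y, p) {
    dy <- numeric(nstate)
    # --- dermis/skin ---
    if (have_dermal) {
      a_vh <- y[i_avh]; v_vh <- y[i_vvh]; v_res <- y[i_vres]
      conc <- y[i_skin]; u <- conc / kk
      c_dis <- if (v_vh > 0) max(min(a_vh / v_vh, s_ug_ml), 0) else 0
      j0 <- if (y[i_tapp] < app_time) g0 * (c_dis / dp$k_vh_w - u[1]) else 0
      if (mode == "flux") {
        jN <- gN * u[nc]
        skin_in <- jN * area
        sink_de <- numeric(nc)
      } else {
        jN <- 0
        sink_de <- numeric(nc)
        sink_de[idx_de] <- ksys * conc[idx_de]
        skin_in <- sum(sink_de[idx_de] * h[idx_de]) * area
      }
      j_edges <- c(j0, g_int * (u[-nc] - u[-1]), jN)
      dy[i_skin] <- (j_edges[-(nc + 1)] - j_edges[-1]) / h - sink_de
      dy[i_avh] <- -j0 * area
      dy[i_vvh] <- if (v_vh > v_res) -evap_rate else 0
      dy[i_tapp] <- 1
    } else skin_in <- 0
    # --- circulation (amounts ug, volumes L, conc ug/L) ---
    a_t <- y[i_tis]
    cv <- (a_t / ts$volume_l) * rbp / ts$kp
    c_art <- y[i_art] / bv[["arterial"]]
    c_ven <- y[i_ven] / bv[["venous"]]
    q <- ts$flow_l_h
    d_t <- q * (c_art - cv)
    d_t[il] <- co * (c_ven - cv[il])
    d_t[ili] <- q[ili] * c_art + q[igu] * cv[igu] + q[isp] * cv[isp] -
      q_li_tot * cv[ili] - clint_hepatic * cv[ili]
    d_t[iki] <- q[iki] * (c_art - cv[iki]) - cl_renal * cv[iki] / rbp
    dy[i_tis] <- d_t
    dy[i_art] <- co * cv[il] - sum(q[-il]) * c_art
    dy[i_ven] <- sum(q[into_ven] * cv[into_ven]) + q_li_tot * cv[ili] -
      co * c_ven + skin_in
    dy[i_eh] <- clint_hepatic * cv[ili]
    dy[i_er] <- cl_renal * cv[iki] / rbp
    dy[i_abs] <- skin_in
    list(dy)
  }

  t_end <- if (nrow(ev) > 0) max(ev$time_h) + 24 else 24
  if (is.null(times)) times <- seq(0, t_end, by = 0.1)

  y0 <- numeric(nstate)
  y0[i_vvh] <- 1e-9   # avoid 0/0 before the first application
  y0[i_tapp] <- 1e6   # exposure clock: "long past" until an event resets it
  y0[i_ven] <- iv_bolus_ug

  ev_use <- ev[ev$time_h <= max(times), , drop = FALSE]
  events <- NULL
  brk <- numeric(0)
  if (nrow(ev_use) > 0) {
    evf <- function(t, y, p) {
      row <- ev_use[abs(ev_use$time_h - t) < 1e-9, , drop = FALSE][1, ]
      y[i_strand] <- y[i_strand] + y[i_avh]
      y[i_avh] <- row$mass_mg * form$active_fraction * 1000
      y[i_vvh] <- row$volume_ml
      y[i_vres] <- row$volume_ml * form$residual_fraction
      y[i_tapp] <- 0
      y
    }
    events <- list(func = evf, time = unique(ev_use$time_h))
    evt <- evaporation_time(ev_use$volume_ml[1], form$residual_fraction,
                            evap_rate)
    brk <- as.vector(outer(ev_use$time_h,
                           c(if (is.finite(evt)) evt, app_time), `+`))
  }
  out_times <- sort(unique(c(times, ev_use$time_h,
                             brk[is.finite(brk) & brk <= max(times)])))
  sol <- deSolve::ode(y = y0, times = out_times, func = derivs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events, maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff-solver failure; try looser rtol/atol or a coarser skin grid",
         call. = FALSE)
  keep <- match(sort(unique(times)), sol[, 1])
  sol <- sol[keep, , drop = FALSE]
  tt <- sol[, 1]
  y <- sol[, -1, drop = FALSE]

  if (min(y[, i_tis]) < -atol * 100)
    stop("negative tissue amounts: solver accuracy insufficient", call. = FALSE)

  skin_amt <- as.numeric(y[, i_skin, drop = FALSE] %*% h) * area
  # the solver reports the pre-event state at an event instant, so an
  # application at time t counts as applied only for output times > t
  dose_applied <- vapply(tt, function(t)
    sum(ev_use$mass_mg[ev_use$time_h < t - 1e-9]) *
      form$active_fraction * 1000,
    numeric(1))
  dose_applied <- dose_applied + iv_bolus_ug
  total <- y[, i_avh] + y[, i_strand] + skin_amt +
    rowSums(y[, i_tis, drop = FALSE]) + y[, i_art] + y[, i_ven] +
    y[, i_eh] + y[, i_er]
  mass_balance <- ifelse(dose_applied > 0, total / dose_applied, 1)

  conc_plasma <- (y[, i_ven] / bv[["venous"]]) / 1000 / rbp  # ug/mL plasma

  amounts <- cbind(vehicle = y[, i_avh], stranded = y[, i_strand],
                   skin = skin_amt,
                   y[, i_tis, drop = FALSE],
                   arterial = y[, i_art], venous = y[, i_ven],
                   eliminated_hepatic = y[, i_eh],
                   eliminated_renal = y[, i_er])
  colnames(amounts)[3 + seq_len(ntis)] <- ts$tissue

  structure(list(times = tt, concentration = conc_plasma,
                 amounts = amounts, mass_balance = mass_balance,
                 absorbed_ug = y[, i_abs],
                 dose_regimen = regimen,
                 subject = list(body_weight = sp$body_weight, age = sp$age,
                                sex = sp$sex),
                 clearances = c(hepatic = cl_hepatic_ws, renal = cl_renal,
                                clint_hepatic = clint_hepatic),
                 mode = mode),
            class = "plasma_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plasma_profile <- function(x, ...) {
  i <- which.max(x$concentration)
  cat("<plasma_profile> ", length(x$times), " times to ",
      format(max(x$times)), " h (", x$mode, " coupling)\n", sep = "")
  cat(sprintf("  Cmax %.4g ug/mL at %.3g h; absorbed %.4g ug\n",
              x$concentration[i], x$times[i], max(x$absorbed_ug)))
  invisible(x)
}
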