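#' Franz diffusion-cell configuration
#'
#' Geometry and sampling design of a static Franz cell. Defaults reproduce a
#' standard finite-dose protocol: 2 mg formulation per cm^2 on 2 cm^2 of
#' skin, 3 mL stirred receptor with 300 uL replaced at each of 15 sampling
#' times over 24 h, and wash/termination arms at 4, 16 and 24 h.
#'
#' @param receptor_volume receptor fluid volume, mL.
#' @param replacement_volume volume replaced with fresh buffer at each
#'   sampling time, mL (must not exceed `receptor_volume`).
#' @param sampling_times receptor sampling times, h (strictly increasing).
#' @param wash_times times at which cells are terminated and layer amounts
#'   measured, h.
#' @param dose_per_area applied formulation mass per area, mg/cm^2 (`NULL`
#'   to take the formulation's own value).
#' @param area exposed skin area, cm^2.
#' @param occlusive logical; occlusion suppresses vehicle evaporation.
#' @return a `franz_cell_config` record.
#' @export
franz_cell_config <- function(receptor_volume = 3, replacement_volume = 0.3,
                              sampling_times = c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5,
                                                 6, 8, 10, 12, 16, 20, 24),
                              wash_times = c(4, 16, 24),
                              dose_per_area = NULL, area = 2,
                              occlusive = FALSE) {
  stopifnot(replacement_volume >= 0, replacement_volume <= receptor_volume,
            all(diff(sampling_times) > 0), area > 0)
  structure(list(receptor_volume = receptor_volume,
                 replacement_volume = replacement_volume,
                 sampling_times = sampling_times,
                 wash_times = wash_times,
                 dose_per_area = dose_per_area, area = area,
                 occlusive = occlusive),
            class = c("franz_cell_config", "pbk_record", "list"))
}

#' Spatial grid and solver tolerances for the skin PDE
#'
#' @param n_per_layer finite-volume cells per skin layer (>= 10 recommended;
#'   the stratum corneum is thin and stiff against the dermis, so cells are
#'   allocated per layer, not per unit length).
#' @param rtol,atol relative/absolute solver tolerances passed to the stiff
#'   integrator.
#' @return a list used as `grid_spec` by [simulate_franz()].
#' @export
franz_grid <- function(n_per_layer = 20, rtol = 1e-8, atol = 1e-8) {
  list(n_per_layer = n_per_layer, rtol = rtol, atol = atol)
}

# ---------------------------------------------------------------------------
# Internal finite-volume engine for 1-D partition-coupled diffusion through
# a stack of homogeneous layers. Works in "activity" variables u = C / K_x/w
# (water-referenced), which are continuous across interfaces; fluxes between
# adjacent cells use two half-cell resistances so the same expression covers
# intra-layer edges and layer interfaces.
#
# layers: data.frame(name, d_cm2h, k, l_cm, n)
# donor:  list(mode = "finite" | "constant",
#              for finite: amount0_ug, v0_ml, s_ug_ml, evap_rate_ml_h,
#                          residual_fraction, k, app_time_h
#              for constant: conc_ug_ml, k)
# receptor: list(mode = "finite" | "sink", v_ml, k, v_repl_ml, sample_times)
.skin_pde <- function(layers, donor, receptor, area, times,
                      rtol = 1e-8, atol = 1e-8) {
  n_cells <- sum(layers$n)
  h <- rep(layers$l_cm / layers$n, layers$n)       # cell widths, cm
  dk <- rep(layers$d_cm2h * layers$k, layers$n)    # conductance numerators
  kk <- rep(layers$k, layers$n)

  # edge conductances between consecutive cells (length n_cells - 1)
  g_int <- 1 / (h[-n_cells] / (2 * dk[-n_cells]) + h[-1] / (2 * dk[-1]))
  g0 <- 1 / (h[1] / (2 * dk[1]))                   # surface half-cell
  gN <- 1 / (h[n_cells] / (2 * dk[n_cells]))       # basal half-cell

  i_cells <- 1 + seq_len(n_cells)                  # y[1] = donor amount
  i_rf <- n_cells + 2
  i_rem <- n_cells + 3

  finite_donor <- identical(donor$mode, "finite")
  finite_rf <- identical(receptor$mode, "finite")

  v_res <- if (finite_donor) donor$v0_ml * donor$residual_fraction else NA

  derivs <- function(t, y, p) {
    a_vh <- y[1]
    conc <- y[i_cells]
    u <- conc / kk

    if (finite_donor) {
      v <- max(donor$v0_ml - donor$evap_rate_ml_h * t, v_res)
      c_dis <- if (v > 0) min(a_vh / v, donor$s_ug_ml) else 0
      c_dis <- max(c_dis, 0)
      u_d <- c_dis / donor$k
      j0 <- if (t < donor$app_time_h) g0 * (u_d - u[1]) else 0
    } else {
      j0 <- g0 * (donor$conc_ug_ml / donor$k - u[1])
    }

    u_r <- if (finite_rf) (y[i_rf] / receptor$v_ml) / receptor$k else 0
    jN <- gN * (u[n_cells] - u_r)

    j_edges <- c(j0, g_int * (u[-n_cells] - u[-1]), jN)
    dconc <- (j_edges[-(n_cells + 1)] - j_edges[-1]) / h

    list(c(-j0 * area, dconc, jN * area, 0))
  }

  ev_times <- numeric(0)
  events <- NULL
  if (finite_rf && receptor$v_repl_ml > 0 && length(receptor$sample_times)) {
    ev_times <- receptor$sample_times
    frac <- receptor$v_repl_ml / receptor$v_ml
    evf <- function(t, y, p) {
      removed <- y[i_rf] * frac
      y[i_rf] <- y[i_rf] - removed
      y[i_rem] <- y[i_rem] + removed
      y
    }
    events <- list(func = evf, time = ev_times)
  }

  brk <- numeric(0)
  if (finite_donor) {
    brk <- c(brk, donor$app_time_h)
    if (donor$evap_rate_ml_h > 0)
      brk <- c(brk, (donor$v0_ml - v_res) / donor$evap_rate_ml_h)
  }
  out_times <- sort(unique(c(0, times, ev_times, brk[is.finite(brk) &
                                                    brk <= max(times) & brk >= min(times)])))

  y0 <- c(if (finite_donor) donor$amount0_ug else 0,
          rep(0, n_cells), 0, 0)
  sol <- deSolve::ode(y = y0, times = out_times, func = derivs, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 1, banddown = 1,
                      rtol = rtol, atol = atol,
                      events = events, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("solver-failure: stiff integrator did not complete; ",
         "try a finer grid or looser tolerances", call. = FALSE)
  keep <- match(sort(unique(times)), sol[, 1])
  sol <- sol[keep, , drop = FALSE]

  conc <- sol[, 1 + i_cells, drop = FALSE]
  neg <- min(conc)
  scale_ref <- max(abs(conc), 1e-12)
  if (neg < -1e-6 * scale_ref)
    stop("solver-failure: negative concentrations (", format(neg),
         "); refine the grid or tolerances", call. = FALSE)
  conc[conc < 0] <- 0

  list(times = sol[, 1],
       donor_amount = pmax(sol[, 2], 0),
       conc = conc,               # matrix time x cells (ug/cm^3)
       a_rf = pmax(sol[, 1 + i_rf], 0),
       a_removed = sol[, 1 + i_rem],
       h = h, layers = layers, area = area)
}

# ---------------------------------------------------------------------------

#' Simulate finite-dose skin absorption in a Franz cell
#'
#' Method-of-lines solution of 1-D partition-coupled diffusion through the
#' stratum corneum, viable epidermis and dermis, fed by a well-mixed,
#' evaporating vehicle film and draining into a well-mixed, periodically
#' sampled receptor compartment.
#'
#' Model assumptions:
#' * Interfaces impose flux continuity and continuity of water-referenced
#'   activity `C_a / K_a/w = C_b / K_b/w`.
#' * The vehicle is well mixed; its volume shrinks linearly at the
#'   (area-scaled) evaporation rate down to the residual fraction. Solute is
#'   conserved: the dissolved concentration rises as volume is lost, capped
#'   at the vehicle solubility with the excess held as an undissolved depot.
#' * At the exposure (application) time - by default the evaporation time -
#'   the vehicle-to-skin flux is switched off and whatever solute remains in
#'   the vehicle is stranded there (counted in the mass balance, excluded
#'   from absorption).
#' * The receptor is a finite well-mixed compartment, not a perfect sink;
#'   each sampling replaces `replacement_volume` of receptor fluid with
#'   fresh buffer, diluting the concentration accordingly.
#'
#' @param chem a [chemical_properties()] record.
#' @param formulation a [formulation_spec()] record.
#' @param stack a [skin_stack()] record (in vitro thicknesses).
#' @param dermal_params a [dermal_parameters()] record.
#' @param cell_config a [franz_cell_config()] record.
#' @param grid_spec a [franz_grid()] list.
#' @param times output times, h (default: dense 0-24 h grid united with the
#'   sampling and wash times).
#' @return object of class `franz_result`: list with `times`, per-layer
#'   spatial profiles (`layer_profiles`, one time-by-node matrix per layer),
#'   `layer_amounts` (ug in SC/VE/DE over time), `vehicle_amount` (ug,
#'   dissolved + depot), `receptor_cumulative` (sampling-corrected ug),
#'   `receptor_conc` (ug/mL in the chamber), `mass_balance` (recovered
#'   fraction over time), `dose_ug`, and the configuration used.
#' @export
simulate_franz <- function(chem, formulation, stack, dermal_params,
                           cell_config = franz_cell_config(),
                           grid_spec = franz_grid(), times = NULL) {
  stopifnot(inherits(chem, "chemical_properties"),
            inherits(formulation, "formulation_spec"),
            inherits(stack, "skin_stack"),
            inherits(dermal_params, "dermal_parameters"))
  dpa <- cell_config$dose_per_area
  if (is.null(dpa)) dpa <- formulation$dose_per_area
  area <- cell_config$area

  form_mass_mg <- dpa * area
  dose_ug <- form_mass_mg * formulation$active_fraction * 1000
  v0 <- form_mass_mg / (1000 * formulation$density)          # mL
  evap_rate <- if (cell_config$occlusive) 0 else
    formulation$evaporation_rate * area / formulation$measured_area

  t_end <- max(cell_config$sampling_times, cell_config$wash_times, 24)
  if (is.null(times))
    times <- sort(unique(c(seq(0, t_end, by = 0.1),
                           cell_config$sampling_times,
                           cell_config$wash_times)))

  layers <- data.frame(
    name = c("sc", "ve", "de"),
    d_cm2h = cm2s_to_cm2h(c(dermal_params$d_sc, dermal_params$d_ve,
                            dermal_params$d_de)),
    k = c(dermal_params$k_sc_w, dermal_params$k_ve_w, dermal_params$k_de_w),
    l_cm = um_to_cm(c(stack$thickness_sc, stack$thickness_ve,
                      stack$thickness_de)),
    n = rep(grid_spec$n_per_layer, 3))

  donor <- list(mode = "finite", amount0_ug = dose_ug, v0_ml = v0,
                s_ug_ml = formulation$solubility_in_vehicle * 1000,
                evap_rate_ml_h = evap_rate,
                residual_fraction = formulation$residual_fraction,
                k = dermal_params$k_vh_w,
                app_time_h = dermal_params$application_time)
  receptor <- list(mode = "finite", v_ml = cell_config$receptor_volume, k = 1,
                   v_repl_ml = cell_config$replacement_volume,
                   sample_times = cell_config$sampling_times)

  sol <- .skin_pde(layers, donor, receptor, area, times,
                   rtol = grid_spec$rtol, atol = grid_spec$atol)

  idx <- split(seq_len(sum(layers$n)), rep(seq_len(3), layers$n))
  layer_profiles <- lapply(idx, function(i) sol$conc[, i, drop = FALSE])
  names(layer_profiles) <- layers$name
  layer_amounts <- vapply(seq_len(3), function(l) {
    hs <- sol$h[idx[[l]]]
    as.numeric(sol$conc[, idx[[l]], drop = FALSE] %*% hs) * area
  }, numeric(length(sol$times)))
  if (is.null(dim(layer_amounts)))
    layer_amounts <- matrix(layer_amounts, nrow = 1)
  colnames(layer_amounts) <- c("sc", "ve", "de")

  receptor_cumulative <- sol$a_rf + sol$a_removed
  total <- sol$donor_amount + rowSums(layer_amounts) + receptor_cumulative
  mass_balance <- if (dose_ug > 0) total / dose_ug else rep(1, length(total))
  if (dose_ug > 0 && any(abs(mass_balance - 1) > 0.005))
    stop("accuracy: mass-balance drift ",
         format(max(abs(mass_balance - 1))),
         " exceeds 0.5%; use a finer grid or tighter tolerances",
         call. = FALSE)

  structure(list(times = sol$times,
                 vehicle_amount = sol$donor_amount,
                 layer_profiles = layer_profiles,
                 layer_amounts = layer_amounts,
                 receptor_cumulative = receptor_cumulative,
                 receptor_conc = sol$a_rf / cell_config$receptor_volume,
                 mass_balance = mass_balance,
                 dose_ug = dose_ug,
                 stack = stack, cell_config = cell_config,
                 dermal_params = dermal_params, grid = sol$h),
            class = "franz_result")
}

#' @export
print.franz_result <- function(x, ...) {
  tend <- max(x$times)
  i <- length(x$times)
  cat("<franz_result> ", length(x$times), " times over ",
      format(tend), " h, dose ", format(x$dose_ug), " ug\n", sep = "")
  cat(sprintf("  at %g h: SC %.3g, VE %.3g, DE %.3g, receptor %.3g ug (%.1f%% of dose)\n",
              tend, x$layer_amounts[i, "sc"], x$layer_amounts[i, "ve"],
              x$layer_amounts[i, "de"], x$receptor_cumulative[i],
              if (x$dose_ug > 0) 100 * x$receptor_cumulative[i] / x$dose_ug else 0))
  cat(sprintf("  mass balance within [%.4f, %.4f]\n",
              min(x$mass_balance), max(x$mass_balance)))
  invisible(x)
}

#' Reconstruct cumulative permeated amount from sampled receptor concentrations
#'
#' With a receptor of volume V sampled by replacing a volume v with fresh
#' buffer after each measurement, the cumulative amount that has permeated
#' by sample k is `V * C(t_k) + sum_{j<k} v * C(t_j)`.
#'
#' @param conc measured receptor concentrations at the sampling times,
#'   ug/mL (in sampling order).
#' @param cell_config a [franz_cell_config()] (uses `receptor_volume` and
#'   `replacement_volume`).
#' @return cumulative permeated amount, ug, per sampling time.
#' @export
receptor_bookkeeping <- function(conc, cell_config = franz_cell_config()) {
  v <- cell_config$receptor_volume
  vr <- cell_config$replacement_volume
  v * conc + vr * c(0, cumsum(conc)[-length(conc)])
}

#' Per-layer amounts at selected times
#'
#' Linear-in-time interpolation of the spatially integrated layer amounts of
#' a [simulate_franz()] result. Since termination (wash) arms carry no
#' feedback into the simulation, evaluating one continuous run at the wash
#' times is identical to running separate cells truncated there.
#'
#' @param result a `franz_result`.
#' @param times times, h (must lie within the simulated range).
#' @return matrix (length(times) x 3) of amounts in SC, VE, DE, ug.
#' @export
layer_amounts_at <- function(result, times) {
  stopifnot(inherits(result, "franz_result"))
  if (any(times < min(result$times) - 1e-9) ||
      any(times > max(result$times) + 1e-9))
    stop("range: requested times outside the simulated range", call. = FALSE)
  out <- vapply(c("sc", "ve", "de"), function(l)
    stats::approx(result$times, result$layer_amounts[, l], xout = times,
                  rule = 2)$y, numeric(length(times)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, c("sc", "ve", "de")))
  out
}

#' Simulate a single homogeneous membrane (analytic-check configuration)
#'
#' Constant donor concentration, perfect-sink receptor, one membrane. This
#' is the configuration for which [qrf_series()] is the exact solution with
#' `m2 = D/L^2` and `m1 = C_d K L`; it exists so the finite-volume engine
#' can be checked against the closed form.
#'
#' @param d diffusivity, cm^2/s.
#' @param k membrane/water partition coefficient.
#' @param l_um membrane thickness, um.
#' @param c_d donor concentration (water phase), ug/mL.
#' @param times output times, h.
#' @param n number of finite-volume cells.
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time_h` and `q_ug_cm2` (cumulative amount per
#'   area through the basal face).
#' @export
simulate_membrane <- function(d, k, l_um, c_d, times, n = 40,
                              rtol = 1e-10, atol = 1e-12) {
  layers <- data.frame(name = "m", d_cm2h = cm2s_to_cm2h(d), k = k,
                       l_cm = um_to_cm(l_um), n = n)
  donor <- list(mode = "constant", conc_ug_ml = c_d, k = 1)
  receptor <- list(mode = "sink", v_repl_ml = 0, sample_times = numeric(0))
  sol <- .skin_pde(layers, donor, receptor, area = 1, times = times,
                   rtol = rtol, atol = atol)
  data.frame(time_h = sol$times, q_ug_cm2 = sol$a_rf)
}
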