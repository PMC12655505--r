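#' Objective specification for dermal-parameter refinement
#'
#' The error term is a weighted sum of squared differences between observed
#' (Y) and predicted (Y~) compartment amounts over every observed
#' (compartment, time) pair, with a relative weighting of one of three
#' kinds: `inv_y2` (1/Y^2), `inv_yhat2` (1/Y~^2) or `inv_y_plus_yhat2`
#' (1/(Y + Y~)^2), optionally combined with per-compartment weights
#' (stratum corneum, viable epidermis, dermis, receptor fluid; default all
#' 1).
#'
#' @param kind one of `"inv_y2"`, `"inv_yhat2"`, `"inv_y_plus_yhat2"`.
#' @param weights named non-negative weights for compartments
#'   `sc`, `ve`, `de`, `rf` (at least one positive).
#' @return an `objective_spec` record.
#' @export
objective_spec <- function(kind = c("inv_y_plus_yhat2", "inv_y2", "inv_yhat2"),
                           weights = c(sc = 1, ve = 1, de = 1, rf = 1)) {
  kind <- match.arg(kind)
  stopifnot(all(weights >= 0), any(weights > 0),
            all(c("sc", "ve", "de", "rf") %in% names(weights)))
  structure(list(kind = kind, weights = weights),
            class = c("objective_spec", "pbk_record", "list"))
}

#' Evaluate the refinement objective
#'
#' `sum_i w_comp(i) * (Y_i - Y~_i)^2 * w_kind(Y_i, Y~_i)`; pairs with
#' Y = Y~ = 0 contribute zero; the objective is zero iff the fit is
#' perfect on all weighted pairs.
#'
#' @param observed,predicted data.frames with columns `compartment` (one of
#'   sc/ve/de/rf), `time_h`, `amount_ug`, matched on (compartment, time).
#' @param spec an [objective_spec()].
#' @return non-negative scalar.
#' @export
objective <- function(observed, predicted, spec = objective_spec()) {
  r <- objective_residuals(observed, predicted, spec)
  sum(r^2)
}

# weighted residual vector sqrt(w) * (Y - Yhat); shared by objective() and
# the least-squares fitters
objective_residuals <- function(observed, predicted, spec) {
  key_o <- paste(observed$compartment, signif(observed$time_h, 10))
  key_p <- paste(predicted$compartment, signif(predicted$time_h, 10))
  m <- match(key_o, key_p)
  if (anyNA(m))
    stop("observation/prediction index sets do not match", call. = FALSE)
  y <- observed$amount_ug
  yh <- predicted$amount_ug[m]
  wc <- spec$weights[as.character(observed$compartment)]
  both_zero <- (y == 0 & yh == 0)
  wk <- switch(spec$kind,
    inv_y2 = {
      if (any(y == 0 & !both_zero))
        stop("undefined-weight: objective kind inv_y2 with observed Y = 0",
             call. = FALSE)
      ifelse(both_zero, 0, 1 / y^2)
    },
    inv_yhat2 = ifelse(both_zero, 0, ifelse(yh == 0, NA, 1 / yh^2)),
    inv_y_plus_yhat2 = ifelse(both_zero, 0, 1 / (y + yh)^2))
  if (anyNA(wk))
    stop("undefined-weight: objective kind inv_yhat2 with predicted Y~ = 0",
         call. = FALSE)
  sqrt(wc * wk) * (y - yh)
}

#' Bundle one formulation's Franz-cell kinetics for fitting
#'
#' @param formulation a [formulation_spec()].
#' @param stack the in vitro [skin_stack()].
#' @param cell_config the [franz_cell_config()] used for the measurements.
#' @param observations data.frame (`compartment`, `time_h`, `amount_ug`):
#'   layer amounts at the wash times and cumulative receptor amounts at the
#'   sampling times.
#' @param dermal_params baseline [dermal_parameters()] supplying every
#'   value not being fitted.
#' @return a `franz_dataset` record.
#' @export
franz_dataset <- function(formulation, stack, cell_config, observations,
                          dermal_params) {
  stopifnot(all(c("compartment", "time_h", "amount_ug") %in%
                  names(observations)))
  structure(list(formulation = formulation, stack = stack,
                 cell_config = cell_config, observations = observations,
                 dermal_params = dermal_params),
            class = c("franz_dataset", "pbk_record", "list"))
}

# Predict the observed (compartment, time) amounts of a dataset under a
# dermal parameter set.
predict_franz_observations <- function(chem, dataset, dermal_params,
                                       grid_spec) {
  obs <- dataset$observations
  t_layer <- sort(unique(obs$time_h[obs$compartment != "rf"]))
  t_rf <- sort(unique(obs$time_h[obs$compartment == "rf"]))
  sim_times <- sort(unique(c(0, t_layer, t_rf,
                             dataset$cell_config$sampling_times)))
  res <- simulate_franz(chem, dataset$formulation, dataset$stack,
                        dermal_params, dataset$cell_config,
                        grid_spec = grid_spec, times = sim_times)
  out <- list()
  if (length(t_layer) > 0) {
    la <- layer_amounts_at(res, t_layer)
    out <- c(out, lapply(c("sc", "ve", "de"), function(l)
      data.frame(compartment = l, time_h = t_layer, amount_ug = la[, l])))
  }
  if (length(t_rf) > 0) {
    rf <- stats::approx(res$times, res$receptor_cumulative, xout = t_rf)$y
    out <- c(out, list(data.frame(compartment = "rf", time_h = t_rf,
                                  amount_ug = rf)))
  }
  do.call(rbind, out)
}

# Bounded least-squares in log10 parameter space with optional
# Latin-hypercube multistart. Returns the best nls.lm fit augmented with
# the start used.
.lsq_multistart <- function(resid_fn, start, lower, upper, n_starts, seed,
                            maxiter = 50) {
  nm <- names(start)
  free <- upper > lower
  if (!any(free)) {
    r <- resid_fn(lower)
    return(list(par = lower, deviance = sum(r^2), info = 0,
                message = "all parameters pinned by bounds", niter = 0,
                converged = TRUE))
  }
  l10 <- log10(lower[free]); u10 <- log10(upper[free])
  s10 <- pmin(pmax(log10(start[free]), l10), u10)

  wrap <- function(p10) {
    full <- start
    full[free] <- 10^p10
    resid_fn(full)
  }
  starts <- list(s10)
  if (n_starts > 1) {
    set.seed(as.integer(seed))
    lh <- lhs::randomLHS(n_starts - 1, sum(free))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- l10 + lh[i, ] * (u10 - l10)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      # epsfcn sets the forward-difference step well above the inner ODE
      # solver noise (step ~ sqrt(epsfcn) * |p|); the default machine-eps
      # step makes the numerical Jacobian unusable against rtol ~ 1e-6
      # simulations
      minpack.lm::nls.lm(par = st, fn = wrap, lower = l10, upper = u10,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-8, ptol = 1e-8,
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed from every start", call. = FALSE)
  full <- start
  full[free] <- 10^best$par
  list(par = full, deviance = best$deviance, info = best$info,
       message = best$message, niter = best$niter,
       converged = best$info %in% 1:4)
}

#' Stage 1: refine chemical-specific dermal parameters across formulations
#'
#' Simultaneously fits the parameters tied to the chemical (by default
#' `d_ve`, `k_ve_w`, `d_de`, `k_de_w`; any subset via `start`) to the skin
#' kinetics of all supplied formulations at once: one shared value per
#' parameter minimizes the summed objective over every formulation's
#' records, while each formulation keeps its own formulation-specific
#' values from its dataset. Deterministic given (seed, start, bounds).
#'
#' @param datasets list of [franz_dataset()] objects (>= 2; a single
#'   dataset runs but is flagged for reduced identifiability).
#' @param chem a [chemical_properties()] record.
#' @param start named vector of initial values for the shared parameters.
#' @param lower,upper named bounds (same names as `start`); a parameter
#'   with `lower == upper` is pinned at that value.
#' @param spec an [objective_spec()].
#' @param grid_spec Franz grid for the inner simulations (a coarser grid
#'   than the reporting default keeps the refinement fast).
#' @param n_starts Latin-hypercube multistarts (1 = start only).
#' @param seed integer seed for the multistart design.
#' @return object of class `fit_result`: `fitted_params`, `bounds`,
#'   `objective_value`, `per_record_residuals`, `convergence_report`.
#' @export
stage1_chemical_fit <- function(datasets, chem,
                                start = c(d_ve = 1e-8, k_ve_w = 5,
                                          d_de = 1e-7, k_de_w = 3),
                                lower = start / 30, upper = start * 30,
                                spec = objective_spec(),
                                grid_spec = franz_grid(n_per_layer = 10,
                                                       rtol = 1e-6,
                                                       atol = 1e-8),
                                n_starts = 1, seed = 1) {
  stopifnot(length(datasets) >= 1,
            identical(names(start), names(lower)),
            identical(names(start), names(upper)))
  flag <- NULL
  if (length(datasets) < 2) {
    warning("single-formulation input: chemical-specific parameters are ",
            "only weakly identifiable", call. = FALSE)
    flag <- "reduced identifiability (single formulation)"
  }
  resid_fn <- function(p) {
    unlist(lapply(datasets, function(ds) {
      dp <- ds$dermal_params
      for (nm in names(p)) dp[[nm]] <- p[[nm]]
      pred <- predict_franz_observations(chem, ds, dp, grid_spec)
      objective_residuals(ds$observations, pred, spec)
    }))
  }
  fit <- .lsq_multistart(resid_fn, start, lower, upper, n_starts, seed)
  structure(list(fitted_params = fit$par,
                 bounds = rbind(lower = lower, upper = upper),
                 objective_value = fit$deviance,
                 per_record_residuals = resid_fn(fit$par),
                 convergence_report = list(converged = fit$converged,
                                           message = fit$message,
                                           n_iter = fit$niter,
                                           flag = flag)),
            class = "fit_result")
}

#' Stage 2: refine formulation-specific dermal parameters
#'
#' With the chemical-specific (stage-1) parameters frozen, fits the
#' formulation-specific parameters (by default `k_vh_w`, `d_sc`, `k_sc_w`
#' and the application time) for one formulation, within finite bounds.
#' All three objective kinds are tried; the winner is the kind with the
#' lowest objective value, ties broken by the receptor-curve RMSE (the
#' profile most consistent with the receptor-fluid kinetics); all three
#' fits are reported.
#'
#' @param dataset a [franz_dataset()].
#' @param chem a [chemical_properties()] record.
#' @param shared_params [dermal_parameters()] carrying the frozen stage-1
#'   values (and any other non-fitted parameter).
#' @param start,lower,upper named vectors over the fitted parameters.
#' @param weights per-compartment weights for every objective kind.
#' @param grid_spec,n_starts,seed as in [stage1_chemical_fit()].
#' @return a `fit_result`; `convergence_report$kind` names the selected
#'   objective kind and `convergence_report$all_kinds` tabulates all three.
#' @export
stage2_formulation_fit <- function(dataset, chem, shared_params,
                                   start = c(k_vh_w = 500, d_sc = 1e-9,
                                             k_sc_w = 100,
                                             application_time = 0.5),
                                   lower = start / 30, upper = start * 30,
                                   weights = c(sc = 1, ve = 1, de = 1, rf = 1),
                                   grid_spec = franz_grid(n_per_layer = 10,
                                                          rtol = 1e-6,
                                                          atol = 1e-8),
                                   n_starts = 1, seed = 1) {
  stopifnot(inherits(dataset, "franz_dataset"),
            identical(names(start), names(lower)),
            identical(names(start), names(upper)))
  kinds <- c("inv_y2", "inv_yhat2", "inv_y_plus_yhat2")
  fit_one <- function(kind) {
    spec <- objective_spec(kind, weights)
    resid_fn <- function(p) {
      dp <- shared_params
      for (nm in names(p)) dp[[nm]] <- p[[nm]]
      pred <- predict_franz_observations(chem, dataset, dp, grid_spec)
      objective_residuals(dataset$observations, pred, spec)
    }
    fit <- .lsq_multistart(resid_fn, start, lower, upper, n_starts, seed)
    # receptor RMSE under the fitted parameters (unweighted, rf rows only)
    dp <- shared_params
    for (nm in names(fit$par)) dp[[nm]] <- fit$par[[nm]]
    pred <- predict_franz_observations(chem, dataset, dp, grid_spec)
    obs <- dataset$observations
    rf <- obs$compartment == "rf"
    key <- paste(pred$compartment, signif(pred$time_h, 10))
    m <- match(paste(obs$compartment[rf], signif(obs$time_h[rf], 10)), key)
    rmse_rf <- sqrt(mean((obs$amount_ug[rf] - pred$amount_ug[m])^2))
    c(fit, list(rmse_rf = rmse_rf, kind = kind))
  }
  fits <- list()
  for (k in kinds)
    fits[[k]] <- tryCatch(fit_one(k), error = function(e)
      list(failed = TRUE, message = conditionMessage(e), kind = k))
  ok <- !vapply(fits, function(f) isTRUE(f$failed), logical(1))
  if (!any(ok))
    stop("all objective kinds failed: ",
         paste(vapply(fits, function(f) f$message, ""), collapse = " | "),
         call. = FALSE)
  tab <- do.call(rbind, lapply(fits[ok], function(f)
    data.frame(kind = f$kind, objective = f$deviance, rmse_rf = f$rmse_rf)))
  best_i <- order(tab$objective, tab$rmse_rf)[1]
  best <- fits[ok][[best_i]]
  structure(list(fitted_params = best$par,
                 bounds = rbind(lower = lower, upper = upper),
                 objective_value = best$deviance,
                 per_record_residuals = NULL,
                 convergence_report = list(converged = best$converged,
                                           message = best$message,
                                           n_iter = best$niter,
                                           kind = best$kind,
                                           all_kinds = tab)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", format(x$objective_value), "\n")
  print(x$fitted_params)
  cr <- x$convergence_report
  cat("converged:", cr$converged, if (!is.null(cr$kind))
    paste0("(objective kind: ", cr$kind, ")"), "\n")
  invisible(x)
}
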