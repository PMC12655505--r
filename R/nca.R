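#' Non-compartmental PK metrics from a concentration-time profile
#'
#' Cmax/Tmax are taken at the sampled maximum. AUC uses the linear-up /
#' log-down trapezoid (standard NCA practice: linear when concentration
#' rises or either endpoint is zero, logarithmic when it falls between two
#' positive values). AUC to infinity adds `C_last / lambda_z`, with the
#' terminal slope `lambda_z` from a log-linear regression over the last
#' points after Tmax; it is reported as undefined (with a reason) when the
#' profile is still rising at the cutoff (no interior maximum), when too
#' few terminal points exist, or when the terminal regression is
#' unconvincing (R^2 < 0.9 or non-negative slope).
#'
#' @param profile a `plasma_profile`, or a list/data.frame with `times` and
#'   `concentration`.
#' @param t_cut cutoff time for AUC0-t, h (default: last sampled time; a
#'   cutoff between samples is handled by linear interpolation).
#' @param dose_ug optional systemically available dose; when given (e.g.
#'   for an intravenous profile with a defined AUC0-inf), systemic
#'   clearance `dose/AUC0-inf` and `Vss = CL * AUMC/AUC` are reported.
#' @param n_lambda number of terminal points for the lambda_z regression.
#' @return object of class `pk_metrics`: `cmax` (ug/mL), `tmax` (h),
#'   `auc_0_t`, `auc_0_inf` (ug*h/mL; `auc_0_inf` NA when undefined, with
#'   attribute `"reason"`), `lambda_z` (1/h), `clsys` (L/h or NA), `vss`
#'   (L or NA), `t_cut`.
#' @export
pk_metrics <- function(profile, t_cut = NULL, dose_ug = NULL, n_lambda = 4) {
  times <- profile$times
  conc <- profile$concentration
  stopifnot(length(times) == length(conc), length(times) >= 3,
            all(diff(times) > 0))
  if (is.null(t_cut)) t_cut <- max(times)
  if (t_cut < min(times) || t_cut > max(times))
    stop("t_cut outside the profile range", call. = FALSE)

  keep <- times <= t_cut + 1e-12
  tt <- times[keep]; cc <- conc[keep]
  if (max(times[keep]) < t_cut) {
    cc <- c(cc, stats::approx(times, conc, xout = t_cut)$y)
    tt <- c(tt, t_cut)
  }

  imax <- which.max(cc)
  cmax <- cc[imax]; tmax <- tt[imax]

  auc_seg <- function(t1, t2, c1, c2) {
    dt <- t2 - t1
    if (c2 < c1 && c2 > 0 && c1 > 0) (c1 - c2) / log(c1 / c2) * dt
    else (c1 + c2) / 2 * dt
  }
  auc_0_t <- 0
  aumc_0_t <- 0
  for (i in seq_len(length(tt) - 1)) {
    auc_0_t <- auc_0_t + auc_seg(tt[i], tt[i + 1], cc[i], cc[i + 1])
    aumc_0_t <- aumc_0_t +
      auc_seg(tt[i], tt[i + 1], tt[i] * cc[i], tt[i + 1] * cc[i + 1])
  }

  auc_0_inf <- NA_real_
  lambda_z <- NA_real_
  reason <- NULL
  if (all(cc == 0)) {
    auc_0_inf <- 0
    reason <- "all-zero profile"
  } else if (imax == length(cc)) {
    reason <- "no Cmax reached: profile still rising at the cutoff"
  } else {
    term <- which(tt > tmax & cc > 0)
    term <- utils::tail(term, n_lambda)
    if (length(term) < 3) {
      reason <- "fewer than 3 positive terminal points"
    } else {
      fit <- stats::lm(log(cc[term]) ~ tt[term])
      sl <- unname(stats::coef(fit)[2])
      r2 <- summary(fit)$r.squared
      if (!is.finite(sl) || sl >= 0 || r2 < 0.9) {
        reason <- sprintf("non-identifiable terminal phase (slope %.3g, R^2 %.3f)",
                          sl, r2)
      } else {
        lambda_z <- -sl
        auc_0_inf <- auc_0_t + cc[length(cc)] / lambda_z
      }
    }
  }
  if (!is.null(reason) && is.na(auc_0_inf)) attr(auc_0_inf, "reason") <- reason

  clsys <- vss <- NA_real_
  if (!is.null(dose_ug) && is.finite(auc_0_inf) && auc_0_inf > 0 &&
      is.finite(lambda_z)) {
    aumc_inf <- aumc_0_t + tt[length(tt)] * cc[length(cc)] / lambda_z +
      cc[length(cc)] / lambda_z^2
    clsys <- (dose_ug / auc_0_inf) / 1000            # ug/(ug*h/mL) -> L/h
    vss <- clsys * aumc_inf / auc_0_inf
  }

  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
                 auc_0_inf = auc_0_inf, lambda_z = lambda_z,
                 clsys = clsys, vss = vss, t_cut = t_cut),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> Cmax %.4g ug/mL at Tmax %.3g h; AUC0-%g %.4g",
              x$cmax, x$tmax, x$t_cut, x$auc_0_t))
  if (is.na(x$auc_0_inf)) {
    cat(" (AUC0-inf undefined: ", attr(x$auc_0_inf, "reason"), ")\n", sep = "")
  } else cat(sprintf("; AUC0-inf %.4g ug*h/mL\n", x$auc_0_inf))
  invisible(x)
}

#' 2-fold external validation of predicted against observed PK metrics
#'
#' For each shared, defined metric, reports the predicted/observed ratio and
#' the fold deviation `max(r, 1/r)`; a metric passes when its fold deviation
#' is at most `fold` (default 2, the WHO-style acceptance rule). The pass
#' decision is symmetric: swapping predicted and observed inverts the ratio
#' but leaves the fold deviation unchanged.
#'
#' @param predicted,observed `pk_metrics` objects, or named lists/vectors
#'   holding any of `cmax`, `tmax`, `auc_0_t`, `auc_0_inf`.
#' @param metrics which metrics to compare.
#' @param fold acceptance threshold on the fold deviation.
#' @return data.frame with columns `metric`, `predicted`, `observed`,
#'   `ratio`, `fold_deviation`, `pass`; observed zeros yield NA ratios.
#'   Attribute `"pass_all"` is TRUE when every defined comparison passes.
#' @export
fold_validation <- function(predicted, observed,
                            metrics = c("cmax", "auc_0_t"), fold = 2) {
  get1 <- function(x, m) {
    v <- x[[m]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  rows <- lapply(metrics, function(m) {
    p <- get1(predicted, m); o <- get1(observed, m)
    if (is.na(p) || is.na(o)) {
      data.frame(metric = m, predicted = p, observed = o,
                 ratio = NA_real_, fold_deviation = NA_real_, pass = NA)
    } else if (o == 0) {
      data.frame(metric = m, predicted = p, observed = o,
                 ratio = NA_real_, fold_deviation = NA_real_, pass = NA)
    } else {
      r <- p / o
      fd <- max(r, 1 / r)
      data.frame(metric = m, predicted = p, observed = o,
                 ratio = r, fold_deviation = fd, pass = fd <= fold)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "pass_all") <- all(out$pass[!is.na(out$pass)])
  out
}
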