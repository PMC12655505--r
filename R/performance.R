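#' WHO-style classification of sensitivity and uncertainty values
#'
#' Sensitivity classes on |S|: high (>= 0.5), medium (>= 0.2), low (>= 0.1),
#' negligible (< 0.1). The published three-band rule leaves (0, 0.1)
#' unassigned and puts 0.2 in two bands; here classes are assigned by first
#' match from the top (0.5 -> high boundary, 0.2 -> medium, 0.1 -> low) and
#' values below 0.1 get an explicit fourth class rather than silently
#' extending "low". Uncertainty classes on the percentile-spread metric:
#' high (>= 2), medium (>= 0.3), low (< 0.3), again first-match from the
#' top. Both functions are total: every finite input maps to exactly one
#' class.
#'
#' @param s normalized sensitivity coefficient(s).
#' @param u uncertainty metric value(s).
#' @return character vector of classes.
#' @name who_classes
NULL

#' @rdname who_classes
#' @export
classify_sensitivity <- function(s) {
  stopifnot(all(is.finite(s)))
  a <- abs(s)
  ifelse(a >= 0.5, "high",
         ifelse(a >= 0.2, "medium",
                ifelse(a >= 0.1, "low", "negligible")))
}

#' @rdname who_classes
#' @export
classify_uncertainty <- function(u) {
  stopifnot(all(is.finite(u)), all(u >= 0))
  ifelse(u >= 2, "high", ifelse(u >= 0.3, "medium", "low"))
}

#' Normalized local sensitivity scan
#'
#' For each parameter x with baseline output y, runs the model at x(1 - p)
#' and x(1 + p) (default p = 5%) and reports the normalized central
#' sensitivity coefficient `S = (dy/dx) * (x/y) = (y+ - y-) / (2 p y)`,
#' together with the two one-sided coefficients, classified per
#' [classify_sensitivity()].
#'
#' @param runner function(params) -> scalar output (e.g. Cmax); `params` is
#'   the full named numeric vector.
#' @param params named numeric baseline parameter vector.
#' @param perturbation relative perturbation, in (0, 0.5).
#' @param output_metric label for the scanned output (recorded only).
#' @return data.frame of class `sensitivity_result` with columns
#'   `parameter`, `s` (central), `s_minus`, `s_plus` (one-sided),
#'   `s_class`, `output_metric`.
#' @export
sensitivity_scan <- function(runner, params, perturbation = 0.05,
                             output_metric = "cmax") {
  stopifnot(is.numeric(params), !is.null(names(params)),
            perturbation > 0, perturbation < 0.5)
  y0 <- runner(params)
  if (!is.finite(y0)) stop("baseline run failed", call. = FALSE)
  if (y0 == 0)
    stop("undefined-sensitivity: baseline output is 0", call. = FALSE)
  rows <- lapply(names(params), function(nm) {
    up <- params; up[nm] <- up[nm] * (1 + perturbation)
    dn <- params; dn[nm] <- dn[nm] * (1 - perturbation)
    yp <- runner(up); ym <- runner(dn)
    s_c <- (yp - ym) / (2 * perturbation * y0)
    data.frame(parameter = nm,
               s = s_c,
               s_plus = (yp - y0) / (perturbation * y0),
               s_minus = (y0 - ym) / (perturbation * y0),
               s_class = classify_sensitivity(s_c),
               output_metric = output_metric)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Monte-Carlo uncertainty analysis of a model output
#'
#' Samples the listed parameters independently from log-normal
#' distributions whose median is the baseline value and whose coefficient
#' of variation is given per parameter (`sigma^2 = ln(1 + CV^2)`), runs the
#' model for each draw, and summarizes the output by its 2.5th, 50th and
#' 97.5th percentiles (type-7 quantiles). The uncertainty metric is
#' `(p97.5 - p2.5) / p50`, classified per [classify_uncertainty()].
#' Individual run failures are caught, counted and excluded; more than 5%
#' failures is an error.
#'
#' @param runner function(params) -> scalar output.
#' @param params named numeric baseline vector.
#' @param cv named numeric CVs (fractions, e.g. 0.3 for 30%) for the
#'   parameters to vary; parameters absent from `cv` stay fixed.
#' @param n_subjects Monte-Carlo sample size (>= 50).
#' @param seed integer seed; the analysis is deterministic given the seed.
#' @param label label for the varied model/parameter group.
#' @return object of class `uncertainty_result`: list with `label`, `p2_5`,
#'   `p50`, `p97_5`, `metric`, `u_class`, `n_ok`, `n_failed`, `samples`.
#' @export
uncertainty_eval <- function(runner, params, cv, n_subjects = 100, seed,
                             label = "model") {
  stopifnot(n_subjects >= 50, all(cv >= 0), !missing(seed))
  set.seed(as.integer(seed))
  vary <- intersect(names(cv), names(params))
  sigma <- sqrt(log(1 + cv[vary]^2))
  draws <- matrix(stats::rnorm(n_subjects * length(vary)),
                  nrow = n_subjects)
  out <- rep(NA_real_, n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- params
    if (length(vary) > 0)
      p[vary] <- p[vary] * exp(draws[i, ] * sigma)
    out[i] <- tryCatch(runner(p), error = function(e) NA_real_)
  }
  n_failed <- sum(!is.finite(out))
  if (n_failed > 0.05 * n_subjects)
    stop("more than 5% of simulations failed (", n_failed, "/", n_subjects,
         ")", call. = FALSE)
  ok <- out[is.finite(out)]
  qs <- stats::quantile(ok, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  metric <- if (qs[2] != 0) (qs[3] - qs[1]) / qs[2] else 0
  structure(list(label = label, p2_5 = qs[1], p50 = qs[2], p97_5 = qs[3],
                 metric = metric, u_class = classify_uncertainty(metric),
                 n_ok = length(ok), n_failed = n_failed, samples = ok),
            class = "uncertainty_result")
}

#' Reliability matrix from sensitivity and uncertainty classes
#'
#' Combines per-parameter sensitivity and uncertainty classes into a
#' reliability grade: `low` iff (high sensitivity, high uncertainty);
#' `high` iff the sensitivity is low (or negligible) and the uncertainty is
#' low; `medium` otherwise. The mapping can be replaced through `rule`.
#'
#' @param sens data.frame with `parameter` and `s_class` (e.g. from
#'   [sensitivity_scan()]).
#' @param unc data.frame with `parameter` and `u_class` (one row per
#'   parameter).
#' @param rule function(s_class, u_class) -> reliability grade.
#' @return data.frame with `parameter`, `s_class`, `u_class`,
#'   `reliability`; parameters present on only one side generate a warning
#'   and are dropped.
#' @export
reliability_matrix <- function(sens, unc, rule = NULL) {
  if (is.null(rule)) {
    rule <- function(s, u) {
      if (s == "high" && u == "high") "low"
      else if (s %in% c("low", "negligible") && u == "low") "high"
      else "medium"
    }
  }
  common <- intersect(sens$parameter, unc$parameter)
  extra <- setdiff(union(sens$parameter, unc$parameter), common)
  if (length(extra) > 0)
    warning("unmatched parameters dropped: ", paste(extra, collapse = ", "),
            call. = FALSE)
  s <- sens[match(common, sens$parameter), "s_class"]
  u <- unc[match(common, unc$parameter), "u_class"]
  data.frame(parameter = common, s_class = s, u_class = u,
             reliability = mapply(rule, s, u, USE.NAMES = FALSE))
}

#' Population simulation of PK dose metrics
#'
#' Samples subject demographics uniformly within the stated ranges (age;
#' body weight; sex by the given ratio), scales the physiology
#' allometrically through the model runner, samples chemical/dermal
#' parameters log-normally by CV (median at baseline), runs the full model
#' chain per subject, and summarizes Cmax/Tmax/AUC across the population:
#' arithmetic and geometric means, CV%, min, max, a 90% confidence interval
#' of the mean (normal approximation), and the 5th-95th population
#' percentile interval (both intervals are reported because either reading
#' of a "90% interval" is in use).
#'
#' @param runner function(subject) -> named numeric vector (e.g. `cmax`,
#'   `tmax`, `auc_0_t`); `subject` is a list with `body_weight`, `age`,
#'   `sex`, and `params` (the per-subject parameter vector).
#' @param params named numeric baseline parameter vector.
#' @param cv named CVs for the parameters to vary (fractions).
#' @param n number of subjects (>= 2).
#' @param age_range,weight_range demographic ranges (years, kg).
#' @param prop_male fraction of male subjects.
#' @param seed integer seed (mandatory).
#' @return object of class `population_result`: `summary` (data.frame, one
#'   row per metric), `subjects` (per-subject demographics), `metrics`
#'   (per-subject metric matrix), `n_failed`.
#' @export
population_simulate <- function(runner, params, cv = numeric(0), n = 500,
                                age_range = c(18, 70),
                                weight_range = c(50, 90),
                                prop_male = 0.5, seed) {
  stopifnot(n >= 2, !missing(seed))
  set.seed(as.integer(seed))
  age <- stats::runif(n, age_range[1], age_range[2])
  bw <- stats::runif(n, weight_range[1], weight_range[2])
  sex <- ifelse(stats::runif(n) < prop_male, "male", "female")
  vary <- intersect(names(cv), names(params))
  sigma <- sqrt(log(1 + cv[vary]^2))
  zmat <- matrix(stats::rnorm(n * length(vary)), nrow = n)

  res <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    if (length(vary) > 0) p[vary] <- p[vary] * exp(zmat[i, ] * sigma)
    subj <- list(body_weight = bw[i], age = age[i], sex = sex[i], params = p)
    res[[i]] <- tryCatch(runner(subj), error = function(e) NULL)
  }
  ok <- !vapply(res, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n)
    stop("more than 5% of subject simulations failed", call. = FALSE)
  metrics <- do.call(rbind, res[ok])

  summarize <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    se <- s / sqrt(length(x))
    gm <- if (all(x > 0)) exp(mean(log(x))) else NA_real_
    q <- stats::quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
    data.frame(mean = m, geo_mean = gm,
               cv_pct = if (m != 0) 100 * s / m else 0,
               min = min(x), max = max(x),
               ci90_lo = m - 1.645 * se, ci90_hi = m + 1.645 * se,
               p5 = q[1], p95 = q[2])
  }
  summ <- do.call(rbind, lapply(colnames(metrics), function(mm)
    cbind(metric = mm, summarize(metrics[, mm]))))
  structure(list(summary = summ,
                 subjects = data.frame(age = age[ok], body_weight = bw[ok],
                                       sex = sex[ok]),
                 metrics = metrics, n_failed = n_failed),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result> n =", nrow(x$metrics), "subjects",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)"), "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
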