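.ts_schemas <- list(
  receptor = c("time_h", "amount_ug", "replicate_id"),
  dermis = c("time_h", "q_rf_ug_per_cm2", "replicate_id"),
  evaporation = c("time_h", "mass_mg"),
  layers = c("time_h", "compartment", "amount_ug", "replicate_id"),
  plasma = c("time_h", "conc_ug_ml"))

#' Read a validated time-series CSV
#'
#' Readers for the CSV interfaces consumed by the pipeline. Each schema
#' names its required columns; values are checked (numeric, non-negative
#' amounts, strictly increasing times within a replicate/compartment
#' group) and violations are reported with the offending row number.
#'
#' Schemas: `receptor` (time_h, amount_ug, replicate_id), `dermis`
#' (time_h, q_rf_ug_per_cm2, replicate_id), `evaporation` (time_h,
#' mass_mg), `layers` (time_h, compartment, amount_ug, replicate_id),
#' `plasma` (time_h, conc_ug_ml).
#'
#' @param path CSV file path.
#' @param schema one of the schema names above.
#' @return validated data.frame with the schema's columns.
#' @export
read_timeseries <- function(path, schema = names(.ts_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- .ts_schemas[[schema]]
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " for schema '", schema, "'",
         call. = FALSE)
  value_col <- setdiff(cols, c("time_h", "replicate_id", "compartment"))
  for (cc in c("time_h", value_col)) {
    if (!is.numeric(df[[cc]]))
      stop("schema error: column ", cc, " is not numeric", call. = FALSE)
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad) > 0)
      stop("schema error: non-finite ", cc, " at row ", bad[1], call. = FALSE)
  }
  bad <- which(df[[value_col]] < 0)
  if (length(bad) > 0)
    stop("schema error: negative ", value_col, " at row ", bad[1],
         call. = FALSE)
  grp <- interaction(
    if ("replicate_id" %in% cols) df$replicate_id else 0,
    if ("compartment" %in% cols) df$compartment else 0, drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    tg <- df$time_h[rows]
    if (anyDuplicated(tg) > 0)
      stop("schema error: duplicated timepoint at row ",
           rows[anyDuplicated(tg)], call. = FALSE)
    if (is.unsorted(tg))
      stop("schema error: non-monotone time at row ",
           rows[which(diff(tg) < 0)[1] + 1], call. = FALSE)
  }
  df[, cols]
}

#' Write a time-series CSV
#'
#' @param df data.frame matching one of the [read_timeseries()] schemas.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, configuration hash, input digests, seed, package
#' version and the output file list of a pipeline run as JSON next to the
#' outputs, so a run can be verified unchanged.
#'
#' @param out_dir output directory.
#' @param command label of the executed command.
#' @param config the configuration object (hashed after serialization).
#' @param inputs character vector of input file paths (digested).
#' @param seed the seed used.
#' @param outputs character vector of produced files.
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(out_dir, command, config, inputs = character(0),
                           seed = NA, outputs = character(0)) {
  tmp <- tempfile()
  saveRDS(config, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command, config_hash = cfg_hash,
                   input_digests = digests, seed = seed,
                   package_version = as.character(utils::packageVersion("dermalpbk")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = as.list(outputs))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full L1/L2 parameterization and prediction chain
#'
#' Executes the bottom-up workflow in order: parameter estimation ->
#' in vitro skin simulation -> (L2 only) two-stage refinement against
#' Franz-cell kinetics -> whole-body plasma simulation -> PK metrics and
#' 2-fold validation. L1 uses only in silico dermal parameters
#' ([l1_insilico_dermal()]); L2 additionally uses the isolated-dermis fit
#' and refines chemical- and formulation-specific parameters against the
#' supplied skin-absorption datasets.
#'
#' @param config list with elements:
#'   * `level`: `"L1"` or `"L2"`.
#'   * `chem`: [chemical_properties()].
#'   * `formulations`: named list of [formulation_spec()] records to build
#'     full models for (e.g. `F1`, `F2`).
#'   * `stack_invitro`, `stack_invivo`: [skin_stack()] records.
#'   * `subjects`: named list (same names as `formulations`) of
#'     demographics lists (`age`, `body_weight`, `sex`).
#'   * `regimen`: a [dose_regimen()] (applied per formulation; its area is
#'     used for the in vivo stack).
#'   * `observed`: optional named list of observed metrics for
#'     [fold_validation()].
#'   * `t_cut`: AUC cutoff, h (default 23).
#'   * L2 only: `franz_datasets` (named list of [franz_dataset()],
#'     normally all four formulations), `dermis_curve` (data.frame
#'     `time_h`, `q_rf_ug_per_cm2` of the isolated-dermis experiment),
#'     `dermis_c_d` (applied concentration, ug/mL), optional
#'     `stage1_start/lower/upper`, `stage2_start/lower/upper`,
#'     `fit_d_de` (default FALSE: d_de is taken from the dermis fit, not
#'     refitted).
#' @param out_dir optional directory for CSV outputs and the run manifest.
#' @param seed integer seed recorded in the manifest (the chain itself is
#'   deterministic).
#' @return list with `level`, `dermal_params` (per formulation),
#'   `dermis_fit` (L2), `stage1`, `stage2` (L2), `franz` (in vitro
#'   simulation per formulation), `plasma` (per formulation),
#'   `pk` (per formulation), `validation` (per formulation, when observed
#'   values are given).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1) {
  level <- match.arg(config$level, c("L1", "L2"))
  for (need in c("chem", "formulations", "stack_invitro", "stack_invivo",
                 "subjects", "regimen"))
    if (is.null(config[[need]]))
      stop("configuration: missing '", need, "'", call. = FALSE)
  if (level == "L2") {
    for (need in c("franz_datasets", "dermis_curve", "dermis_c_d"))
      if (is.null(config[[need]]))
        stop("configuration: L2 requires '", need, "'", call. = FALSE)
  }
  chem <- config$chem
  t_cut <- config$t_cut %||% 23

  dermis_fit <- NULL
  stage1 <- NULL
  stage2 <- list()
  dermal_params <- list()

  if (level == "L1") {
    for (nm in names(config$formulations))
      dermal_params[[nm]] <- l1_insilico_dermal(chem, config$stack_invitro,
                                                config$formulations[[nm]])
  } else {
    dc <- config$dermis_curve
    dermis_fit <- fit_isolated_dermis(dc$time_h, dc$q_rf_ug_per_cm2,
                                      config$stack_invitro,
                                      c_d = config$dermis_c_d)
    s1_start <- config$stage1_start %||%
      c(d_ve = 2e-8, k_ve_w = 4, k_de_w = 2)
    s1_lower <- config$stage1_lower %||% (s1_start / 30)
    s1_upper <- config$stage1_upper %||% (s1_start * 30)
    datasets <- lapply(config$franz_datasets, function(ds) {
      ds$dermal_params$d_de <- dermis_fit$d_de
      ds
    })
    stage1 <- stage1_chemical_fit(datasets, chem, start = s1_start,
                                  lower = s1_lower, upper = s1_upper,
                                  seed = seed)
    for (nm in names(config$formulations)) {
      ds <- datasets[[nm]]
      if (is.null(ds))
        stop("configuration: no franz_dataset for formulation '", nm, "'",
             call. = FALSE)
      shared <- ds$dermal_params
      for (p in names(stage1$fitted_params))
        shared[[p]] <- stage1$fitted_params[[p]]
      s2_start <- config$stage2_start %||%
        c(k_vh_w = 800, d_sc = 2e-9, k_sc_w = 100, application_time = 0.5)
      s2_lower <- config$stage2_lower %||% (s2_start / 30)
      s2_upper <- config$stage2_upper %||% (s2_start * 30)
      stage2[[nm]] <- stage2_formulation_fit(ds, chem, shared,
                                             start = s2_start,
                                             lower = s2_lower,
                                             upper = s2_upper, seed = seed)
      dp <- shared
      for (p in names(stage2[[nm]]$fitted_params))
        dp[[p]] <- stage2[[nm]]$fitted_params[[p]]
      dermal_params[[nm]] <- dp
    }
  }

  franz <- list(); plasma <- list(); pk <- list(); validation <- list()
  for (nm in names(config$formulations)) {
    form <- config$formulations[[nm]]
    franz[[nm]] <- simulate_franz(chem, form, config$stack_invitro,
                                  dermal_params[[nm]],
                                  franz_cell_config(dose_per_area = NULL))
    subj <- config$subjects[[nm]]
    stack_vivo <- config$stack_invivo
    sp <- build_systemic_parameters(chem, subj$body_weight, subj$age,
                                    subj$sex,
                                    dermal_params = dermal_params[[nm]],
                                    stack = stack_vivo)
    plasma[[nm]] <- simulate_plasma(
      chem, sp,
      list(formulation = form, stack = stack_vivo,
           dermal_params = dermal_params[[nm]]),
      config$regimen)
    pk[[nm]] <- pk_metrics(plasma[[nm]],
                           t_cut = min(t_cut, max(plasma[[nm]]$times)))
    if (!is.null(config$observed[[nm]]))
      validation[[nm]] <- fold_validation(pk[[nm]], config$observed[[nm]])
  }

  out <- list(level = level, dermal_params = dermal_params,
              dermis_fit = dermis_fit, stage1 = stage1, stage2 = stage2,
              franz = franz, plasma = plasma, pk = pk,
              validation = validation)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(plasma)) {
      f <- file.path(out_dir, paste0("plasma_", nm, ".csv"))
      write_timeseries(data.frame(time_h = plasma[[nm]]$times,
                                  conc_ug_ml = plasma[[nm]]$concentration), f)
      files <- c(files, f)
    }
    write_manifest(out_dir, paste0("run_pipeline:", level), config,
                   seed = seed, outputs = files)
  }
  out
}

.config_constructors <- list(
  chemical = "chemical_properties",
  formulation = "formulation_spec",
  skin_stack = "skin_stack",
  dermal_parameters = "dermal_parameters",
  dose_regimen = "dose_regimen")

#' Read a typed model configuration from YAML or JSON
#'
#' Parses a configuration file holding any of the sections `chemical`,
#' `formulation` (or `formulations`, a named list), `skin_stack`,
#' `dermal_parameters` and `dose_regimen`, passes each section's fields to
#' the corresponding record constructor, and validates the invariants.
#' A `dose_regimen` section holds `events` as a list of records with
#' `time_h`, `mass_mg`, `volume_ml`, `area_cm2`. Unknown sections are kept
#' untouched so callers can carry extra settings alongside the typed
#' records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list in which every recognized section has been replaced
#'   by its validated record.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(kind, fields) {
    ctor <- .config_constructors[[kind]]
    if (kind == "dose_regimen") {
      ev <- fields$events
      if (!is.data.frame(ev))
        ev <- do.call(rbind, lapply(ev, as.data.frame))
      fields$events <- ev
    }
    do.call(ctor, fields)
  }
  out <- raw
  for (kind in names(.config_constructors)) {
    if (!is.null(raw[[kind]]))
      out[[kind]] <- build(kind, raw[[kind]])
  }
  if (!is.null(raw$formulations))
    out$formulations <- lapply(raw$formulations, build, kind = "formulation")
  out
}
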