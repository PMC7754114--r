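#' Write / read a patient table as delimited text
#'
#' Flat tab-separated table, one row per patient, header row, explicit `NA`
#' token.  A JSON side-car (`<path>.meta.json`) records the generating seed
#' and regimen/anchor labels when the records came from
#' [simulate_cohorts()], so a run is fully reproducible from its files.
#'
#' @param records Patient data frame.
#' @param path Output path (e.g. `cohort.tsv`).
#' @return `write_patient_table` returns `path` invisibly;
#'   `read_patient_table` returns the records with factor covariates
#'   restored to their standard levels.
#' @export
write_patient_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  simc <- attr(records, "sim_config")
  meta <- list(n = nrow(records),
               columns = names(records),
               seed = if (!is.null(simc)) simc$seed else NULL,
               anchor = if (!is.null(simc)) simc$anchor else NULL,
               experimental = if (!is.null(simc)) simc$experimental else NULL)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_patient_table
#' @export
read_patient_table <- function(path) {
  rec <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE)
  spec <- default_covariate_spec()
  for (v in names(spec))
    if (spec[[v]]$type == "categorical" && v %in% names(rec))
      rec[[v]] <- factor(as.character(rec[[v]]), levels = spec[[v]]$levels)
  for (v in c("response_assessed", "transplant_lot1", "severe_cardiac",
              "other_malignancy"))
    if (v %in% names(rec)) rec[[v]] <- as.logical(rec[[v]])
  rec
}

#' Write a run configuration to YAML
#'
#' Serializes a [run_config()] (including any embedded
#' [simulation_config()]) so that a run is fully specified by one side-car
#' file; [read_run_config()] reconstructs it.
#'
#' @param config A [run_config()].
#' @param path YAML output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)  # keep names in YAML
    else x
  }
  yaml::write_yaml(strip(config), path, precision = 17L)  # lossless doubles
  invisible(path)
}

#' @rdname write_run_config
#' @param path YAML path written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  relist_num <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1))) &&
        all(vapply(x, length, integer(1)) == 1) && !is.null(names(x)))
      unlist(x) else x
  }
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    sim <- simulation_config(
      n_trial_per_arm = s$n_trial_per_arm,
      n_rwd_per_regimen = unlist(s$n_rwd_per_regimen),
      anchor = s$anchor, experimental = s$experimental,
      covariate_spec = lapply(s$covariate_spec, function(cs) {
        cs$probs <- unlist(cs$probs); cs$levels <- unlist(cs$levels)
        cs[!vapply(cs, is.null, logical(1))]
      }),
      true_log_hr = unlist(s$true_log_hr),
      effect_modifier_coefs = unlist(s$effect_modifier_coefs) %||% numeric(0),
      prognostic_coefs = unlist(s$prognostic_coefs) %||% numeric(0),
      prognostic_shift = lapply(s$prognostic_shift, unlist),
      assignment_coefs = lapply(s$assignment_coefs, unlist),
      baseline_hazard = unlist(s$baseline_hazard),
      admin_cap_months = s$admin_cap_months,
      dropout_rate = unlist(s$dropout_rate),
      discontinuation_rate = lapply(s$discontinuation_rate, unlist),
      missing_rates = lapply(s$missing_rates, unlist),
      missing_mechanism = s$missing_mechanism,
      event_detection_prob = unlist(s$event_detection_prob),
      n_clinics = s$n_clinics, seed = s$seed)
  }
  elig <- do.call(eligibility_criteria, c(
    raw$eligibility[setdiff(names(raw$eligibility),
                            c("lab_bounds", "excluded_comorbidities"))],
    list(lab_bounds = lapply(raw$eligibility$lab_bounds, unlist),
         excluded_comorbidities = unlist(raw$eligibility$excluded_comorbidities)
           %||% character(0))))
  run_config(sim = sim, input_path = raw$input_path,
             eligibility = elig, m = raw$m, n_cycles = raw$n_cycles,
             weighting_set = raw$weighting_set,
             outcome = do.call(outcome_spec, raw$outcome),
             analysis_set = raw$analysis_set, seed = raw$seed)
}
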