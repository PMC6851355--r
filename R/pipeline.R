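#' Pipeline configuration
#'
#' One object holding every tunable the analysis stages expose, with the
#' published defaults. Round-trips losslessly through JSON; unknown keys in a
#' file are rejected.
#'
#' @param seed Integer master seed.
#' @param detection List: `threshold_k`, `min_separation_ms`,
#'   `baseline_window_ms`, `fit_window_fraction`.
#' @param boundaries List: `mixed_low`, `mixed_high` (ms).
#' @param calcium List: `threshold` (% dF/F), `min_separation_s`, `window_s`,
#'   `burst_min_peaks`, `drug_arrival_s`.
#' @param scrna List: `threshold`, `direction`, `select_gene`.
#' @param output_dir Where [run_pipeline()] reports are written (optional).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            detection = list(threshold_k = 4,
                                             min_separation_ms = 5,
                                             baseline_window_ms = 200,
                                             fit_window_fraction = 0.1),
                            boundaries = list(mixed_low = 16.8, mixed_high = 35.7),
                            calcium = list(threshold = 3.5, min_separation_s = 2,
                                           window_s = 300, burst_min_peaks = 3,
                                           drug_arrival_s = 60),
                            scrna = list(threshold = 0.01, direction = ">",
                                         select_gene = "Grpr"),
                            output_dir = NULL) {
  cfg <- list(seed = as.integer(seed), detection = detection,
              boundaries = boundaries, calcium = calcium, scrna = scrna,
              output_dir = output_dir)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

config_schema <- function() {
  list(
    seed = NULL,
    detection = c("threshold_k", "min_separation_ms", "baseline_window_ms",
                  "fit_window_fraction"),
    boundaries = c("mixed_low", "mixed_high"),
    calcium = c("threshold", "min_separation_s", "window_s", "burst_min_peaks",
                "drug_arrival_s"),
    scrna = c("threshold", "direction", "select_gene"),
    output_dir = NULL
  )
}

validate_config <- function(cfg) {
  schema <- config_schema()
  extra <- setdiff(names(cfg), names(schema))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  for (sec in c("detection", "boundaries", "calcium", "scrna")) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad)) stop("unknown config key(s) in ", sec, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  # JSON does not distinguish integer from double; all tunables are doubles
  raw <- rapply(raw, function(x) if (is.numeric(x)) as.numeric(x) else x,
                how = "replace")
  raw$seed <- as.integer(raw$seed)
  validate_config(raw)
  structure(raw, class = "pipeline_config")
}

#' Run an end-to-end experiment on synthetic data
#'
#' Strings the stages into the two published experiment designs plus the
#' supporting measurements, on generator presets driven by the config seed:
#'
#' * `ipsc_profile` — control / strychnine / strychnine+bicuculline IPSC
#'   recordings: kinetic fractions, tonic currents, blockade fractions.
#' * `epsc_profile` — EPSC recording at a -70 mV hold, CNQX and NBQX blocks
#'   and their baseline shifts.
#' * `excitability` — rheobase, input resistance and resting potential of the
#'   preset cell before/after antagonists, with cohort comparisons.
#' * `calcium_cohort` — a somatostatin imaging cohort: percent responders,
#'   reaction times, dF/F summary.
#' * `scrna` — synthetic count matrix: normalization, population selection
#'   and panel prevalence.
#'
#' Reports are a pure function of `(config, seed)`: the same config yields
#' byte-identical numeric sections.
#'
#' @param config A [pipeline_config()].
#' @param experiment One of the five experiment names.
#' @return A list of class `tone_report` with `experiment`, `results` (named
#'   list of tibbles/values, each numeric entry unit-tagged in its name),
#'   `provenance` (seed, package version, config) and `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         experiment = c("ipsc_profile", "epsc_profile",
                                        "excitability", "calcium_cohort",
                                        "scrna")) {
  stopifnot(inherits(config, "pipeline_config"))
  experiment <- match.arg(experiment)
  warn <- character(0)
  results <- withCallingHandlers(
    switch(experiment,
      ipsc_profile = stage_ipsc(config),
      epsc_profile = stage_epsc(config),
      excitability = stage_excitability(config),
      calcium_cohort = stage_calcium(config),
      scrna = stage_scrna(config)
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  structure(
    list(
      experiment = experiment,
      results = results,
      provenance = list(
        seed = config$seed,
        package_version = as.character(utils::packageVersion("spinaltone")),
        config = unclass(config)
      ),
      warnings = warn
    ),
    class = "tone_report"
  )
}

stage_ipsc <- function(cfg) {
  b <- class_boundaries(cfg$boundaries$mixed_low, cfg$boundaries$mixed_high)
  prof <- inhibition_profile(
    preset_vc_ipsc(seed = cfg$seed),
    boundaries = b,
    threshold_k = cfg$detection$threshold_k,
    min_separation_ms = cfg$detection$min_separation_ms
  )
  list(
    kinetic_fractions = prof$mixture,
    tonic_glycine_pa = prof$tonic_glycine_pa,
    tonic_gaba_pa = prof$tonic_gaba_pa,
    strychnine_block_fraction = prof$strychnine_block_fraction,
    bicuculline_block_fraction = prof$bicuculline_block_fraction,
    frequency_hz = prof$frequency_hz
  )
}

stage_epsc <- function(cfg) {
  base <- vc_params(
    duration = 40, hold_voltage = -70,
    event_rate = c(ampa = 8, glycine = 0, gaba = 0, mixed = 0),
    baseline_current = -15, seed = cfg$seed
  )
  run <- function(p, pol) {
    sim <- gen_vc_trace(p)
    ev <- detect_events(sim$trace, pol, cfg$detection$threshold_k,
                        cfg$detection$min_separation_ms)
    list(freq = event_frequency(ev, c(0, p$duration)),
         hold = as.numeric(estimate_holding_current(sim$trace)))
  }
  p_cnqx <- apply_drug(base, "cnqx"); p_cnqx$seed <- base$seed + 1L
  p_nbqx <- apply_drug(base, "nbqx"); p_nbqx$seed <- base$seed + 2L
  ctrl <- run(base, "inward")
  cnqx <- run(p_cnqx, "inward")
  nbqx <- run(p_nbqx, "inward")
  list(
    epsc_frequency_hz = c(control = ctrl$freq, cnqx = cnqx$freq, nbqx = nbqx$freq),
    cnqx_block_fraction = blockade_fraction(ctrl$freq, cnqx$freq),
    nbqx_block_fraction = blockade_fraction(ctrl$freq, nbqx$freq),
    cnqx_shift_pa = cnqx$hold - ctrl$hold,
    nbqx_shift_pa = nbqx$hold - ctrl$hold
  )
}

stage_excitability <- function(cfg) {
  cell <- preset_cell()
  blocked <- apply_drug(apply_drug(cell, "strychnine"), "bicuculline")
  ctrl <- measure_excitability(cell, "control")
  post <- measure_excitability(blocked, "antagonist")
  # small simulated cohorts at the published group sizes for the comparison
  sim_cohort <- function(mu, n, rel_sd, seed_off) {
    withr::with_seed(cfg$seed + seed_off, pmax(0.5, stats::rnorm(n, mu, rel_sd * mu)))
  }
  rheo_ctrl <- sim_cohort(ctrl$rheobase_pa, 15, 0.35, 101L)
  rheo_post <- sim_cohort(post$rheobase_pa, 5, 0.35, 102L)
  cmp <- compare_groups(rheo_ctrl, rheo_post, "t_two_tailed")
  list(
    measures = dplyr::bind_rows(ctrl, post),
    rheobase_shift_pa = ctrl$rheobase_pa - post$rheobase_pa,
    tonic_current_at_threshold_pa = lif_tonic_current_at_threshold(cell),
    rheobase_comparison = cmp
  )
}

stage_calcium <- function(cfg) {
  cal <- simulate_calibration(seed = cfg$seed)
  thr <- tryCatch(calibrate_threshold(cal), error = function(e) cfg$calcium$threshold)
  cohort <- gen_calcium_cohort(seed = cfg$seed)
  responders <- cohort$records[!cohort$records$spontaneous, , drop = FALSE]
  list(
    calibration = cal,
    calibrated_threshold_dff_percent = thr,
    cohort_summary = summarize_cohort(responders),
    n_spontaneous = sum(cohort$records$spontaneous)
  )
}

stage_scrna <- function(cfg) {
  sim <- gen_count_matrix(
    n_genes = 200, n_cells = 2000,
    prevalence = withr::with_seed(cfg$seed + 11L, stats::runif(200, 0.05, 0.95)),
    seed = cfg$seed
  )
  # plant the selection gene
  rownames(sim$counts)[1] <- cfg$scrna$select_gene
  sim$truth$gene[1] <- cfg$scrna$select_gene
  nl <- normalize_and_log(sim$counts)
  pop <- select_population(nl, cfg$scrna$select_gene, cfg$scrna$threshold,
                           cfg$scrna$direction)
  panel <- sim$truth$gene[2:11]
  prev <- gene_prevalence(pop, panel, cfg$scrna$threshold, cfg$scrna$direction)
  list(
    n_cells_selected = attr(pop, "n_selected"),
    prevalence = dplyr::left_join(
      prev,
      dplyr::rename(sim$truth[, c("gene", "prevalence")], planted = "prevalence"),
      by = "gene"
    )
  )
}

#' Write a pipeline report to JSON
#'
#' @param report A `tone_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tone_report"))
  jsonlite::write_json(
    list(experiment = report$experiment, results = report$results,
         provenance = report$provenance, warnings = report$warnings),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  invisible(path)
}
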