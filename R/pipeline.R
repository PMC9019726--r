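#' Default end-to-end pipeline configuration
#'
#' A nested list with one section per stage; every value can be overridden
#' by [modifyList()]-style partial configs passed to [run_pipeline()].
#'
#' @param seed integer seed for all stochastic stages
#' @return named list (sections `simulate`, `foci`, `response`, `paths`)
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(preset = "hb_like", direction = "ltd",
                    n_embryos = 8L, n_controls = 8L, shift_time = 5,
                    duration = NULL, n_nuclei = 140,
                    frame_interval = 0.5, focus_visible_prob = 0.98,
                    foci_amplitude = 800),
    foci = list(roi = c(0, 150, 10, 50), field = c(150, 60),
                filter_sigma = 0.3, threshold_k = 5),
    response = list(window = 5L, exclusion_threshold = 0.25),
    paths = list(out_dir = NULL, manifest = NULL))
}

#' Validate a pipeline configuration
#'
#' Pure check: returns a character vector of problems (empty when valid),
#' never mutates or errors.
#'
#' @param config a config list as from [default_config()]
#' @return character vector of problem descriptions
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  sim <- config$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$frame_interval) && sim$frame_interval <= 0)
      add("simulate$frame_interval must be > 0")
    if (!is.null(sim$n_embryos) && sim$n_embryos < 1)
      add("simulate$n_embryos must be >= 1")
    if (!is.null(sim$shift_time) && sim$shift_time <= 0)
      add("simulate$shift_time must be > 0")
    if (!is.null(sim$preset) &&
        !sim$preset %in% c("hb_like", "gt_like", "Kr_like", "kni_like"))
      add("simulate$preset is not a known gene preset")
    if (!is.null(sim$focus_visible_prob) &&
        (sim$focus_visible_prob < 0 || sim$focus_visible_prob > 1))
      add("simulate$focus_visible_prob must be in [0, 1]")
  }
  fo <- config$foci
  if (!is.null(fo$roi) && !is.null(fo$field)) {
    if (fo$roi[1] < 0 || fo$roi[3] < 0 ||
        fo$roi[2] > fo$field[1] || fo$roi[4] > fo$field[2])
      add("foci$roi extends outside foci$field")
  }
  re <- config$response
  if (!is.null(re$window) &&
      (re$window < 3 || re$window %% 2 == 0))
    add("response$window must be an odd integer >= 3")
  if (!is.null(re$exclusion_threshold) &&
      (re$exclusion_threshold < 0 || re$exclusion_threshold > 1))
    add("response$exclusion_threshold must be in [0, 1]")
  if (!is.null(config$paths$manifest) &&
      !file.exists(config$paths$manifest))
    add(sprintf("manifest file does not exist: %s", config$paths$manifest))
  problems
}

#' Run the simulate -> response-time pipeline end to end
#'
#' Simulates a perturbation + control cohort with the configured preset,
#' runs the full response-time workflow, and writes per-embryo trace CSVs,
#' a per-embryo results CSV, a cohort summary JSON and a provenance record
#' to the output directory. Deterministic for a fixed `(config, seed)`.
#' A stage failure aborts with the failing stage named and leaves a
#' `FAILED` marker in the output directory.
#'
#' @param config partial config list; merged over [default_config()]
#' @param out_dir output directory (overrides `config$paths$out_dir`)
#' @return list: `summary` (cohort summary), `results`, `out_dir`, invisibly
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir)) cfg$paths$out_dir <- out_dir
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir <- cfg$paths$out_dir
  if (is.null(dir)) dir <- tempfile("optoembryo_run_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- cfg$simulate
  cohort <- stage("simulate", simulate_response_cohort(
    sim$preset, sim$direction, n_embryos = sim$n_embryos,
    n_controls = sim$n_controls, shift_time = sim$shift_time,
    duration = sim$duration, seed = cfg$seed, n_nuclei = sim$n_nuclei,
    frame_interval = sim$frame_interval,
    focus_visible_prob = sim$focus_visible_prob,
    foci_amplitude = sim$foci_amplitude))

  stage("write_traces", {
    for (i in seq_along(cohort$embryos))
      write_foci_trace(cohort$embryos[[i]],
                       file.path(dir, sprintf("embryo_%02d.csv", i)))
    for (i in seq_along(cohort$controls))
      write_foci_trace(cohort$controls[[i]],
                       file.path(dir, sprintf("control_%02d.csv", i)))
  })

  ana <- stage("response_time", analyze_response_cohort(
    cohort$embryos, cohort$controls, cohort$shift_time,
    cohort$expected_sign, window = cfg$response$window,
    threshold = cfg$response$exclusion_threshold))

  stage("write_results", {
    res_df <- do.call(rbind, lapply(ana$results, function(r) data.frame(
      embryo_id = r$embryo_id, response_time_min = r$response_time,
      included = r$included, max_abs_difference = r$max_abs_difference,
      control_peak = r$control_peak,
      exclusion_reason = if (is.null(r$exclusion_reason)) ""
      else r$exclusion_reason)))
    utils::write.csv(res_df, file.path(dir, "response_times.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ana$summary, file.path(dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_file <- file.path(dir, "config.json")
    jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    prov <- list(
      package = "optoembryo",
      version = as.character(utils::packageVersion("optoembryo")),
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      stages = c("simulate", "write_traces", "response_time",
                 "write_results"),
      true_delay_min = cohort$true_delay)
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(summary = ana$summary, results = ana$results,
                 out_dir = dir))
}
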