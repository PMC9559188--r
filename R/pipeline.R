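# End-to-end pipeline: cohort (read+filter or simulate) -> screen ->
# weights -> stage -> nomogram -> validate, with a machine-readable manifest.

.pipeline_stages <- c("cohort", "screen", "weights", "stage", "nomogram",
                      "validate")

#' Build and validate a pipeline configuration
#'
#' @param config A list, or path to a JSON file, with elements:
#'   * `cohort_path` (+ optional `dialect`) **or** `simulate` (arguments for
#'     [simulation_config()]) -- exactly one source is required;
#'   * `seed` integer (default 1), used for splitting and bootstraps (a
#'     simulated cohort uses `simulate$seed`, defaulting to `seed`);
#'   * `out_dir` output directory (default `"dr_run"`);
#'   * optional `bin_centers`, `half_width`, `upper_r`, `min_subgroup`,
#'     `min_bin`, `alpha`, `split_ratio`, `c_boot`, `cal_boot`, `groups`,
#'     `horizons`.
#' @return Validated config list of class `dr_pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  has_path <- !is.null(config$cohort_path)
  has_sim <- !is.null(config$simulate)
  if (!xor(has_path, has_sim))
    stop("configuration error: exactly one of cohort_path or simulate required",
         call. = FALSE)
  defaults <- list(seed = 1L, out_dir = "dr_run", bin_centers = 1:15,
                   half_width = 1, upper_r = 10, min_subgroup = 20,
                   min_bin = 100, alpha = 0.05, split_ratio = c(2, 1),
                   c_boot = 200, cal_boot = 1000, groups = 3,
                   horizons = c(3, 5, 10))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (has_path && !file.exists(config$cohort_path))
    stop("configuration error: cohort_path not found: ", config$cohort_path,
         call. = FALSE)
  structure(config, class = c("dr_pipeline_config", "list"))
}

# stable hash of the configuration (md5 of its canonical JSON)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full DR pipeline
#'
#' Executes read/filter (or simulate) -> screen -> fit-weights -> stage ->
#' fit-nomogram -> validate, writing every intermediate artifact plus a
#' machine-readable manifest (`manifest.json`: package version, seed, config
#' hash, completed stages) into the output directory.  Any stage error
#' aborts with the stage name; artifacts of completed stages are preserved.
#'
#' @param config A [pipeline_config()] (or list / JSON path accepted by it).
#' @param quiet Suppress progress messages.
#' @return The output directory path, invisibly, with the collected results
#'   as attribute `results`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(package = "drbilat",
                   version = as.character(packageVersion("drbilat")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   config_hash = .config_hash(config),
                   stages = character())
  results <- list()
  stage <- function(name, expr) {
    say("[", name, "]")
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  }

  cohort <- stage("cohort", {
    co <- if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path, dialect = config$dialect)
    } else {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      simulate_cohort(do.call(simulation_config, sim_args))
    }
    co <- apply_eligibility_filters(co)
    write_cohort(co, file.path(config$out_dir, "cohort.tsv"))
    rep <- attr(co, "exclusion_report")
    jsonlite::write_json(rep, file.path(config$out_dir, "exclusions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    co
  })

  screening <- stage("screen", {
    sc <- screen_variables(cohort, alpha = config$alpha)
    write.table(sc$table, file.path(config$out_dir, "screening.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(selected = sc$selected, skipped = sc$skipped,
                              variable_p = sc$variable_p),
                         file.path(config$out_dir, "screening.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sc
  })

  weights <- stage("weights", {
    w <- fit_all_weights(cohort, centers = config$bin_centers,
                         half_width = config$half_width,
                         upper_r = config$upper_r,
                         min_subgroup = config$min_subgroup,
                         min_bin = config$min_bin)
    weights_to_json(w, file.path(config$out_dir, "weights.json"))
    for (v in names(w)) {
      s <- w[[v]]$series
      write.table(as.data.frame(s[, c("center", "count", "raw_wp", "sparse")]),
                  file.path(config$out_dir, sprintf("weights_%s.tsv", v)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    w
  })

  staged <- stage("stage", {
    st <- stage_cohort(cohort, weights)
    write.table(as.data.frame(st),
                file.path(config$out_dir, "staged.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    st
  })

  model_split <- stage("nomogram", {
    sp <- split_cohort(staged, seed = config$seed, ratio = config$split_ratio)
    # split_cohort returns plain cohorts; staging columns travel with rows
    model <- fit_dr_nomogram(sp$training, horizons = config$horizons)
    nomogram_to_json(model, file.path(config$out_dir, "nomogram.json"))
    list(model = model, split = sp)
  })

  validation <- stage("validate", {
    val <- lapply(list(training = model_split$split$training,
                       validation = model_split$split$validation),
                  function(part)
                    validate_nomogram(model_split$model, part,
                                      horizons = config$horizons,
                                      groups = config$groups,
                                      n_boot_c = config$c_boot,
                                      n_boot_cal = config$cal_boot,
                                      seed = config$seed))
    jsonlite::write_json(
      lapply(val, function(v) list(
        c_index = v$c_index,
        calibration = lapply(v$calibration, as.data.frame))),
      file.path(config$out_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    val
  })

  results <- list(cohort = cohort, screening = screening, weights = weights,
                  staged = staged, nomogram = model_split$model,
                  split = model_split$split, validation = validation,
                  manifest = manifest)
  say("pipeline complete: ", config$out_dir)
  invisible(structure(config$out_dir, results = results))
}
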