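#' Default run configuration
#'
#' Every tunable of the pipeline is a named key here; [run_sds_pipeline()]
#' rejects unknown keys so configs round-trip losslessly through YAML.
#'
#' @param seed master seed, forwarded to the synthetic city when simulating.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = TRUE,              # generate a synthetic city (no input paths needed)
    paths = list(poi = NULL, visits = NULL, complaints = NULL, covariates = NULL),
    city = list(),                # overrides forwarded to city_config()
    scoring = list(min_baseline = 4L, log_base = 10, stratified_baseline = FALSE),
    analysis = list(
      indicators = c("covid_case_rate", "vaccination_rate"),
      share_col = "nonhispanic_white_pct",
      police_low = 0.3, police_high = 0.6
    ),
    out_dir = "sds_results"
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown top-level or nested keys are rejected; missing keys take their
#' defaults from [default_run_config()].
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  merge_run_config(raw)
}

#' @rdname read_run_config
#' @param overrides named list of overrides on top of the defaults.
#' @export
merge_run_config <- function(overrides = list()) {
  cfg <- unclass(default_run_config())
  .merge_checked <- function(base, over, prefix = "") {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]]) && k != "city") {
        base[[k]] <- .merge_checked(base[[k]], over[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  cfg <- .merge_checked(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full sensitivity pipeline
#'
#' Orchestrates simulate (or load) -> pool -> bin -> flag -> score ->
#' neighborhood analysis as one reproducible run. All stage outputs are
#' written as CSV to `config$out_dir`, the filter ledger as JSON, and a run
#' manifest (config hash, output file hashes, package version, per-stage row
#' counts, wall timestamps) is written last. A hard error in any stage aborts
#' with a message naming the stage, after writing a partial manifest.
#'
#' @param config a `run_config` list from [default_run_config()],
#'   [merge_run_config()] or [read_run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly.
#' @export
run_sds_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  t0 <- Sys.time()
  if (!inherits(config, "run_config")) config <- merge_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ledger <- new_ledger()
  manifest <- list(package_version = as.character(utils::packageVersion("sdsens")),
                   config = config[setdiff(names(config), "out_dir")],
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  manifest$config_hash <- .hash_obj(manifest$config)

  fail <- function(stage, e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    .write_manifest(manifest, out_dir)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)

  # --- stage: inputs --------------------------------------------------------
  stage <- "inputs"
  inputs <- tryCatch({
    if (isTRUE(config$simulate)) {
      say("simulating synthetic city")
      cfg <- do.call(city_config, c(config$city, list(seed = config$seed)))
      city <- generate_city(cfg)
      utils::write.csv(city$poi, file.path(out_dir, "poi.csv"), row.names = FALSE)
      utils::write.csv(.iso_ts(city$visits), file.path(out_dir, "visits.csv"),
                       row.names = FALSE)
      utils::write.csv(.iso_ts(city$complaints), file.path(out_dir, "complaints.csv"),
                       row.names = FALSE)
      utils::write.csv(city$covariates, file.path(out_dir, "covariates.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(theta = city$ground_truth$theta,
             n_complaints = nrow(city$complaints)),
        file.path(out_dir, "ground_truth.json"), dataframe = "columns",
        auto_unbox = TRUE, digits = NA)
      city[c("poi", "visits", "complaints", "covariates")]
    } else {
      say("loading input tables")
      tabs <- load_tables(config$paths$poi, config$paths$visits,
                          config$paths$complaints, ledger = ledger)
      covariates <- if (!is.null(config$paths$covariates))
        utils::read.csv(config$paths$covariates, stringsAsFactors = FALSE) else NULL
      c(tabs[c("poi", "visits", "complaints")], list(covariates = covariates))
    }
  }, error = function(e) fail(stage, e))
  manifest$stages$inputs <- list(n_pois = nrow(inputs$poi),
                                 n_visit_rows = nrow(inputs$visits),
                                 n_complaints = nrow(inputs$complaints))

  # --- stage: ingest --------------------------------------------------------
  stage <- "ingest"
  ingested <- tryCatch({
    say("pooling to buildings and binning to six-hour intervals")
    pooled <- pool_to_buildings(inputs$poi, inputs$visits, ledger = ledger)
    intervals <- bin_six_hour(pooled$visits, pooled$units)
    intervals <- flag_complaints(intervals, inputs$complaints, ledger = ledger)
    list(units = pooled$units, intervals = intervals)
  }, error = function(e) fail(stage, e))
  manifest$stages$ingest <- list(n_units = nrow(ingested$units),
                                 n_intervals = nrow(ingested$intervals))

  # --- stage: score ---------------------------------------------------------
  stage <- "score"
  fit <- tryCatch({
    say("fitting sensitivity scores")
    sc <- config$scoring
    sds_fit(ingested$intervals, ingested$units,
            min_baseline = sc$min_baseline, log_base = sc$log_base,
            stratified_baseline = sc$stratified_baseline, ledger = ledger)
  }, error = function(e) fail(stage, e))
  utils::write.csv(fit$estimates, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$zip_scores, file.path(out_dir, "zip_scores.csv"),
                   row.names = FALSE)
  curves <- citywide_complaint_curves(fit$intervals)
  curves$interval_start <- format(curves$interval_start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
  ts_tab <- type_summary(fit, inputs$complaints, ingested$units)
  utils::write.csv(ts_tab, file.path(out_dir, "type_summary.csv"), row.names = FALSE)
  manifest$stages$score <- list(n_scored_units = nrow(fit$estimates),
                                n_scored_zips = nrow(fit$zip_scores))

  # --- stage: neighborhoods -------------------------------------------------
  stage <- "neighborhoods"
  tryCatch({
    say("neighborhood disparity analysis")
    grouping <- classify_quartiles(fit$zip_scores)
    utils::write.csv(grouping$groups, file.path(out_dir, "quartiles.csv"),
                     row.names = FALSE)
    if (!is.null(inputs$covariates)) {
      gc_res <- compare_groups(grouping, inputs$covariates)
      utils::write.csv(gc_res$anova, file.path(out_dir, "group_comparison.csv"),
                       row.names = FALSE)
      inds <- intersect(config$analysis$indicators, names(inputs$covariates))
      if (length(inds) > 0) {
        utils::write.csv(
          correlate_indicators(fit$zip_scores, inputs$covariates, inds),
          file.path(out_dir, "correlations.csv"), row.names = FALSE)
      }
      if ("police_action" %in% names(inputs$complaints) &&
          config$analysis$share_col %in% names(inputs$covariates)) {
        rates <- police_action_rates(inputs$complaints, ingested$units)
        pc <- compare_police_by_group(rates, grouping, inputs$covariates,
                                      share_col = config$analysis$share_col,
                                      low = config$analysis$police_low,
                                      high = config$analysis$police_high)
        utils::write.csv(pc, file.path(out_dir, "police_comparison.csv"),
                         row.names = FALSE)
      }
    }
  }, error = function(e) fail(stage, e))

  # --- manifest -------------------------------------------------------------
  led_df <- as.data.frame(ledger)
  jsonlite::write_json(led_df, file.path(out_dir, "ledger.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest$ledger = led_df
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest$output_hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$output_hashes) <- files
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

# format POSIXct columns as ISO-8601 for CSV output
.iso_ts <- function(df) {
  for (k in names(df)) {
    if (inherits(df[[k]], "POSIXct")) df[[k]] <- format(df[[k]], "%Y-%m-%dT%H:%M:%S")
  }
  df
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, dataframe = "rows",
                       digits = NA, pretty = TRUE)
}

#' Render a plain-text summary report for a completed run
#'
#' Assembles the CSV outputs of [run_sds_pipeline()] into a single markdown
#' document: score summary, per-type table, quartile table, covariate ANOVA,
#' health-indicator correlations, police-action comparison, and the filter
#' ledger. Sections whose output file is missing are marked "not computed".
#'
#' @param results_dir directory written by [run_sds_pipeline()].
#' @param out_file output path (default `report.md` inside `results_dir`).
#' @return the path to the report, invisibly. Attribute `missing` lists the
#'   sections that could not be rendered.
#' @export
render_report <- function(results_dir, out_file = file.path(results_dir, "report.md")) {
  if (!dir.exists(results_dir)) stop("results directory not found: ", results_dir)
  sections <- list(
    c("Per-unit thresholds (head)", "thresholds.csv"),
    c("Zip-level scores", "zip_scores.csv"),
    c("Establishment-type summary", "type_summary.csv"),
    c("Sensitivity quartiles", "quartiles.csv"),
    c("Covariate comparison (ANOVA)", "group_comparison.csv"),
    c("Health indicator correlations", "correlations.csv"),
    c("Police action comparison", "police_comparison.csv")
  )
  lines <- c("# Social distancing sensitivity run report", "")
  missing <- character()
  for (s in sections) {
    lines <- c(lines, paste("##", s[1]), "")
    f <- file.path(results_dir, s[2])
    if (!file.exists(f)) {
      lines <- c(lines, "*not computed*", "")
      missing <- c(missing, s[2])
      next
    }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (s[2] == "thresholds.csv") df <- utils::head(df, 10)
    lines <- c(lines, .md_table(df), "")
  }
  lf <- file.path(results_dir, "ledger.json")
  lines <- c(lines, "## Filter ledger", "")
  if (file.exists(lf)) {
    led <- jsonlite::fromJSON(lf)
    lines <- c(lines, if (length(led) > 0) .md_table(as.data.frame(led)) else "*empty*", "")
  } else {
    lines <- c(lines, "*not computed*", "")
    missing <- c(missing, "ledger.json")
  }
  writeLines(lines, out_file)
  structure(invisible(out_file), missing = missing)
}

.md_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  cells <- rbind(names(df), rep("---", ncol(df)), apply(df, 2, as.character))
  apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
}
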