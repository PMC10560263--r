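#' Pipeline run configuration
#'
#' Gathers everything one end-to-end run needs: the scene (a
#' [scene_config()] to synthesize, or a directory of scene files), the
#' travel scenarios, the coverage thresholds, which facility sets to
#' evaluate, the referral mode, and the staffing benchmark. File paths are
#' validated before any computation; nothing is written on validation
#' failure.
#'
#' @param scene a `scene_config` or a directory written by
#'   [scene_to_disk()].
#' @param scenarios named list of `travel_scenario` objects or YAML paths.
#' @param thresholds coverage thresholds in minutes.
#' @param facility_sets subset of `c("hp_and_hc", "hc_only")`.
#' @param referral_scenario name of the (walking) scenario used for
#'   referrals.
#' @param referral_mode `"cross_district"` or `"within_district"`.
#' @param benchmark a `staffing_benchmark` or a YAML path.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(),
                       scenarios = default_scenarios(),
                       thresholds = c(60, 120, 180),
                       facility_sets = c("hp_and_hc", "hc_only"),
                       referral_scenario = "walking_only",
                       referral_mode = "cross_district",
                       benchmark = default_benchmark()) {
  stopifnot(all(facility_sets %in% c("hp_and_hc", "hc_only")))
  structure(list(scene = scene, scenarios = scenarios,
                 thresholds = thresholds, facility_sets = facility_sets,
                 referral_scenario = referral_scenario,
                 referral_mode = referral_mode, benchmark = benchmark),
            class = "run_config")
}

validate_run_config <- function(config) {
  if (is.character(config$scene) && !dir.exists(config$scene))
    stop("scene directory does not exist: ", config$scene)
  for (s in config$scenarios)
    if (is.character(s) && !file.exists(s))
      stop("scenario file does not exist: ", s)
  if (is.character(config$benchmark) && !file.exists(config$benchmark))
    stop("benchmark file does not exist: ", config$benchmark)
  if (!config$referral_scenario %in% names(config$scenarios))
    stop("referral_scenario not among the configured scenarios")
  invisible(config)
}

load_run_inputs <- function(config) {
  scene <- if (is.character(config$scene)) scene_from_disk(config$scene)
           else generate_scene(config$scene)
  scenarios <- lapply(config$scenarios, function(s)
    if (is.character(s)) read_scenario(s) else s)
  benchmark <- if (is.character(config$benchmark))
    read_benchmark(config$benchmark) else config$benchmark
  list(scene = scene, scenarios = scenarios, benchmark = benchmark)
}

#' Run the full accessibility and workforce pipeline
#'
#' Stages: scene (synthesize or load) -> merged landcover + facility
#' snapping -> accumulated cost surfaces per scenario and facility set ->
#' coverage reports -> HP-to-HC referrals (walking scenario) -> workforce
#' scoring (HC staffing vs minima, group densities vs required densities,
#' HEW gaps per district). All tabular outputs are written as CSV and all
#' rasters as ASCII grids under `out_dir`, and a JSON manifest records the
#' config, package version, per-stage wall times and the SHA-256 of every
#' output file. Rerunning with an identical config reproduces identical
#' files. Any stage error aborts the run with the stage name; no manifest
#' is written for a failed run.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr),
                    error = function(e) stop(sprintf("stage '%s' failed: %s",
                                                     name, conditionMessage(e)),
                                             call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_asc <- function(r, name) {
    write_asc(r, file.path(out_dir, name))
    files <<- c(files, name)
  }

  inp <- stage("inputs", load_run_inputs(config))
  scene <- inp$scene

  prep <- stage("geoprep", {
    merged <- build_merged_landcover(scene$landcover, scene$roads,
                                     scene$rivers, scene$lakes, scene$grid)
    fac <- snap_facilities(scene$facilities, merged)
    list(merged = merged, facilities = fac)
  })
  emit_asc(prep$merged$classes, "merged_landcover.asc")
  emit_csv(prep$facilities[, c("facility_id", "snapped", "snap_distance_m")],
           "snap_log.csv")

  fac_sets <- lapply(config$facility_sets, function(fs)
    if (fs == "hc_only") prep$facilities[prep$facilities$type == "HC", ]
    else prep$facilities)
  names(fac_sets) <- config$facility_sets

  surfaces <- list(); coverage <- list()
  for (sc_name in names(inp$scenarios)) {
    for (fs in config$facility_sets) {
      key <- paste(sc_name, fs, sep = ".")
      cs <- stage(paste0("accessibility:", key),
                  accumulate_cost(prep$merged, scene$dem,
                                  inp$scenarios[[sc_name]], fac_sets[[fs]]))
      surfaces[[key]] <- cs
      emit_asc(cs$travel_time, sprintf("travel_time_%s_%s.asc", sc_name, fs))
      emit_asc(cs$allocation, sprintf("allocation_%s_%s.asc", sc_name, fs))
      cov <- stage(paste0("coverage:", key),
                   zonal_coverage(cs, scene$population, scene$districts,
                                  config$thresholds))
      coverage[[key]] <- cov
      emit_csv(cov$per_zone, sprintf("coverage_zones_%s_%s.csv", sc_name, fs))
      emit_csv(cov$overall, sprintf("coverage_overall_%s_%s.csv", sc_name, fs))
      emit_csv(cov$per_facility,
               sprintf("coverage_facilities_%s_%s.csv", sc_name, fs))
      for (nm in names(cov$uncovered))
        emit_asc(cov$uncovered[[nm]],
                 sprintf("uncovered_pop_%s_%s_%s.asc", sc_name, fs, nm))
    }
  }

  referrals <- stage("referral",
    build_referrals(prep$facilities, prep$merged, scene$dem,
                    inp$scenarios[[config$referral_scenario]],
                    mode = config$referral_mode,
                    districts = scene$districts))
  ref_out <- referrals
  ref_out$time_hm <- format_travel_time(ref_out$time_min)
  emit_csv(ref_out, "referrals.csv")

  wf_cov_hc <- coverage[[paste(config$referral_scenario, "hc_only", sep = ".")]]
  wf_cov_all <- coverage[[paste(config$referral_scenario, "hp_and_hc", sep = ".")]]
  workforce <- stage("workforce", {
    staffing <- score_hc_staffing(prep$facilities, inp$benchmark)
    dens <- if (!is.null(wf_cov_hc))
      group_density(prep$facilities, wf_cov_hc, inp$benchmark,
                    thresholds = intersect(c(60, 120), config$thresholds))
    hew <- if (!is.null(wf_cov_all))
      hew_gap(prep$facilities, wf_cov_all, inp$benchmark, scene$districts)
    list(staffing = staffing, density = dens, hew = hew)
  })
  emit_csv(workforce$staffing$per_cadre, "staffing_per_cadre.csv")
  emit_csv(workforce$staffing$per_hc, "staffing_per_hc.csv")
  if (!is.null(workforce$density)) {
    emit_csv(workforce$density$per_group, "workforce_density.csv")
    emit_csv(workforce$density$per_zone, "workforce_needs_zones.csv")
  }
  if (!is.null(workforce$hew))
    emit_csv(workforce$hew$per_zone, "hew_gap_zones.csv")

  manifest <- list(
    package = "hfaccess",
    version = as.character(utils::packageVersion("hfaccess")),
    config = serialize_config(config),
    stage_seconds = timings,
    n_products = length(surfaces),
    files = lapply(stats::setNames(files, files), function(f)
      digest::digest(file.path(out_dir, f), algo = "sha256", file = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scene = scene, merged = prep$merged,
                 facilities = prep$facilities, surfaces = surfaces,
                 coverage = coverage, referrals = referrals,
                 workforce = workforce, benchmark = inp$benchmark,
                 config = config, manifest = manifest, out_dir = out_dir))
}

# config echo for the manifest (objects summarized, paths kept)
serialize_config <- function(config) {
  list(scene = if (is.character(config$scene)) config$scene
       else unclass(config$scene),
       scenarios = lapply(config$scenarios, function(s)
         if (is.character(s)) s else s$name),
       thresholds = config$thresholds,
       facility_sets = config$facility_sets,
       referral_scenario = config$referral_scenario,
       referral_mode = config$referral_mode,
       benchmark = if (is.character(config$benchmark)) config$benchmark
       else "inline")
}

#' Headline summary of a pipeline run
#'
#' One row per scenario, facility set and threshold with the percentage of
#' the population uncovered, plus the referral and workforce headline
#' numbers. Every value is recomputed from the stage results carried in
#' the run object, so the summary always agrees with the written CSVs.
#'
#' @param run the list returned by [run_pipeline()].
#' @return list with `coverage` (data.frame), `referral` (list),
#'   `workforce` (list).
#' @export
summarize_run <- function(run) {
  if (is.null(run$coverage) || is.null(run$referrals))
    stop("incomplete run: missing stage results")
  cov_tab <- do.call(rbind, lapply(names(run$coverage), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ov <- run$coverage[[key]]$overall
    data.frame(scenario = parts[1], facility_set = parts[2],
               threshold_min = ov$threshold_min,
               pct_covered = round(ov$pct_covered, 1),
               pct_uncovered = round(100 - ov$pct_covered, 1),
               stringsAsFactors = FALSE)
  }))
  ref <- referral_summary(run$referrals)
  wf <- run$workforce
  list(coverage = cov_tab,
       referral = list(mean_time_min = ref$mean_time_min,
                       mean_time_hm = format_travel_time(ref$mean_time_min),
                       max_time_min = ref$max_time_min,
                       share_beyond_comprehensive = ref$share_beyond_comprehensive,
                       n_unreachable = ref$n_unreachable),
       workforce = list(
         n_fully_adequate_hc = sum(wf$staffing$per_hc$fully_adequate),
         total_hew_shortage = if (!is.null(wf$hew)) wf$hew$total_shortage,
         total_hew_surplus = if (!is.null(wf$hew)) wf$hew$total_surplus))
}
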