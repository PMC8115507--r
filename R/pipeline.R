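# End-to-end pipeline: simulate both scenarios, calibrate the ponding
# threshold, compute Wetness Index cubes, stream masks, exceedance maps,
# coverage series with monthly statistics, stability classifications, and
# the scenario summary table; write every artifact plus a JSON manifest.

config_params <- function(config) {
  bucket_params(
    store_capacity = unlist(config$bucket$store_capacity),
    drainage_coeff = unlist(config$bucket$drainage_coeff),
    et_coeff = config$bucket$et_coeff,
    slope_drainage_gain = config$bucket$slope_drainage_gain,
    riparian_floor = config$bucket$riparian_floor,
    baseflow_mm = config$bucket$baseflow_mm,
    drainage_sd = config$bucket$drainage_sd,
    initial_saturation = config$bucket$initial_saturation,
    seed = config$seed
  )
}

config_schedule <- function(config, enabled) {
  irrigation_schedule(
    group_a = config$irrigation$group_a, group_b = config$irrigation$group_b,
    turn_length = config$irrigation$turn_length,
    daily_depth = config$irrigation$daily_depth,
    hours_per_day = config$irrigation$hours_per_day,
    active_months = config$irrigation$active_months,
    enabled = enabled
  )
}

#' Simulate the baseline and irrigation scenarios
#'
#' Builds the synthetic domain and forcing from the configuration, then runs
#' the bucket model twice with identical domain, forcing, parameters, and
#' seed: once with irrigation disabled (baseline) and once with the rotating
#' dry-season scheme enabled.
#'
#' @param config Configuration list (see [default_config()]).
#' @return List with `domain`, `forcing`, `seasons`, and per-scenario lists
#'   `baseline` / `irrigation`, each holding `saturation`, `flow`, and
#'   `mass_balance`.
#' @export
simulate_scenarios <- function(config = default_config()) {
  domain <- make_domain(config$domain$n_rows, config$domain$n_cols,
                        seed = config$seed,
                        farm_fraction = config$domain$farm_fraction,
                        cell_size = config$domain$cell_size)
  forcing <- make_forcing(make_dates(config$year), seed = config$seed,
                          rainy_months = config$forcing$rainy_months,
                          annual_total_mm = config$forcing$annual_total_mm)
  params <- config_params(config)
  list(
    domain = domain, forcing = forcing,
    seasons = season_definition(config$seasons$dry_months,
                                config$seasons$rainy_months),
    baseline = run_bucket_model(domain, forcing,
                                config_schedule(config, FALSE), params),
    irrigation = run_bucket_model(domain, forcing,
                                  config_schedule(config, TRUE), params)
  )
}

#' Run the full habitat-mapping pipeline
#'
#' Simulation, threshold calibration (or a fixed theta), Wetness Index
#' computation, stream masking, exceedance maps for every (T, period,
#' scenario) combination, inside-farm coverage series with monthly means and
#' per-month Welch tests, stability classification inside farms, and the
#' scenario summary table with rank-sum p-values. When `out_dir` is given,
#' every artifact is written there and listed with MD5 checksums in
#' `manifest.json`.
#'
#' @param config Configuration list (see [default_config()], [read_config()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of in-memory results: `theta`, `calibration`, `survey`,
#'   `mask`, `summary`, `stability`, `coverage`, `monthly`, `monthly_tests`,
#'   `mass_balance`, and (when written) `files`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  sim <- simulate_scenarios(config)
  seasons <- sim$seasons
  comparator <- config$comparator
  files <- character(0)
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path, if (file.exists(sidecar_path(path)))
      sidecar_path(path))
    invisible(path)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(out_dir, 2) != 0) stop("output directory not writable: ",
                                           out_dir)
  }

  # --- survey + threshold -------------------------------------------------
  survey <- make_survey(sim$baseline$saturation, sim$domain,
                        theta_true = config$survey$theta_true,
                        n_points = config$survey$n_points,
                        seed = config$seed,
                        frac_excluded_types = config$survey$frac_excluded_types,
                        grid_step = config$calibration$theta_grid_step,
                        seasons = seasons)
  calibration <- NULL
  if (identical(config$theta, "calibrate")) {
    usable <- filter_survey(survey)
    calibration <- calibrate_theta(
      sim$baseline$saturation, usable,
      theta_grid_step = config$calibration$theta_grid_step,
      n_bootstrap = config$calibration$n_bootstrap,
      seed = config$seed, seasons = seasons)
    theta <- calibration$theta_star
  } else {
    theta <- as.numeric(config$theta)
  }

  # --- WI, masks ----------------------------------------------------------
  wi <- list(BASELINE = compute_wi(sim$baseline$saturation, theta),
             IRRIGATION = compute_wi(sim$irrigation$saturation, theta))
  mask <- stream_mask(sim$baseline$flow, config$mask$q_threshold,
                      config$mask$persistence) |
    stream_mask(sim$irrigation$flow, config$mask$q_threshold,
                config$mask$persistence)
  stat_mask <- if (isTRUE(config$mask$apply_to_stats)) mask else NULL

  # --- exceedance maps and summary table ----------------------------------
  inside <- sim$domain$farm_id > 0
  outside <- sim$domain$farm_id == 0
  summary_rows <- list()
  for (T in config$T_list) {
    for (period in c("YEAR", "DRY", "RAINY")) {
      maps <- lapply(wi, exceedance_probability, T = T, period = period,
                     seasons = seasons, mask = stat_mask)
      for (scen in names(maps)) {
        emit(write_exceedance_map, maps[[scen]],
             sprintf("exceedance_T%02d_%s_%s.csv", T, tolower(period),
                     tolower(scen)))
      }
      for (reg in c("INSIDE_FARMS", "OUTSIDE_FARMS")) {
        cells <- if (reg == "INSIDE_FARMS") inside else outside
        summary_rows[[length(summary_rows) + 1L]] <-
          summarize_exceedance(maps$BASELINE, maps$IRRIGATION, cells,
                               region_label = reg)
      }
    }
  }
  summary <- do.call(rbind, summary_rows)

  # --- coverage inside farms ----------------------------------------------
  farm_cells <- if (is.null(stat_mask)) which(inside) else
    which(inside & !mask)
  coverage <- list(); monthly <- list(); monthly_tests <- list()
  for (T in config$T_list) {
    cov <- lapply(wi, coverage_series, T = T, region_cells = farm_cells,
                  comparator = comparator)
    key <- sprintf("T%02d", T)
    coverage[[key]] <- cov
    monthly[[key]] <- lapply(cov, monthly_mean_coverage)
    monthly_tests[[key]] <- do.call(rbind, lapply(1:12, function(m) {
      tst <- monthly_coverage_test(cov$BASELINE, cov$IRRIGATION, m)
      data.frame(T = T, month = m, t_stat = tst$t_stat,
                 p_value = tst$p_value,
                 significant_at_0.01 = tst$significant_at_0.01)
    }))
    for (scen in names(cov)) {
      emit(function(obj, path) data.table::fwrite(obj, path), cov[[scen]],
           sprintf("coverage_%s_%s.csv", key, tolower(scen)))
      emit(function(obj, path) data.table::fwrite(obj, path),
           monthly[[key]][[scen]],
           sprintf("monthly_coverage_%s_%s.csv", key, tolower(scen)))
    }
    emit(function(obj, path) data.table::fwrite(obj, path),
         monthly_tests[[key]], sprintf("monthly_tests_%s.csv", key))
  }

  # --- stability inside farms ---------------------------------------------
  farm_mask <- mask | !inside
  stability <- lapply(wi, function(w) {
    classify_stability(max_ponding_duration(w), mask = farm_mask)
  })
  for (scen in names(stability)) {
    emit(function(obj, path) data.table::fwrite(obj$histogram, path),
         stability[[scen]],
         sprintf("stability_histogram_%s.csv", tolower(scen)))
  }

  # --- write remaining artifacts and manifest ------------------------------
  if (!is.null(out_dir)) {
    dom_files <- write_domain(sim$domain, file.path(out_dir, "domain"))
    files <- c(files, unname(dom_files))
    emit(write_survey, survey, "survey.csv")
    if (!is.null(calibration)) {
      emit(write_calibration, calibration, "calibration.json")
    }
    emit(function(obj, path) data.table::fwrite(obj, path), summary,
         "scenario_summary.csv")
    emit(write_grid_layer, mask * 1L, "stream_mask.csv")
    if (isTRUE(config$output$write_cubes)) {
      emit(write_cube, sim$baseline$saturation, "saturation_baseline.csv")
      emit(write_cube, sim$irrigation$saturation, "saturation_irrigation.csv")
      emit(write_cube, sim$baseline$flow, "flow_baseline.csv")
      emit(write_cube, sim$irrigation$flow, "flow_irrigation.csv")
      emit(write_cube, wi$BASELINE, "wi_baseline.csv")
      emit(write_cube, wi$IRRIGATION, "wi_irrigation.csv")
    }
    config_path <- file.path(out_dir, "config.yaml")
    write_config(config, config_path)
    files <- c(files, config_path)
    manifest_path <- file.path(out_dir, "manifest.json")
    write_manifest(files, config, manifest_path)
  }

  list(
    theta = theta, calibration = calibration, survey = survey,
    domain = sim$domain, mask = mask, summary = summary,
    stability = lapply(stability, `[[`, "fractions"),
    stability_maps = stability,
    coverage = coverage, monthly = monthly, monthly_tests = monthly_tests,
    mass_balance = list(baseline = sim$baseline$mass_balance,
                        irrigation = sim$irrigation$mass_balance),
    files = if (is.null(out_dir)) NULL else files
  )
}
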