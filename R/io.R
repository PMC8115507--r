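# Plain-text serialisation of every pipeline artifact: cubes as long-format
# CSV (date,row,col,value) with a JSON sidecar carrying grid metadata, 2-D
# maps and domain layers as CSV matrices, survey tables and summaries as CSV,
# calibration results and the run manifest as JSON, configuration as YAML.
# On disk, grid indices are 0-based with row 0 the northernmost row; in R
# they are 1-based. Readers and writers round-trip losslessly at double
# precision (fwrite writes 15 significant digits).

sidecar_path <- function(path) paste0(path, ".json")

#' Write a saturation/flow/wetness cube to CSV with a JSON sidecar
#'
#' @param cube A `sat_cube`, `flow_cube`, or `wetness_cube`.
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$values)
  dt <- data.table::data.table(
    date = rep(as.character(cube$dates), each = d[1] * d[2]),
    row = rep(rep(0:(d[1] - 1L), d[2]), d[3]),
    col = rep(rep(0:(d[2] - 1L), each = d[1]), d[3]),
    value = as.vector(cube$values)
  )
  data.table::fwrite(dt, path)
  meta <- list(
    class = class(cube)[1], n_rows = d[1], n_cols = d[2], n_days = d[3],
    start_date = as.character(min(cube$dates)),
    scenario_label = cube$scenario_label,
    variable = switch(class(cube)[1], sat_cube = "saturation",
                      flow_cube = "flowrate", wetness_cube = "wetness_index"),
    units = switch(class(cube)[1], sat_cube = "fraction",
                   flow_cube = "m3 s-1", wetness_cube = "days"),
    index_base = 0L, row0 = "north"
  )
  if (!is.null(cube$theta)) meta$theta <- cube$theta
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cube written by [write_cube()]
#'
#' @param path CSV path.
#' @return The reconstructed cube object.
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  dt <- data.table::fread(path)
  arr <- array(NA_real_, dim = c(meta$n_rows, meta$n_cols, meta$n_days))
  dates <- sort(unique(as.Date(dt$date)))
  t_idx <- match(as.Date(dt$date), dates)
  arr[cbind(dt$row + 1L, dt$col + 1L, t_idx)] <- dt$value
  if (meta$class == "wetness_cube") storage.mode(arr) <- "integer"
  cube <- new_cube(arr, dates, meta$scenario_label, meta$variable, meta$class)
  if (!is.null(meta$theta)) cube$theta <- meta$theta
  cube
}

#' Write/read a 2-D grid layer as a CSV matrix
#'
#' @param m Matrix (numeric, integer, logical, or character).
#' @param path CSV path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_grid_layer <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_grid_layer
#' @param mode Storage mode to coerce the read matrix to.
#' @export
read_grid_layer <- function(path, mode = "double") {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- mode
  m
}

#' Write a domain grid as one CSV per layer plus JSON metadata
#'
#' @param domain A `domain_grid`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_domain <- function(domain, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    elevation = file.path(dir, "elevation.csv"),
    soil_class = file.path(dir, "soil_class.csv"),
    farm_id = file.path(dir, "farm_id.csv"),
    flow_dir = file.path(dir, "flow_dir.csv"),
    stream_mask = file.path(dir, "stream_mask.csv")
  )
  write_grid_layer(domain$elevation, paths["elevation"])
  write_grid_layer(domain$soil_class, paths["soil_class"])
  write_grid_layer(domain$farm_id, paths["farm_id"])
  write_grid_layer(domain$flow_dir, paths["flow_dir"])
  write_grid_layer(domain$stream_mask_static * 1L, paths["stream_mask"])
  meta_path <- file.path(dir, "domain.json")
  jsonlite::write_json(
    list(n_rows = domain$n_rows, n_cols = domain$n_cols,
         cell_size = domain$cell_size, index_base = 0L, row0 = "north"),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, domain = meta_path))
}

#' @rdname write_domain
#' @export
read_domain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "domain.json"),
                              simplifyVector = TRUE)
  soil <- read_grid_layer(file.path(dir, "soil_class.csv"), "character")
  soil[] <- gsub('"', "", soil)
  structure(
    list(
      n_rows = meta$n_rows, n_cols = meta$n_cols, cell_size = meta$cell_size,
      elevation = read_grid_layer(file.path(dir, "elevation.csv")),
      soil_class = soil,
      farm_id = read_grid_layer(file.path(dir, "farm_id.csv"), "integer"),
      flow_dir = read_grid_layer(file.path(dir, "flow_dir.csv"), "integer"),
      stream_mask_static = read_grid_layer(file.path(dir, "stream_mask.csv"),
                                           "integer") == 1L
    ),
    class = "domain_grid"
  )
}

#' Write/read a survey table (CSV, 0-based grid indices on disk)
#'
#' @param survey Survey `data.frame` with 1-based `row`/`col`.
#' @param path CSV path.
#' @return `path` (writer) or the survey with 1-based indices (reader).
#' @export
write_survey <- function(survey, path) {
  out <- survey
  out$row <- out$row - 1L
  out$col <- out$col - 1L
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  s <- as.data.frame(data.table::fread(path))
  s$row <- s$row + 1L
  s$col <- s$col + 1L
  s
}

#' Write a calibration result as JSON
#'
#' @param result A `calibration_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(result, path) {
  jsonlite::write_json(
    list(
      theta_star = result$theta_star,
      pod_calibration = result$pod_calibration,
      pod_validation = result$pod_validation,
      n_points_used = result$n_points_used,
      settings = result$settings,
      pod_curve = list(theta = result$pod_curve$theta,
                       pod = result$pod_curve$pod),
      bootstrap_thetas = result$bootstrap_thetas
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write an exceedance map (CSV matrix plus JSON sidecar)
#'
#' @param map An `exceedance_map`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_exceedance_map <- function(map, path) {
  write_grid_layer(map$values, path)
  jsonlite::write_json(
    list(T = map$T, period = map$period, scenario_label = map$scenario_label,
         mask_applied = map$mask_applied, index_base = 0L, row0 = "north"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: an 80 x 60 grid at 50 m, one simulated year (2018),
#' seasonal rainfall totalling 1477 mm, the rotating four-farm dry-season
#' irrigation scheme, threshold calibration against a planted synthetic
#' survey, duration thresholds T of 10 and 15 days, and stream masking at
#' 0.01 m^3/s for 90% of the year.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    year = 2018L,
    domain = list(n_rows = 80L, n_cols = 60L, cell_size = 50,
                  farm_fraction = 0.25),
    forcing = list(rainy_months = 5:10, annual_total_mm = 1477),
    bucket = as.list(unclass(bucket_params())),
    irrigation = list(group_a = c(1L, 3L), group_b = c(2L, 4L),
                      turn_length = 10L, daily_depth = 10,
                      hours_per_day = 22, active_months = c(1:4, 11:12)),
    theta = "calibrate",
    survey = list(n_points = 134L, theta_true = 0.48,
                  frac_excluded_types = 0.24),
    calibration = list(theta_grid_step = 0.01, n_bootstrap = 200L),
    T_list = c(10L, 15L),
    seasons = list(dry_months = c(1:4, 11:12), rainy_months = 5:10),
    mask = list(q_threshold = 0.01, persistence = 0.9,
                apply_to_stats = TRUE),
    comparator = "gt",
    output = list(write_cubes = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML pipeline configuration, merged over defaults
#'
#' @param path YAML file; keys override [default_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest (JSON) listing artifacts with MD5 checksums
#'
#' @param files Character vector of file paths written by the run.
#' @param config The configuration that produced them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, config, path) {
  files <- sort(unique(files))
  sums <- tools::md5sum(files)
  jsonlite::write_json(
    list(
      files = data.frame(path = basename(files), md5 = unname(sums)),
      config = config
    ),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
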