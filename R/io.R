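# Typed CSV ingestion, TIFF reading and pipeline orchestration.

# Column schemas for the measurement tables the pipeline consumes.
# Units are encoded in column names (_um, _um2, _deg).
.schemas <- list(
  profile       = c("cell_id", "sample_index", "intensity"),
  polyline      = c("cell_id", "point_index", "x_um", "y_um"),
  island_spans  = c("cell_id", "span_start_um", "span_end_um"),
  contour       = c("trace_id", "point_index", "x_um", "y_um"),
  segments      = c("segment_id", "x1_um", "y1_um", "x2_um", "y2_um"),
  cross_profile = c("segment_id", "position_um", "intensity"),
  roi           = c("cell_id", "roi_id", "vertex_index", "x_um", "y_um"),
  fan           = c("cell_id", "cx", "cy", "eax", "eay", "ebx", "eby",
                    "sx", "sy"),
  counts        = c("condition", "polarized", "non_polarized")
)

#' Read and validate a measurement table
#'
#' Reads a comma-separated, headered CSV and validates it against one of the
#' named column schemas used by the pipeline. Numeric columns are checked
#' cell by cell; errors name the offending row and column.
#'
#' @param path CSV file path.
#' @param schema_name One of `"profile"`, `"polyline"`, `"island_spans"`,
#'   `"contour"`, `"segments"`, `"cross_profile"`, `"roi"`, `"fan"`,
#'   `"counts"`.
#' @return A data frame with validated columns.
#' @export
read_measurement_table <- function(path, schema_name) {
  if (!schema_name %in% names(.schemas))
    stop("unknown schema '", schema_name, "'")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- .schemas[[schema_name]]
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("missing column(s) %s in %s",
                 paste(missing, collapse = ", "), path))
  id_cols <- c("cell_id", "trace_id", "segment_id", "roi_id", "condition")
  for (cl in setdiff(cols, id_cols)) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   cl, if (is.na(bad)) 1L else bad, path))
    }
    if (anyNA(v))
      stop(sprintf("missing value in column '%s', row %d of %s",
                   cl, which(is.na(v))[1], path))
  }
  idx_col <- intersect(c("sample_index", "point_index", "vertex_index"),
                       cols)
  if (length(idx_col) == 1) {
    key_col <- intersect(id_cols, cols)[1]
    key <- paste(df[[key_col]], df[[idx_col]])
    if (anyDuplicated(key))
      stop(sprintf("duplicate (%s, %s) at row %d of %s",
                   key_col, idx_col, anyDuplicated(key), path))
  }
  df
}

#' Write a table as CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header row, no row names: the
#' dialect every reader in the package expects.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_measurement_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single-plane grayscale TIFF
#'
#' @param path TIFF file path.
#' @param pixel_um Pixel size in micrometres; required because acquisition
#'   metadata is not trusted for calibration.
#' @return List: `image` (numeric matrix, rows = y), `pixel_um`.
#' @export
read_grayscale_tiff <- function(path, pixel_um) {
  .check_scalar(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop("multi-channel/RGB TIFF: extract a single grayscale channel ",
              "before analysis (e.g. img[ , , channel])")
  }
  if (!is.matrix(img)) stop("TIFF did not decode to a 2-D grayscale image")
  list(image = img, pixel_um = pixel_um)
}

#' Write a grayscale image as TIFF
#'
#' @param image Numeric matrix; rescaled to `[0, 1]` if needed.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_grayscale_tiff <- function(image, path) {
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1)
    image <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF(image, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed for all synthetic stages.
#' @return Named list of the tunable parameters with their defaults:
#'   confocal and super-resolution pixel sizes, ASI threshold and band
#'   width, the curvature rule lengths, comb-fit settings, and the
#'   synthetic-cohort sizes.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       pixel_um_confocal = 0.108,
       pixel_um_srrf = 0.053,
       asi_threshold = 0.35,
       asi_band_um = 0.5,
       min_island_um = 1,
       exclusion_um = 5,
       max_region_um = 5,
       mixture_k = 7L,
       bandwidth = "sj",
       sim = list(n_cells_asi = 60L, n_profile_samples = 400L,
                  crescent_fraction = 0.25, crescent_level = 5,
                  background_level = 1, profile_noise_sd = 0.3,
                  n_comb = 754L, comb_spacing_um = 0.38,
                  comb_sd_um = 0.06 * 0.38,
                  fwhm_um = 0.23, cross_noise_sd = 0.05,
                  n_fan_cells = 40L, fan_inside_fraction = 0.8))
}

#' Run the full synthetic pipeline
#'
#' Generates a seeded synthetic bundle (perimeter profiles, arc points,
#' comb lengths, cross-sections, fan cohort), pushes each through the
#' corresponding analysis stage, and writes per-stage CSVs plus a JSON
#' report containing every summary, the resolved configuration and the
#' package version. Reruns with the same configuration are bit-identical.
#'
#' @param config Configuration list as from [default_config()], or a path
#'   to a YAML file with the same fields (missing fields take defaults).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing files.
#' @return The report, invisibly a list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(default_config(), user)
  }
  stopifnot(is.list(config), !is.null(config$seed))
  cfg <- utils::modifyList(default_config(config$seed), config)
  sim <- cfg$sim

  # --- ASI stage ------------------------------------------------------
  asi_vals <- vapply(seq_len(sim$n_cells_asi), function(i) {
    pp <- make_perimeter_profile(sim$n_profile_samples,
                                 sim$crescent_fraction,
                                 sim$crescent_level, sim$background_level,
                                 sim$profile_noise_sd,
                                 seed = cfg$seed + i,
                                 spacing_um = cfg$pixel_um_confocal)
    asi(pp$profile, threshold = cfg$asi_threshold)$asi
  }, numeric(1))
  asi_summary <- asi_cohort_summary(asi_vals, threshold = cfg$asi_threshold)

  # --- curvature stage ------------------------------------------------
  arc <- make_arc_points(1.70, jitter_sd = 0, seed = cfg$seed)
  island_radius <- circumradius(arc$points[1, ], arc$points[2, ],
                                arc$points[3, ])

  # --- meshwork stage -------------------------------------------------
  comb <- make_comb_lengths(sim$n_comb, sim$comb_spacing_um,
                            sim$comb_sd_um, k = cfg$mixture_k,
                            seed = cfg$seed)
  dens <- length_density(comb$lengths_um, bandwidth = cfg$bandwidth)
  fit <- fit_k_gaussians(dens, k = cfg$mixture_k, seed = cfg$seed)
  spec <- spectral_periodicity(dens)
  cross <- make_cross_profile(sim$fwhm_um, 1, 0.2,
                              cfg$pixel_um_srrf / 2.65,
                              sim$cross_noise_sd, seed = cfg$seed)
  width <- segment_width_fwhm(cross$positions_um, cross$intensities)

  # --- geometry stage -------------------------------------------------
  fans <- make_fan_cohort(sim$n_fan_cells,
                          inside_fraction = sim$fan_inside_fraction,
                          seed = cfg$seed)
  fan_geoms <- lapply(seq_len(nrow(fans$cohort)), function(i) {
    r <- fans$cohort[i, ]
    crescent_fan(c(r$cx, r$cy), c(r$eax, r$eay), c(r$ebx, r$eby),
                 c(r$sx, r$sy))
  })
  fan_frac <- fraction_within_fan(fan_geoms)

  report <- list(
    package_version = as.character(utils::packageVersion("parcortex")),
    config = cfg[setdiff(names(cfg), "sim")],
    sim = sim,
    asi = list(values = asi_vals, summary = asi_summary[
      c("n", "mean", "sd", "n_polarized", "fraction_polarized")]),
    curvature = list(island_circumradius_um = island_radius),
    meshwork = list(
      peak_interval_mean_um = fit$peak_interval_mean_um,
      peak_interval_sd_um = fit$peak_interval_sd_um,
      component_means_um = fit$components$mean_um,
      major_frequency_um_inv = spec$major_frequency_um_inv,
      implied_interval_um = spec$implied_interval_um,
      fwhm_um = width$fwhm_um),
    geometry = list(fan_count_inside = fan_frac$count_inside,
                    fan_n = fan_frac$n,
                    fan_fraction = fan_frac$fraction))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_measurement_table(
      data.frame(cell_id = seq_along(asi_vals), asi = asi_vals,
                 polarized = classify_polarized(asi_vals,
                                                cfg$asi_threshold)),
      file.path(out_dir, "asi.csv"))
    write_measurement_table(
      data.frame(length_um = comb$lengths_um),
      file.path(out_dir, "contour_lengths.csv"))
    write_measurement_table(fans$cohort, file.path(out_dir, "fan.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
  }
  invisible(report)
}
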