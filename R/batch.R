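#' Run configuration
#'
#' Bundles every tunable of the image pipeline. Values can come from a flat
#' `key = value` text file ([read_run_config()]) with CLI flags overriding
#' file values.
#'
#' @param sigma,eps_mi,eps_ma,mask_rows,mask_cols Oriented-mask parameters;
#'   see [mask_params()] (`mask_rows`/`mask_cols` `NULL` = automatic extent).
#' @param theta_step_deg Orientation sweep step in degrees (default 1).
#' @param flatten_background Apply [flatten_background()] before the median
#'   prefilter (default `FALSE`).
#' @param pixel_weighted Pixel-weighted `phi_sr`/`phi_std` (default `FALSE`).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in every output.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(sigma = 2, eps_mi = -2, eps_ma = 4,
                       mask_rows = NULL, mask_cols = NULL,
                       theta_step_deg = 1, flatten_background = FALSE,
                       pixel_weighted = FALSE, out_dir = ".",
                       seed = 1L, log_level = "info") {
  mp <- if (is.null(mask_rows)) {
    mask_params(eps_mi = eps_mi, eps_ma = eps_ma, sigma = sigma)
  } else {
    mask_params(
      eps_mi = eps_mi, eps_ma = eps_ma, sigma = sigma,
      rows = mask_rows, cols = if (is.null(mask_cols)) mask_rows else mask_cols
    )
  }
  structure(
    list(
      mask = mp, theta_step_deg = theta_step_deg,
      flatten_background = isTRUE(flatten_background),
      pixel_weighted = isTRUE(pixel_weighted),
      out_dir = out_dir, seed = as.integer(seed), log_level = log_level
    ),
    class = "run_config"
  )
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; keys are the
#' arguments of [run_config()]. Unknown keys raise an error.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("Malformed config line: '%s'", lines[bad][1]))
  vals <- lapply(kv, function(p) utils::type.convert(p[2], as.is = TRUE))
  names(vals) <- vapply(kv, `[[`, "", 1L)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

log_line <- function(cfg, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  inform(line)
  log_path <- file.path(cfg$out_dir, "run.log")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(NULL)
}

config_string <- function(cfg) {
  sprintf(
    "sigma=%g eps_mi=%g eps_ma=%g mask=%dx%d theta_step=%g flatten=%s pixel_weighted=%s seed=%d",
    cfg$mask$sigma, cfg$mask$eps_mi, cfg$mask$eps_ma, cfg$mask$rows, cfg$mask$cols,
    cfg$theta_step_deg, cfg$flatten_background, cfg$pixel_weighted, cfg$seed
  )
}

#' Run the vessel-inclination pipeline on an image in memory
#'
#' The core chain: optional background flattening, 3x3 median prefilter,
#' oriented-filter sweep, Otsu gating into the tangent-angle map, radial
#' re-expression about the disc centre, and annulus morphometrics.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param disc A [disc_geometry()].
#' @param cfg A [run_config()].
#' @return List with `metrics` (`annulus_metrics`), `lw`, `lk`
#'   (`angle_map`s), `p_r` (Otsu threshold) and `response`.
#' @export
analyze_vessels <- function(img, disc, cfg = run_config()) {
  if (cfg$flatten_background) img <- flatten_background(img)
  med <- median3x3(img)
  resp <- sweep_orientations(med, cfg$mask, theta_step_deg = cfg$theta_step_deg)
  p_r <- otsu_threshold(resp$l_ma)
  lw <- angle_field(resp, p_r)
  lk <- radialize(lw, disc)
  band <- annulus_mask(dim(lk$angles), disc)
  metrics <- compute_metrics(lk, band, pixel_weighted = cfg$pixel_weighted)
  list(metrics = metrics, lw = lw, lk = lk, p_r = p_r, response = resp)
}

#' Analyse one image file and save artifacts
#'
#' Loads the image, runs [analyze_vessels()] and writes the tangent and
#' radial angle maps (16-bit TIFF), the angle histogram CSV and the metrics
#' row, all named after the image id (file stem), into the config's output
#' directory. A structured log line records parameters and timing.
#'
#' @param image_path Path to a PNG/TIFF angiogram.
#' @param disc A [disc_geometry()] for this image.
#' @param cfg A [run_config()].
#' @return One-row tibble of metrics (with `image_id`), invisibly.
#' @export
analyze_image <- function(image_path, disc, cfg = run_config()) {
  t0 <- Sys.time()
  image_id <- tools::file_path_sans_ext(basename(image_path))
  img <- load_gray(image_path)
  res <- analyze_vessels(img, disc, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_angle_map(res$lw, file.path(cfg$out_dir, paste0(image_id, "_lw.tif")))
  write_angle_map(res$lk, file.path(cfg$out_dir, paste0(image_id, "_lk.tif")))
  readr::write_csv(
    dplyr::bind_cols(tibble(image_id = image_id), angle_histogram(res$metrics)),
    file.path(cfg$out_dir, paste0(image_id, "_histogram.csv"))
  )
  row <- dplyr::bind_cols(tibble(image_id = image_id), tidy(res$metrics))
  readr::write_csv(row, file.path(cfg$out_dir, paste0(image_id, "_metrics.csv")))
  log_line(cfg, sprintf(
    "analyze %s: z=%d p_s=%.2f p_r=%.4g elapsed=%.2fs [%s]",
    image_id, res$metrics$z, res$metrics$p_s, res$p_r,
    as.numeric(difftime(Sys.time(), t0, units = "secs")), config_string(cfg)
  ))
  invisible(row)
}

resolve_geometry <- function(geometry, image_id) {
  g <- geometry[geometry$image_id == image_id, ]
  if (nrow(g) != 1L) return(NULL)
  disc_geometry(center = c(g$row, g$col), radius_r = g$r)
}

#' Analyse a folder (or list) of images
#'
#' Disc geometry is supplied per image through a sidecar table with columns
#' `image_id`, `row`, `col`, `r` (a CSV path or a data frame). Images
#' without geometry are skipped with a warning and listed in the summary.
#'
#' @param images A directory containing PNG/TIFF files, or a character
#'   vector of image paths.
#' @param geometry Sidecar CSV path or data frame (`image_id`, `row`,
#'   `col`, `r`).
#' @param cfg A [run_config()].
#' @return A `batch_result`: `$per_image` tibble, `$summary` tibble (mean,
#'   sd, median of each metric), `$skipped` character vector.
#' @export
analyze_batch <- function(images, geometry, cfg = run_config()) {
  if (length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  }
  if (length(images) == 0L) abort("No images to analyse.")
  if (is.character(geometry)) geometry <- readr::read_csv(geometry, show_col_types = FALSE)
  need <- c("image_id", "row", "col", "r")
  if (!all(need %in% names(geometry))) {
    abort("Geometry table needs columns image_id, row, col, r.")
  }
  rows <- list(); skipped <- character(0)
  for (path in images) {
    image_id <- tools::file_path_sans_ext(basename(path))
    disc <- resolve_geometry(geometry, image_id)
    if (is.null(disc)) {
      warn(sprintf("No disc geometry for '%s'; skipped.", image_id))
      skipped <- c(skipped, image_id)
      next
    }
    rows[[image_id]] <- analyze_image(path, disc, cfg)
  }
  if (length(rows) == 0L) abort("No processable images in the batch.")
  per_image <- dplyr::bind_rows(rows)
  metric_cols <- c("z", "phi_sr", "phi_std", "phi_max", "p_s")
  summary <- purrr::map_dfr(metric_cols, function(col) {
    v <- per_image[[col]]
    tibble(
      metric = col, mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
      median = median(v)
    )
  })
  readr::write_csv(per_image, file.path(cfg$out_dir, "batch_metrics.csv"))
  readr::write_csv(summary, file.path(cfg$out_dir, "batch_summary.csv"))
  log_line(cfg, sprintf(
    "batch: %d analysed, %d skipped", nrow(per_image), length(skipped)
  ))
  structure(list(per_image = per_image, summary = summary, skipped = skipped),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d image(s), %d skipped\n", nrow(x$per_image), length(x$skipped)))
  print(x$summary)
  invisible(x)
}

#' Classify a cohort from a metrics CSV
#'
#' Reads the per-subject feature table, runs [evaluate_attribute_trees()]
#' and writes a JSON report (per-tree counts and metrics, the chosen tree
#' and its threshold) plus a plain-text dump of the best tree.
#'
#' @param metrics_csv CSV with the five attribute columns and a label
#'   column.
#' @param label Label column name (default `"hypertension"`).
#' @param seed Integer seed for the stratified folds.
#' @param out_dir Output directory for `classification_report.json` and
#'   `best_tree.txt` (`NULL` = don't write).
#' @param folds Number of folds (default 3).
#' @return The `tree_evaluation`, invisibly.
#' @export
classify_cohort <- function(metrics_csv, label = "hypertension", seed = 1L,
                            out_dir = NULL, folds = 3L) {
  table <- readr::read_csv(metrics_csv, show_col_types = FALSE)
  if (!label %in% names(table)) {
    abort(sprintf("Label column '%s' missing from '%s'.", label, metrics_csv))
  }
  if (length(unique(as.character(table[[label]]))) < 2L) {
    abort("The cohort contains a single class; classification is undefined.")
  }
  ev <- evaluate_attribute_trees(table, seed = seed, folds = folds, label = label)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    best <- ev$summary$tree[ev$summary$best]
    report <- list(
      seed = seed, folds = folds, n_subjects = nrow(table),
      trees = ev$summary, best_tree = best
    )
    jsonlite::write_json(report, file.path(out_dir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    con <- file(file.path(out_dir, "best_tree.txt"), "w")
    sink(con); print(ev$models[[best]]$fit); sink()
    close(con)
  }
  invisible(ev)
}
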