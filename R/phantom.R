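#' Specify a synthetic vessel
#'
#' Describes one bright curved vessel departing from the optic-disc rim. The
#' centreline is integrated so that its tangent at arc length `s` deviates
#' from the local radial direction by
#' `tortuosity_amplitude_deg * sin(2 * pi * s / tortuosity_period)`; a
#' tortuosity amplitude of zero gives a perfectly radial (straight) vessel.
#' The cross-section is Gaussian with standard deviation `width_sd` and peak
#' `peak_intensity` above background.
#'
#' @param start_angle_deg Direction of departure from the disc centre
#'   (degrees, 0 = east, counter-clockwise).
#' @param length Centreline arc length in pixels.
#' @param width_sd Gaussian cross-section sigma in pixels (> 0).
#' @param peak_intensity Peak intensity added above background.
#' @param tortuosity_amplitude_deg Sinusoidal deviation of the tangent from
#'   the radial direction, degrees in \[0, 90].
#' @param tortuosity_period Arc-length period of the deviation, pixels.
#' @param deviation_offset_deg Constant deviation of the tangent from the
#'   radial direction, degrees (90 traces an arc concentric with the disc).
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(start_angle_deg, length = 180, width_sd = 2,
                        peak_intensity = 120, tortuosity_amplitude_deg = 0,
                        tortuosity_period = 120, deviation_offset_deg = 0) {
  if (width_sd <= 0) abort("`width_sd` must be > 0.")
  if (tortuosity_amplitude_deg < 0 || tortuosity_amplitude_deg > 90) {
    abort("`tortuosity_amplitude_deg` must lie in [0, 90].")
  }
  if (length < 0) abort("`length` must be non-negative.")
  structure(
    list(
      start_angle_deg = start_angle_deg, length = length, width_sd = width_sd,
      peak_intensity = peak_intensity,
      tortuosity_amplitude_deg = tortuosity_amplitude_deg,
      tortuosity_period = tortuosity_period,
      deviation_offset_deg = deviation_offset_deg
    ),
    class = "vessel_spec"
  )
}

#' A fan of vessels evenly spaced around the disc
#'
#' @param n Number of vessels.
#' @param ... Passed on to [vessel_spec()] for every vessel.
#' @return List of `vessel_spec`s with departure angles `0, 360/n, ...`.
#' @export
vessel_fan <- function(n, ...) {
  lapply(seq_len(n) - 1L, function(i) vessel_spec(start_angle_deg = i * 360 / n, ...))
}

#' Specify a phantom angiogram
#'
#' Defines the study-like acquisition the phantom emulates: bright vessels
#' radiating from a known optic-disc centre over a noisy, unevenly lit
#' background, at desk scale (512 x 512 by default, on an 8-bit intensity
#' scale). The `2r`..`3r` measurement annulus must fit inside the raster.
#'
#' @param image_height,image_width Raster size in pixels.
#' @param disc_center Numeric `(row, col)` of the optic-disc centre
#'   (sub-pixel allowed); default image centre.
#' @param disc_radius_r Optic-disc radius `r` in pixels (> 0; `3r` must fit).
#' @param vessels List of [vessel_spec()]s; default a 12-vessel fan.
#' @param background_level Background intensity.
#' @param illumination_gradient Linear illumination ramp amplitude, intensity
#'   per pixel along the column axis.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param intensity_max Clip ceiling of the intensity scale (default 255).
#' @param seed Integer seed making the phantom reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_height = 512L, image_width = 512L,
                         disc_center = c((image_height + 1) / 2, (image_width + 1) / 2),
                         disc_radius_r = 60, vessels = vessel_fan(12),
                         background_level = 40, illumination_gradient = 0.04,
                         noise_sd = 4, intensity_max = 255, seed = 1L) {
  if (disc_radius_r <= 0) abort("`disc_radius_r` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  r3 <- 3 * disc_radius_r
  if (disc_center[1] - r3 < 1 || disc_center[1] + r3 > image_height ||
      disc_center[2] - r3 < 1 || disc_center[2] + r3 > image_width) {
    abort("The 3r measurement annulus must fit inside the image.")
  }
  if (!all(vapply(vessels, inherits, logical(1), "vessel_spec"))) {
    abort("`vessels` must be a list of vessel_spec objects.")
  }
  structure(
    list(
      image_height = as.integer(image_height), image_width = as.integer(image_width),
      disc_center = as.numeric(disc_center), disc_radius_r = disc_radius_r,
      vessels = vessels, background_level = background_level,
      illumination_gradient = illumination_gradient, noise_sd = noise_sd,
      intensity_max = intensity_max, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# integrate one vessel centreline at sub-pixel step, returning sample
# positions, analytic tangents (directed, degrees) and the realised length
trace_centreline <- function(vs, center, radius, M, N, step = 0.25) {
  n_steps <- max(1L, ceiling(vs$length / step))
  rows <- cols <- tangents <- svals <- numeric(n_steps + 1L)
  a0 <- deg2rad(vs$start_angle_deg)
  row <- center[1] - radius * sin(a0)
  col <- center[2] + radius * cos(a0)
  s <- 0
  kept <- 0L
  for (i in 0:n_steps) {
    if (row < 1 || row > M || col < 1 || col > N) break
    radial <- dir_angle_deg(row - center[1], col - center[2])
    tang <- radial + vs$deviation_offset_deg +
      vs$tortuosity_amplitude_deg * sin(2 * pi * s / vs$tortuosity_period)
    kept <- kept + 1L
    rows[kept] <- row; cols[kept] <- col; tangents[kept] <- tang; svals[kept] <- s
    ds <- min(step, vs$length - s)
    if (ds <= 0) break
    row <- row - sin(deg2rad(tang)) * ds
    col <- col + cos(deg2rad(tang)) * ds
    s <- s + ds
  }
  list(
    rows = rows[seq_len(kept)], cols = cols[seq_len(kept)],
    tangents = tangents[seq_len(kept)] %% 180,
    realised_length = if (kept > 0L) svals[kept] else 0
  )
}

#' Generate a phantom angiogram with analytic ground truth
#'
#' Renders every vessel of the spec by max-blending Gaussian cross-section
#' profiles stamped along the sub-pixel (0.25 px step) centreline, adds the
#' background level, an illumination ramp and clipped Gaussian noise, and
#' fills ground-truth maps from the analytic tangents.
#'
#' The ground-truth support (`vessel_mask`) is the set of pixels where the
#' noiseless vessel contribution exceeds 10% of that vessel's peak intensity.
#' `tangent_angle_map` holds the tangent of the nearest centreline sample
#' (degrees mod 180) on that support and `NA` elsewhere; `radial_angle_map`
#' folds the tangent against each pixel's own radial direction into
#' \[0, 90] degrees.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list with elements `image` ([gray_image()]),
#'   `tangent_angle_map`, `radial_angle_map` (numeric matrices, `NA`
#'   sentinel), `vessel_mask` (logical matrix), `vessel_count`,
#'   `truncated_lengths` (realised arc length per vessel) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$image_height; N <- spec$image_width
  contrib <- matrix(0, M, N)
  best_d2 <- matrix(Inf, M, N)
  tangent_map <- matrix(NA_real_, M, N)
  mask <- matrix(FALSE, M, N)
  realised <- numeric(length(spec$vessels))

  for (v in seq_along(spec$vessels)) {
    vs <- spec$vessels[[v]]
    cl <- trace_centreline(vs, spec$disc_center, spec$disc_radius_r, M, N)
    realised[v] <- cl$realised_length
    if (length(cl$rows) == 0L) next
    w <- ceiling(3.5 * vs$width_sd)
    d2_mask <- 2 * vs$width_sd^2 * log(10)  # profile > 10% of peak
    for (i in seq_along(cl$rows)) {
      sr <- cl$rows[i]; sc <- cl$cols[i]
      r0 <- max(1L, floor(sr - w)); r1 <- min(M, ceiling(sr + w))
      c0 <- max(1L, floor(sc - w)); c1 <- min(N, ceiling(sc + w))
      ri <- r0:r1; ci <- c0:c1
      d2 <- outer((ri - sr)^2, (ci - sc)^2, `+`)
      prof <- vs$peak_intensity * exp(-d2 / (2 * vs$width_sd^2))
      contrib[ri, ci] <- pmax(contrib[ri, ci], prof)
      mask[ri, ci] <- mask[ri, ci] | (d2 < d2_mask)
      closer <- d2 < best_d2[ri, ci]
      if (any(closer)) {
        bw <- best_d2[ri, ci]; tw <- tangent_map[ri, ci]
        bw[closer] <- d2[closer]; tw[closer] <- cl$tangents[i]
        best_d2[ri, ci] <- bw; tangent_map[ri, ci] <- tw
      }
    }
  }

  tangent_map[!mask] <- NA_real_
  radial_map <- matrix(NA_real_, M, N)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    psi <- dir_angle_deg(idx[, 1] - spec$disc_center[1], idx[, 2] - spec$disc_center[2]) %% 180
    radial_map[idx] <- fold_angle(tangent_map[idx] - psi)
  }

  ramp <- matrix(spec$illumination_gradient * (seq_len(N) - 1), M, N, byrow = TRUE)
  img <- spec$background_level + ramp + contrib
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed, rnorm(M * N, 0, spec$noise_sd))
  }
  img <- pmin(pmax(img, 0), spec$intensity_max)

  structure(
    list(
      image = gray_image(img, bit_depth = if (spec$intensity_max > 255) 16L else 8L),
      tangent_angle_map = tangent_map,
      radial_angle_map = radial_map,
      vessel_mask = mask,
      vessel_count = length(spec$vessels),
      truncated_lengths = realised,
      spec = spec
    ),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %d x %d image, %d vessels, %d vessel pixels\n",
    nrow(x$image), ncol(x$image), x$vessel_count, sum(x$vessel_mask)
  ))
  invisible(x)
}

#' Disc geometry of a phantom
#'
#' @param truth A `phantom_truth`.
#' @return The [disc_geometry()] used to generate it.
#' @export
phantom_disc <- function(truth) {
  disc_geometry(center = truth$spec$disc_center, radius_r = truth$spec$disc_radius_r)
}

#' Write a phantom and its ground truth to disk
#'
#' The image is written as 16-bit TIFF (native scale stretched to 16 bits);
#' truth maps as 16-bit TIFFs holding whole degrees with sentinel 65535 for
#' "undefined", and the vessel mask as a binary image.
#'
#' @param truth A `phantom_truth`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem, default `"phantom"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_phantom <- function(truth, dir, stem = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(stem, "_", suffix, ".tif"))
  scale <- 65535 / truth$spec$intensity_max
  write_gray(unclass(truth$image) * scale, p("image"), bit_depth = 16L)
  write_angle_tif <- function(m, path) {
    v <- round(m); v[is.na(v)] <- 65535
    write_gray(v, path, bit_depth = 16L)
  }
  write_angle_tif(truth$tangent_angle_map, p("tangent"))
  write_angle_tif(truth$radial_angle_map, p("radial"))
  write_gray(truth$vessel_mask * 65535, p("mask"), bit_depth = 16L)
  invisible(c(
    image = p("image"), tangent = p("tangent"),
    radial = p("radial"), mask = p("mask")
  ))
}
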