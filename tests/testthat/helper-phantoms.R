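# Shared phantom builders for the image-pipeline tests. Sizes are kept at
# desk scale (128-256 px) so the whole suite runs quickly.

straight_phantom <- function(angle_deg, width_sd = 2, size = 128L, r = 20,
                             length = 60, noise_sd = 0, n_vessels = 1L,
                             seed = 1L, ...) {
  vessels <- if (n_vessels == 1L) {
    list(vessel_spec(angle_deg, length = length, width_sd = width_sd, ...))
  } else {
    vessel_fan(n_vessels, length = length, width_sd = width_sd, ...)
  }
  generate_phantom(phantom_spec(
    image_height = size, image_width = size, disc_radius_r = r,
    vessels = vessels, noise_sd = noise_sd, illumination_gradient = 0,
    seed = seed
  ))
}

# centreline pixels away from the vessel endpoints (where mask overhang
# makes the orientation genuinely ambiguous)
interior_centreline <- function(truth, margin = 8, frac_of_peak = 0.8) {
  spec <- truth$spec
  peak <- max(vapply(spec$vessels, function(v) v$peak_intensity, 0))
  img <- unclass(truth$image)
  cl <- which(truth$vessel_mask & (img - spec$background_level > peak * frac_of_peak),
              arr.ind = TRUE)
  d <- sqrt((cl[, 1] - spec$disc_center[1])^2 + (cl[, 2] - spec$disc_center[2])^2)
  len <- min(truth$truncated_lengths)
  cl[d > spec$disc_radius_r + margin & d < spec$disc_radius_r + len - margin, ,
     drop = FALSE]
}

# rotate a matrix 90 degrees counter-clockwise (image viewed row 1 on top)
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

circular_err <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

cohort_fragment_path <- function() {
  system.file("extdata", "cohort_fragment.csv", package = "angiomorph")
}
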