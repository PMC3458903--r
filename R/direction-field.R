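#' Parameters of the oriented matched-filter mask
#'
#' The mask is a Gaussian bright-ridge profile across the filter direction:
#' at orientation 0 the weight in row offset `m` (signed, centre = 0) is
#' `g(m) = eps_mi + (eps_ma - eps_mi) * exp(-m^2 / (2 * sigma^2))`, constant
#' along columns. `eps_ma` is thus the weight on the centre line and `eps_mi`
#' the asymptotic surround value. Rotated masks evaluate `g` at the signed
#' perpendicular distance to the oriented centre line (analytic rotation, no
#' interpolation), so the behaviour is identical at every swept angle.
#'
#' The default extent is `2 * ceiling(3 * sigma) + 1` in both directions —
#' wide enough that the profile has flattened to its surround value.
#' [mask_params_29x19()] preserves the classic 29 x 19 parameterisation
#' (`eps_mi = -2`, `eps_ma = 4`, `sigma = 1`).
#'
#' @param eps_mi Minimum (surround) mask value.
#' @param eps_ma Maximum (centre-line) mask value; must exceed `eps_mi`.
#' @param sigma Ridge profile standard deviation in pixels (> 0); match to
#'   the expected vessel half-width.
#' @param rows,cols Odd mask extent in pixels.
#' @return A `mask_params` list.
#' @export
mask_params <- function(eps_mi = -2, eps_ma = 4, sigma = 2,
                        rows = 2 * ceiling(3 * sigma) + 1,
                        cols = rows) {
  if (eps_ma <= eps_mi) abort("`eps_ma` must be greater than `eps_mi`.")
  if (sigma <= 0) abort("`sigma` must be > 0.")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows %% 2L == 0L || cols %% 2L == 0L) {
    abort("`rows` and `cols` must be odd so the mask has a centre element.")
  }
  structure(
    list(eps_mi = eps_mi, eps_ma = eps_ma, sigma = sigma, rows = rows, cols = cols),
    class = "mask_params"
  )
}

#' @rdname mask_params
#' @export
mask_params_29x19 <- function() {
  mask_params(eps_mi = -2, eps_ma = 4, sigma = 1, rows = 29L, cols = 19L)
}

#' Build one oriented mask
#'
#' @param params A [mask_params()].
#' @param theta_deg Mask orientation in degrees, `0 <= theta < 180`
#'   (0 = east, counter-clockwise).
#' @return A `directional_mask`: the `rows x cols` weight matrix with
#'   attribute `theta_deg`.
#' @export
build_mask <- function(params, theta_deg) {
  stopifnot(inherits(params, "mask_params"))
  if (theta_deg < 0 || theta_deg >= 180) abort("`theta_deg` must lie in [0, 180).")
  hr <- (params$rows - 1L) %/% 2L
  hc <- (params$cols - 1L) %/% 2L
  m <- matrix(-hr:hr, params$rows, params$cols)          # row offsets, down positive
  n <- matrix(-hc:hc, params$rows, params$cols, byrow = TRUE)
  th <- deg2rad(theta_deg)
  # signed perpendicular distance to the line through the centre at theta
  d <- m * cos(th) + n * sin(th)
  w <- params$eps_mi + (params$eps_ma - params$eps_mi) * exp(-d^2 / (2 * params$sigma^2))
  structure(w, theta_deg = theta_deg, class = c("directional_mask", "matrix", "array"))
}

#' Effective sweep kernel at one orientation
#'
#' The kernel actually correlated with the image by [sweep_orientations()]:
#' the oriented mask of [build_mask()], optionally restricted to the ellipse
#' inscribed in its rectangular extent and DC-balanced (mean subtracted over
#' the support, zero outside it).
#'
#' A rectangular support intersects an oriented ridge over a length that
#' varies with orientation (longest on the diagonal), which biases the
#' argmax towards 45/135 degrees; the inscribed-ellipse support makes the
#' overlap geometry orientation-uniform. DC balancing removes the
#' background-level term, which otherwise multiplies an
#' orientation-dependent weight sum.
#'
#' @param params A [mask_params()].
#' @param theta_deg Orientation in degrees.
#' @param zero_mean Subtract the support mean (default `TRUE`).
#' @param support `"circular"` (inscribed ellipse, default) or
#'   `"rectangular"` (the full mask extent).
#' @return Numeric kernel matrix of the mask's extent.
#' @export
effective_kernel <- function(params, theta_deg, zero_mean = TRUE,
                             support = c("circular", "rectangular")) {
  support <- match.arg(support)
  kernel <- unclass(build_mask(params, theta_deg))
  if (support == "circular") {
    hr <- (params$rows - 1L) / 2; hc <- (params$cols - 1L) / 2
    mo <- matrix(-hr:hr, params$rows, params$cols)
    no <- matrix(-hc:hc, params$rows, params$cols, byrow = TRUE)
    inside <- (mo / max(hr, 1))^2 + (no / max(hc, 1))^2 <= 1
    if (zero_mean) kernel <- kernel - mean(kernel[inside])
    kernel[!inside] <- 0
  } else if (zero_mean) {
    kernel <- kernel - mean(kernel)
  }
  kernel
}

#' Centred cross-correlation with replicate borders
#'
#' The elementary filtering step of the orientation sweep, exposed on its
#' own. EBImage's FFT filter performs convolution, so the kernel is flipped
#' to obtain correlation.
#'
#' @param img Numeric matrix or [gray_image()].
#' @param kernel Numeric kernel with odd dimensions.
#' @return Numeric matrix of the same size as `img`.
#' @export
correlate_image <- function(img, kernel) {
  EBImage::filter2(
    unclass(img),
    kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))), drop = FALSE],
    boundary = "replicate"
  )
}

#' Sweep the oriented filter bank over an image
#'
#' Correlates the (median-filtered) image with the oriented mask at every
#' swept orientation `0, theta_step, ..., 180 - theta_step` degrees and keeps,
#' per pixel, the maximal response and the orientation at which it occurred
#' (ties broken towards the smallest angle).
#'
#' Each orientation correlates the image with the [effective_kernel()] —
#' the oriented mask restricted to its inscribed-ellipse support and
#' DC-balanced. Both refinements make the response orientation-uniform:
#' without them the constant background level and the orientation-dependent
#' support geometry bias the argmax towards the diagonals (see
#' [effective_kernel()]). On a constant image every balanced response is
#' (numerically) zero at all orientations.
#'
#' @param img A [gray_image()] or numeric matrix (the `L_MED` stage).
#' @param params A [mask_params()].
#' @param theta_step_deg Sweep resolution in degrees; must divide 180
#'   (default 1).
#' @param zero_mean,support Kernel refinements; see [effective_kernel()].
#' @return An `orientation_response` with numeric matrices `l_ma` (maximal
#'   response) and `l_theta` (argmax orientation, degrees).
#' @export
sweep_orientations <- function(img, params, theta_step_deg = 1, zero_mean = TRUE,
                               support = c("circular", "rectangular")) {
  support <- match.arg(support)
  stopifnot(inherits(params, "mask_params"))
  m <- unclass(img)
  if (params$rows > nrow(m) || params$cols > ncol(m)) {
    abort("Mask must not be larger than the image.")
  }
  if (180 %% theta_step_deg != 0) abort("`theta_step_deg` must divide 180.")
  thetas <- seq(0, 180 - theta_step_deg, by = theta_step_deg)
  l_ma <- matrix(-Inf, nrow(m), ncol(m))
  l_theta <- matrix(0, nrow(m), ncol(m))
  for (th in thetas) {
    resp <- correlate_image(m, effective_kernel(params, th, zero_mean, support))
    better <- resp > l_ma            # strict: ties keep the smaller theta
    l_ma[better] <- resp[better]
    l_theta[better] <- th
  }
  structure(list(l_ma = l_ma, l_theta = l_theta, theta_step_deg = theta_step_deg),
            class = "orientation_response")
}

#' @export
print.orientation_response <- function(x, ...) {
  cat(sprintf(
    "<orientation_response> %d x %d, response range [%.3g, %.3g], step %g deg\n",
    nrow(x$l_ma), ncol(x$l_ma), min(x$l_ma), max(x$l_ma), x$theta_step_deg
  ))
  invisible(x)
}

#' Otsu threshold of the response raster
#'
#' Rescales the responses to 256 integer levels, finds the level that
#' maximises the between-class variance of the level histogram (smallest
#' level on ties) and maps the cut — placed halfway between the chosen level
#' and the next — back to response units, so the threshold falls strictly
#' between the two classes.
#'
#' @param l_ma Numeric matrix or vector of filter responses with at least two
#'   distinct values.
#' @return The threshold `p_r` in response units.
#' @export
otsu_threshold <- function(l_ma) {
  v <- as.vector(if (is.list(l_ma)) l_ma$l_ma else unclass(l_ma))
  mn <- min(v); mx <- max(v)
  if (mx <= mn) abort("Otsu threshold is undefined for a constant response raster.")
  lev <- round((v - mn) / (mx - mn) * 255)
  counts <- tabulate(lev + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)                      # class-0 weight for thresholds 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- which.max(sigma_b) - 1L       # which.max takes the first maximum
  mn + (t_star + 0.5) / 255 * (mx - mn)
}

#' Gate the orientation field into a tangent-angle map
#'
#' Keeps the argmax orientation wherever the maximal response strictly
#' exceeds the threshold and zeroes it elsewhere. A separate logical vessel
#' mask records the gating, so a genuine tangent angle of 0 degrees is not
#' confused with background.
#'
#' @param resp An `orientation_response` from [sweep_orientations()].
#' @param p_r Threshold in response units, e.g. from [otsu_threshold()].
#' @return An `angle_map` with `convention = "tangent_cartesian"`: list of
#'   `angles` (degrees; 0 on background), logical `mask`, and `convention`.
#' @export
angle_field <- function(resp, p_r) {
  stopifnot(inherits(resp, "orientation_response"), is.finite(p_r))
  mask <- resp$l_ma > p_r
  angles <- resp$l_theta
  angles[!mask] <- 0
  new_angle_map(angles, mask, "tangent_cartesian")
}

new_angle_map <- function(angles, mask, convention) {
  structure(list(angles = angles, mask = mask, convention = convention),
            class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  cat(sprintf(
    "<angle_map> %d x %d, %s, %d vessel pixels\n",
    nrow(x$angles), ncol(x$angles), x$convention, sum(x$mask)
  ))
  invisible(x)
}

#' Write an angle map as 16-bit TIFF
#'
#' Angles are written in whole degrees with sentinel 65535 on background,
#' alongside a binary mask image (`<stem>_mask.tif`).
#'
#' @param am An `angle_map`.
#' @param path Output TIFF path.
#' @return Paths written, invisibly.
#' @export
write_angle_map <- function(am, path) {
  v <- round(am$angles)
  v[!am$mask] <- 65535
  write_gray(v, path, bit_depth = 16L)
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  write_gray(am$mask * 65535, mask_path, bit_depth = 16L)
  invisible(c(angles = path, mask = mask_path))
}
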