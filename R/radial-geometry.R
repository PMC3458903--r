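#' Optic-disc geometry
#'
#' @param center Numeric `(row, col)` of the disc centre, sub-pixel allowed.
#' @param radius_r Disc radius `r` in pixels (> 0). All radial measurements
#'   (and the 2r-3r annulus) are anchored to it.
#' @return A `disc_geometry` list.
#' @export
disc_geometry <- function(center, radius_r) {
  if (length(center) != 2L || !is.numeric(center)) {
    abort("`center` must be numeric (row, col).")
  }
  if (radius_r <= 0) abort("`radius_r` must be > 0.")
  structure(list(center = as.numeric(center), radius_r = radius_r),
            class = "disc_geometry")
}

#' Convert tangent angles to radial-relative angles
#'
#' For every vessel pixel the orientation of the ray from the disc centre to
#' the pixel is computed (mod 180 degrees) and the absolute angular
#' difference to the pixel's tangent angle is folded into \[0, 90] degrees:
#' 0 means the vessel radiates from the disc, 90 means it runs concentric to
#' it. Background pixels keep the sentinel and stay unmasked. A pixel exactly
#' at the disc centre has no radial direction and is dropped from the mask
#' (with a message reporting the count).
#'
#' @param lw An `angle_map` with convention `"tangent_cartesian"`, e.g. from
#'   [angle_field()].
#' @param disc A [disc_geometry()].
#' @return An `angle_map` with `convention = "radial_relative"`; `angles` are
#'   in \[0, 90] on the mask and 0 elsewhere.
#' @export
radialize <- function(lw, disc) {
  stopifnot(inherits(lw, "angle_map"), inherits(disc, "disc_geometry"))
  if (lw$convention != "tangent_cartesian") {
    abort("`lw` must be a tangent_cartesian angle map.")
  }
  mask <- lw$mask
  angles <- matrix(0, nrow(lw$angles), ncol(lw$angles))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    dr <- idx[, 1] - disc$center[1]
    dc <- idx[, 2] - disc$center[2]
    at_center <- dr == 0 & dc == 0
    if (any(at_center)) {
      inform(sprintf(
        "radialize(): dropped %d pixel(s) coincident with the disc centre.",
        sum(at_center)
      ))
      mask[idx[at_center, , drop = FALSE]] <- FALSE
      idx <- idx[!at_center, , drop = FALSE]
      dr <- dr[!at_center]; dc <- dc[!at_center]
    }
    psi <- dir_angle_deg(dr, dc) %% 180
    angles[idx] <- fold_angle(lw$angles[idx] - psi)
  }
  new_angle_map(angles, mask, "radial_relative")
}
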