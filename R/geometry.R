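#' Scaling factor between a registration image and the full-resolution image
#'
#' Visium registration is often run on a down-sized copy of the H&E image
#' (for example a 30 percent copy); spot coordinates must then be scaled
#' back. The factor is the registration-image height divided by the
#' full-image height.
#'
#' @param full_height_px,registered_height_px image heights in pixels.
#' @return the scalar `s = registered / full`, with `0 < s <= 1`.
#' @examples
#' compute_scale_factor(20000, 6000)  # 0.3
#' @export
compute_scale_factor <- function(full_height_px, registered_height_px) {
  if (full_height_px <= 0 || registered_height_px <= 0)
    stop("image heights must be > 0")
  if (registered_height_px > full_height_px)
    stop("registration image cannot be taller than the full image")
  registered_height_px / full_height_px
}

#' Geometry linking the registration frame to the full-resolution frame
#'
#' @param full_width_px,full_height_px full-resolution image size.
#' @param registered_height_px height of the registration image; used to
#'   derive `scale` when it is not given directly.
#' @param scale the scaling factor; computed from the heights when `NULL`.
#' @param y_flip whether the registration frame has its y axis reversed, in
#'   which case the full-resolution y is the full height minus the scaled y.
#' @return list of class `image_geometry`.
#' @export
image_geometry <- function(full_width_px, full_height_px,
                           registered_height_px = NULL, scale = NULL,
                           y_flip = FALSE) {
  if (is.null(scale)) {
    if (is.null(registered_height_px))
      stop("either scale or registered_height_px is required")
    scale <- compute_scale_factor(full_height_px, registered_height_px)
  }
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  structure(list(full_width_px = full_width_px,
                 full_height_px = full_height_px,
                 scale = scale, y_flip = isTRUE(y_flip)),
            class = "image_geometry")
}

#' Transform a spot grid from the registration frame to full resolution
#'
#' Centers and radii are divided by the scaling factor; when the geometry
#' declares a y flip, the scaled y is subtracted from the full image height.
#' Spots landing outside the image are kept but flagged (`out_of_bounds`)
#' with a warning.
#'
#' @param grid a `spot_grid` in the registration frame.
#' @param geom an [image_geometry()].
#' @return the grid in the full-resolution frame (`frame` attribute updated).
#' @export
registered_to_fullres <- function(grid, geom) {
  stopifnot(inherits(geom, "image_geometry"))
  fr <- attr(grid, "frame")
  if (!is.null(fr) && fr == "fullres")
    stop("grid is already in the full-resolution frame")
  s <- geom$scale
  g <- grid
  g$x <- grid$x / s
  ys <- grid$y / s
  g$y <- if (geom$y_flip) geom$full_height_px - ys else ys
  if (!is.null(g$radius)) g$radius <- grid$radius / s
  oob <- g$x < 0 | g$x > geom$full_width_px |
    g$y < 0 | g$y > geom$full_height_px
  g$out_of_bounds <- oob
  if (any(oob))
    warning(sum(oob), " spot(s) transformed outside the image; kept and flagged")
  attr(g, "frame") <- "fullres"
  g
}

#' Inverse transform: full-resolution frame back to the registration frame
#'
#' Exact inverse of [registered_to_fullres()], so composing the two recovers
#' the input coordinates.
#'
#' @inheritParams registered_to_fullres
#' @export
fullres_to_registered <- function(grid, geom) {
  stopifnot(inherits(geom, "image_geometry"))
  s <- geom$scale
  g <- grid
  yf <- if (geom$y_flip) geom$full_height_px - grid$y else grid$y
  g$x <- grid$x * s
  g$y <- yf * s
  if (!is.null(g$radius)) g$radius <- grid$radius * s
  g$out_of_bounds <- NULL
  attr(g, "frame") <- "registered"
  g
}
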