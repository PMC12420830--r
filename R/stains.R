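#' Stain model for H&E colour deconvolution
#'
#' Bundles the unit optical-density (OD) vectors of hematoxylin and eosin,
#' the background (unstained) RGB level, and a residual third vector
#' orthogonal to both stains. Stain amounts mix linearly in OD space
#' (Beer-Lambert), so the three vectors form a basis used to separate the
#' two dyes.
#'
#' @param hematoxylin,eosin numeric length-3 OD direction vectors; they are
#'   normalized to unit Euclidean norm. Components must be non-negative and
#'   the two directions must not be collinear (angle > 1 degree).
#' @param background RGB level of unstained pixels on the 0-255 scale.
#' @return An object of class `stain_model`.
#' @examples
#' sm <- stain_model()
#' sm$hematoxylin
#' @export
stain_model <- function(hematoxylin = c(0.651, 0.701, 0.290),
                        eosin = c(0.093, 0.954, 0.283),
                        background = c(255, 255, 255)) {
  h <- as.numeric(hematoxylin)
  e <- as.numeric(eosin)
  if (length(h) != 3L || length(e) != 3L || length(background) != 3L)
    stop("stain vectors and background must have length 3")
  if (any(h < 0) || any(e < 0))
    stop("stain vector components must be non-negative")
  if (any(!is.finite(h)) || any(!is.finite(e)) ||
      sum(h^2) == 0 || sum(e^2) == 0)
    stop("stain vectors must be finite and non-zero")
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  ang <- acos(pmin(1, sum(h * e))) * 180 / pi
  if (ang <= 1)
    stop("hematoxylin and eosin vectors are collinear (angle <= 1 degree)")
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  structure(list(hematoxylin = h, eosin = e, residual = r,
                 background = as.numeric(background)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("H&E stain model\n")
  cat(sprintf("  hematoxylin OD: (%.3f, %.3f, %.3f)\n",
              x$hematoxylin[1], x$hematoxylin[2], x$hematoxylin[3]))
  cat(sprintf("  eosin OD:       (%.3f, %.3f, %.3f)\n",
              x$eosin[1], x$eosin[2], x$eosin[3]))
  cat(sprintf("  background RGB: (%g, %g, %g)\n",
              x$background[1], x$background[2], x$background[3]))
  invisible(x)
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform per channel:
#' `OD_c = log10(background_c / max(pixel_c, 1))`, clipped to `[0, od_max]`.
#' Unstained pixels (equal to the background) map to zero OD; saturated black
#' pixels map to `od_max`.
#'
#' @param image numeric array `height x width x 3` on the 0-255 scale.
#' @param background length-3 background RGB (values > 0).
#' @param od_max upper OD clip (default 3).
#' @param pixel_size physical pixel size in micrometres per pixel, carried
#'   along for downstream geometry; may be `NULL` for pixel-unit work.
#' @return An `od_image`: list with `od` (same shape as `image`),
#'   `pixel_size`, `od_max`.
#' @export
rgb_to_od <- function(image, background = c(255, 255, 255), od_max = 3,
                      pixel_size = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an RGB array (height x width x 3)")
  if (any(background <= 0)) stop("background channel values must be > 0")
  od <- array(0, dim = dim(image))
  for (c in 1:3) {
    ch <- log10(background[c] / pmax(image[, , c], 1))
    ch[image[, , c] <= 0] <- od_max   # zero transmittance: clip rule
    od[, , c] <- ch
  }
  od[od < 0] <- 0
  od[od > od_max] <- od_max
  structure(list(od = od, pixel_size = pixel_size, od_max = od_max),
            class = "od_image")
}

#' Estimate H&E stain vectors from an image
#'
#' Automated stain-vector estimation in the Macenko style. The background
#' level is taken from high-brightness pixels; pixels with negligible total
#' OD are dropped; pixels whose OD direction lies far from the plane spanned
#' by the two dominant OD components (unrecognized colours) are excluded;
#' the hematoxylin and eosin directions are then the extreme-angle
#' percentiles of the remaining OD directions within that plane.
#'
#' @param image RGB array (`height x width x 3`, 0-255).
#' @param roi_mask optional logical matrix selecting the region of interest;
#'   it should cover both stained tissue and blank background.
#' @param beta minimum OD norm for a pixel to count as stained (default 0.15).
#' @param alpha angle percentile for the extreme directions (default 1, i.e.
#'   the 1st and 99th percentiles).
#' @param resid_max maximum out-of-plane fraction of a pixel's OD before it
#'   is discarded as an unrecognized colour (default 0.3).
#' @param min_stained,min_background minimum pixel counts required in each
#'   category.
#' @param bright_quantile brightness quantile defining background pixels.
#' @return A [stain_model()].
#' @export
estimate_stain_vectors <- function(image, roi_mask = NULL, beta = 0.15,
                                   alpha = 1, resid_max = 0.3,
                                   min_stained = 200, min_background = 50,
                                   bright_quantile = 0.9) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an RGB array (height x width x 3)")
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  if (!is.null(roi_mask)) px <- px[as.vector(roi_mask), , drop = FALSE]
  bright <- rowMeans(px)
  bg_sel <- bright >= stats::quantile(bright, bright_quantile)
  if (sum(bg_sel) < min_background)
    stop("insufficient background pixels to estimate the background level")
  bg <- apply(px[bg_sel, , drop = FALSE], 2, stats::median)
  bg <- pmax(bg, 1)

  od <- cbind(log10(bg[1] / pmax(px[, 1], 1)),
              log10(bg[2] / pmax(px[, 2], 1)),
              log10(bg[3] / pmax(px[, 3], 1)))
  od[od < 0] <- 0
  nrm <- sqrt(rowSums(od^2))
  od <- od[nrm > beta, , drop = FALSE]
  if (nrow(od) < min_stained) stop("insufficient stained pixels")

  # plane of the two dominant OD components; drop out-of-plane colours
  sv <- svd(od, nu = 0, nv = 3)
  plane <- sv$v[, 1:2, drop = FALSE]
  proj <- od %*% plane
  resid <- sqrt(pmax(rowSums(od^2) - rowSums(proj^2), 0)) /
    sqrt(rowSums(od^2))
  keep <- resid <= resid_max
  if (sum(keep) < min_stained) stop("insufficient stained pixels")
  od <- od[keep, , drop = FALSE]
  sv <- svd(od, nu = 0, nv = 2)
  plane <- sv$v
  # orient basis so projections are mostly positive
  proj <- od %*% plane
  if (sum(proj[, 1]) < 0) { plane[, 1] <- -plane[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(alpha, 100 - alpha) / 100)
  v1 <- plane %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- plane %*% c(cos(qs[2]), sin(qs[2]))
  fix <- function(v) {
    v <- as.numeric(v)
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  v1 <- fix(v1); v2 <- fix(v2)
  cosang <- sum(v1 * v2)
  if (cosang > cos(pi / 180))
    stop("degenerate stain estimate: recovered vectors are collinear")
  # hematoxylin absorbs red more strongly than eosin does
  if (v1[1] >= v2[1]) {
    stain_model(hematoxylin = v1, eosin = v2, background = bg)
  } else {
    stain_model(hematoxylin = v2, eosin = v1, background = bg)
  }
}

#' Per-pixel stain densities by colour deconvolution
#'
#' Inverts the 3x3 OD basis (hematoxylin, eosin, residual) to obtain the
#' amount of each stain at every pixel. Negative amounts are clipped to 0.
#'
#' @param od an [rgb_to_od()] result.
#' @param stains a [stain_model()].
#' @return list with matrices `hematoxylin`, `eosin` (height x width).
#' @export
stain_densities <- function(od, stains) {
  stopifnot(inherits(od, "od_image"), inherits(stains, "stain_model"))
  d <- dim(od$od)
  M <- cbind(stains$hematoxylin, stains$eosin, stains$residual)
  odm <- cbind(as.vector(od$od[, , 1]), as.vector(od$od[, , 2]),
               as.vector(od$od[, , 3]))
  conc <- odm %*% t(solve(M))
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       eosin = matrix(conc[, 2], d[1], d[2]))
}
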