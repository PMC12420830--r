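#' Parameters for a synthetic H&E scene
#'
#' Defines a scene of elliptical nuclei with class-specific morphology and
#' stain intensity, rendered by Beer-Lambert mixing of hematoxylin and eosin
#' so that downstream optical-density arithmetic is exactly invertible.
#' Classes are separated by design: tumor nuclei are large and eosin-rich,
#' immune nuclei small, round and eosin-poor, stroma nuclei elongated with
#' intermediate eosin.
#'
#' @param width,height image size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param background background RGB (0-255).
#' @param counts named integer vector of cells per class; names must be
#'   `tumor`, `immune`, `stroma`.
#' @param radius_um per-class nucleus radius mean/sd in micrometres
#'   (list of length-2 vectors).
#' @param eccentricity per-class eccentricity ranges in `[0, 1)`.
#' @param hema_intensity,eosin_intensity per-class stain-amount ranges
#'   (unitless OD multipliers).
#' @param min_spacing_um minimum centroid spacing in micrometres.
#' @param cyto_scale cytoplasm halo size as a multiple of the nucleus axes.
#' @param edge_sigma_px Gaussian edge blur applied to the stain maps.
#' @param seed random seed; the scene is a pure function of the parameters.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(width = 1024, height = 1024, pixel_size = 0.5,
                         background = c(255, 255, 255),
                         counts = c(tumor = 50, immune = 50, stroma = 50),
                         radius_um = list(tumor = c(6.0, 0.6),
                                          immune = c(2.8, 0.3),
                                          stroma = c(4.0, 0.4)),
                         eccentricity = list(tumor = c(0.3, 0.6),
                                             immune = c(0.0, 0.2),
                                             stroma = c(0.75, 0.9)),
                         hema_intensity = list(tumor = c(0.8, 1.0),
                                               immune = c(1.0, 1.2),
                                               stroma = c(0.7, 0.9)),
                         eosin_intensity = list(tumor = c(0.50, 0.65),
                                                immune = c(0.05, 0.15),
                                                stroma = c(0.25, 0.35)),
                         min_spacing_um = 18, cyto_scale = 1.7,
                         edge_sigma_px = 1.2, seed = 1) {
  classes <- c("tumor", "immune", "stroma")
  counts <- counts[classes]
  names(counts) <- classes
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop("per-class counts must be >= 0")
  if (pixel_size <= 0) stop("pixel size must be > 0")
  if (min_spacing_um < 0) stop("minimum spacing must be >= 0")
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 background = background, counts = counts,
                 radius_um = radius_um, eccentricity = eccentricity,
                 hema_intensity = hema_intensity,
                 eosin_intensity = eosin_intensity,
                 min_spacing_um = min_spacing_um, cyto_scale = cyto_scale,
                 edge_sigma_px = edge_sigma_px, seed = seed),
            class = "scene_params")
}

# Rasterize an ellipse into a window of `target` (matrix indexed [row, col]),
# adding `value` where the ellipse covers the pixel centre.
.draw_ellipse <- function(target, cx, cy, a, b, theta, value) {
  h <- nrow(target); w <- ncol(target)
  r <- ceiling(max(a, b)) + 1L
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(target)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys - cy, xs - cx, function(y, x) x)   # constant over rows
  dy <- outer(ys - cy, xs - cx, function(y, x) y)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- target[ys + 1L, xs + 1L, drop = FALSE]
  sub[inside] <- sub[inside] + value
  target[ys + 1L, xs + 1L] <- sub
  target
}

#' Generate a synthetic H&E scene with ground truth
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, draws a
#' hematoxylin amount per nucleus and a fainter eosin cytoplasm halo, blurs
#' the stain maps for soft edges, and renders
#' `RGB_c = background_c * 10^-(A_h * H_c + A_e * E_c)` with the stain
#' vectors of `stains`. The transform is the exact inverse of
#' [rgb_to_od()] followed by [stain_densities()].
#'
#' @param params a [scene_params()].
#' @param stains a [stain_model()] providing the mixing vectors.
#' @param max_attempts rejection-sampling cap for centroid placement.
#' @return `synthetic_scene`: list with `image` (height x width x 3 double
#'   array, 0-255), `truth` (data.frame: id, x, y in full-resolution pixels
#'   with 0-based top-left origin, class, nucleus area in square
#'   micrometres), `params`, `stains`.
#' @export
generate_he_scene <- function(params = scene_params(), stains = stain_model(),
                              max_attempts = 1e5) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$seed)
  psz <- p$pixel_size
  classes <- names(p$counts)
  n_total <- sum(p$counts)
  hema <- matrix(0, p$height, p$width)
  eosin <- matrix(0, p$height, p$width)
  truth <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      class = character(0), nucleus_area_um2 = numeric(0))
  if (n_total > 0) {
    spacing_px <- p$min_spacing_um / psz
    margin <- max(vapply(classes, function(cl) {
      r <- p$radius_um[[cl]][1] + 3 * p$radius_um[[cl]][2]
      e <- max(p$eccentricity[[cl]])
      (r / (1 - e^2)^0.25) * p$cyto_scale / psz
    }, numeric(1))) + 2
    if (2 * margin >= min(p$width, p$height))
      stop("image too small for the requested nucleus sizes")
    cls <- rep(classes, times = p$counts)
    xs <- numeric(n_total); ys <- numeric(n_total)
    attempts <- 0L
    for (i in seq_len(n_total)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "packing infeasible after %d attempts while placing a '%s' cell (densest class: %s)",
            max_attempts, cls[i],
            names(which.max(p$counts))))
        x <- stats::runif(1, margin, p$width - 1 - margin)
        y <- stats::runif(1, margin, p$height - 1 - margin)
        if (i == 1L) break
        d2 <- (xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2
        if (min(d2) >= spacing_px^2) break
      }
      xs[i] <- x; ys[i] <- y
    }
    area <- numeric(n_total)
    for (i in seq_len(n_total)) {
      cl <- cls[i]
      r_um <- max(1, stats::rnorm(1, p$radius_um[[cl]][1], p$radius_um[[cl]][2]))
      ecc <- stats::runif(1, p$eccentricity[[cl]][1], p$eccentricity[[cl]][2])
      theta <- stats::runif(1, 0, pi)
      hi <- stats::runif(1, p$hema_intensity[[cl]][1], p$hema_intensity[[cl]][2])
      ei <- stats::runif(1, p$eosin_intensity[[cl]][1], p$eosin_intensity[[cl]][2])
      # ellipse with area pi * r^2 and the drawn eccentricity
      f <- (1 - ecc^2)^0.25
      a <- (r_um / f) / psz
      b <- (r_um * f) / psz
      hema <- .draw_ellipse(hema, xs[i], ys[i], a, b, theta, hi)
      # eosin cytoplasm as an annulus: hematoxylin dominates the nucleus
      eosin <- .draw_ellipse(eosin, xs[i], ys[i], a * p$cyto_scale,
                             b * p$cyto_scale, theta, ei)
      eosin <- .draw_ellipse(eosin, xs[i], ys[i], a, b, theta, -ei)
      area[i] <- pi * r_um^2
    }
    truth <- data.frame(id = seq_len(n_total), x = xs, y = ys, class = cls,
                        nucleus_area_um2 = area, stringsAsFactors = FALSE)
  }
  eosin[eosin < 0] <- 0
  if (p$edge_sigma_px > 0 && n_total > 0) {
    hema <- .gaussian_blur(hema, p$edge_sigma_px)
    eosin <- .gaussian_blur(eosin, p$edge_sigma_px)
  }
  img <- array(0, dim = c(p$height, p$width, 3))
  H <- stains$hematoxylin; E <- stains$eosin
  for (c in 1:3) {
    img[, , c] <- p$background[c] * 10^-(hema * H[c] + eosin * E[c])
  }
  structure(list(image = img, truth = truth, params = p, stains = stains),
            class = "synthetic_scene")
}

# Gaussian blur of a plain [row, col] matrix via EBImage (which indexes
# [x, y], hence the transposes).
.gaussian_blur <- function(m, sigma_px) {
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma_px)))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic H&E scene: %d x %d px, %.3g um/px, %d cells\n",
              x$params$width, x$params$height, x$params$pixel_size,
              nrow(x$truth)))
  if (nrow(x$truth)) print(table(x$truth$class))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Saves the image as an 8-bit TIFF (requires the tiff package) and the
#' ground-truth table as TSV.
#'
#' @param scene a [generate_he_scene()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, "scene.tiff")
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF images")
  tiff::writeTIFF(scene$image / 255, tif,
                  compression = "none", bits.per.sample = 8L)
  tsv <- file.path(dir, "truth.tsv")
  utils::write.table(scene$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(image = tif, truth = tsv))
}
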