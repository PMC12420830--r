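#' Nucleus segmentation parameters
#'
#' @param sigma_um Gaussian smoothing of the hematoxylin channel, in
#'   micrometres (converted to pixels with the image pixel size). When the
#'   image carries no pixel size, the value is interpreted in pixels.
#' @param threshold `"otsu"` for an automatic global threshold on the
#'   smoothed hematoxylin channel, or a numeric OD value.
#' @param min_area_um2,max_area_um2 object area bounds in square
#'   micrometres; objects outside are discarded.
#' @param tolerance watershed tolerance (minimum depth, in distance-map
#'   units, separating two catchment basins).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_um = 1.5, threshold = "otsu",
                                min_area_um2 = 5, max_area_um2 = 400,
                                tolerance = 1) {
  structure(list(sigma_um = sigma_um, threshold = threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 tolerance = tolerance),
            class = "segmentation_params")
}

#' Segment nuclei in the hematoxylin channel
#'
#' Projects the optical-density image onto the hematoxylin stain vector,
#' smooths it, thresholds it (Otsu by default), and splits touching nuclei
#' by a marker-controlled watershed on the distance transform. Objects
#' outside the configured area bounds are discarded.
#'
#' @param od an [rgb_to_od()] result.
#' @param stains a [stain_model()].
#' @param params a [segmentation_params()].
#' @return `nucleus_set`: list with `labels` (integer matrix, 0 =
#'   background, nuclei labelled 1..n), `table` (data.frame: id, x, y
#'   centroid in 0-based pixels, area_px, perimeter_px), `pixel_size`.
#' @export
segment_nuclei <- function(od, stains, params = segmentation_params()) {
  stopifnot(inherits(od, "od_image"), inherits(stains, "stain_model"))
  p <- params
  psz <- if (is.null(od$pixel_size)) 1 else od$pixel_size
  H <- stains$hematoxylin
  hchan <- od$od[, , 1] * H[1] + od$od[, , 2] * H[2] + od$od[, , 3] * H[3]
  sigma_px <- p$sigma_um / psz
  sm <- if (sigma_px > 0) .gaussian_blur(hchan, sigma_px) else hchan
  thr <- if (identical(p$threshold, "otsu")) {
    rng <- max(sm)
    if (rng <= 0) Inf else EBImage::otsu(EBImage::Image(t(sm) / rng),
                                         range = c(0, 1)) * rng
  } else as.numeric(p$threshold)
  mask <- sm > thr
  empty <- structure(list(labels = matrix(0L, nrow(hchan), ncol(hchan)),
                          table = data.frame(id = integer(0), x = numeric(0),
                                             y = numeric(0),
                                             area_px = numeric(0),
                                             perimeter_px = numeric(0)),
                          pixel_size = od$pixel_size),
                     class = "nucleus_set")
  if (!any(mask)) return(empty)
  maske <- EBImage::Image(t(mask) * 1)
  dm <- EBImage::distmap(maske)
  lab <- EBImage::watershed(dm, tolerance = p$tolerance, ext = 1)
  labm <- t(EBImage::imageData(lab))
  # area filter in physical units
  sizes <- tabulate(labm[labm > 0])
  lo <- p$min_area_um2 / psz^2
  hi <- p$max_area_um2 / psz^2
  keep <- which(sizes >= lo & sizes <= hi)
  if (!length(keep)) return(empty)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labm[labm > 0] <- relab[labm[labm > 0]]
  tab <- .label_shape_table(labm)
  structure(list(labels = labm, table = tab, pixel_size = od$pixel_size),
            class = "nucleus_set")
}

# centroid / area / perimeter per label of an integer label matrix
# (0-based x = column, y = row coordinates)
.label_shape_table <- function(labm) {
  n <- max(labm)
  if (n == 0L)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = numeric(0), perimeter_px = numeric(0)))
  idx <- which(labm > 0)
  lab <- labm[idx]
  yy <- (idx - 1) %% nrow(labm)          # 0-based row
  xx <- (idx - 1) %/% nrow(labm)         # 0-based column
  data.frame(id = seq_len(n),
             x = as.numeric(tapply(xx, lab, mean)),
             y = as.numeric(tapply(yy, lab, mean)),
             area_px = tabulate(lab, n),
             perimeter_px = .label_perimeters(labm, n),
             row.names = NULL)
}

# Crofton-corrected perimeter: count 4-neighbour boundary edge transitions
# per label and scale by pi/4, which is exact for disks (8r edges -> 2*pi*r)
# and unbiased for randomly oriented convex shapes.
.label_perimeters <- function(labm, n) {
  h <- nrow(labm); w <- ncol(labm)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- labm
  core <- pad[2:(h + 1), 2:(w + 1)]
  per <- numeric(n)
  for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    nb <- pad[2:(h + 1) + sh[1], 2:(w + 1) + sh[2]]
    per <- per + tabulate(core[core > 0 & nb != core], n)
  }
  per * pi / 4
}

#' Expand nuclei into cell masks
#'
#' Dilates each nucleus by a fixed physical distance to approximate the cell
#' boundary. Expansions never overlap: a pixel within reach of several
#' nuclei is given to the nucleus with the nearest centroid (ties to the
#' lower id). The cell always contains its nucleus; the cytoplasm is the
#' cell minus the nucleus.
#'
#' @param nuclei a [segment_nuclei()] result.
#' @param expansion_um expansion distance in micrometres (>= 0); interpreted
#'   in pixels when the nucleus set carries no pixel size.
#' @return `cell_set`: list with `cell_labels`, `nucleus_labels` (integer
#'   matrices sharing ids), `pixel_size`, `expansion_um`.
#' @export
expand_cells <- function(nuclei, expansion_um) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  if (expansion_um < 0) stop("expansion must be >= 0")
  labm <- nuclei$labels
  psz <- if (is.null(nuclei$pixel_size)) 1 else nuclei$pixel_size
  exp_px <- expansion_um / psz
  if (exp_px == 0 || nrow(nuclei$table) == 0L) {
    return(structure(list(cell_labels = labm, nucleus_labels = labm,
                          pixel_size = nuclei$pixel_size,
                          expansion_um = expansion_um),
                     class = "cell_set"))
  }
  h <- nrow(labm); w <- ncol(labm)
  tab <- nuclei$table
  best_d2 <- matrix(Inf, h, w)       # distance^2 to the claiming centroid
  cells <- matrix(0L, h, w)
  r <- ceiling(exp_px) + 1L
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    sel <- which(labm == id)
    ry <- (sel - 1) %% h; rx <- (sel - 1) %/% h
    y0 <- max(0L, min(ry) - r); y1 <- min(h - 1L, max(ry) + r)
    x0 <- max(0L, min(rx) - r); x1 <- min(w - 1L, max(rx) + r)
    sub <- labm[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
    # distance of every window pixel to this nucleus mask
    dm <- t(EBImage::imageData(EBImage::distmap(
      EBImage::Image(t(1 - (sub == id))))))
    reach <- dm <= exp_px & (sub == 0 | sub == id)
    if (!any(reach)) next
    widx <- which(reach)
    wy <- (widx - 1) %% nrow(sub) + y0
    wx <- (widx - 1) %/% nrow(sub) + x0
    d2 <- (wx - tab$x[i])^2 + (wy - tab$y[i])^2
    gidx <- wy + 1L + wx * h
    claim <- d2 < best_d2[gidx] |
      (d2 == best_d2[gidx] & id < cells[gidx] & cells[gidx] > 0L)
    gi <- gidx[claim]
    best_d2[gi] <- d2[claim]
    cells[gi] <- id
  }
  cells[labm > 0] <- labm[labm > 0]   # nucleus pixels always belong to the cell
  structure(list(cell_labels = cells, nucleus_labels = labm,
                 pixel_size = nuclei$pixel_size, expansion_um = expansion_um),
            class = "cell_set")
}
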