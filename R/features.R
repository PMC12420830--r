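#' Per-cell morphology and stain-density features
#'
#' Builds the cell feature table: nuclear and cell areas in square
#' micrometres, nuclear circularity `4*pi*A/P^2` (capped at 1), and the
#' mean and maximum hematoxylin and eosin densities (colour-deconvolved OD)
#' over the nucleus, the cytoplasm and the whole cell. Cells with an empty
#' cytoplasm keep their row with the cytoplasm features set to `NA`.
#'
#' @param nuclei a [segment_nuclei()] result.
#' @param cells an [expand_cells()] result aligned with `nuclei`.
#' @param od the [rgb_to_od()] image the masks were derived from.
#' @param stains a [stain_model()].
#' @param pixel_size micrometres per pixel; defaults to the value carried by
#'   `od`, or 1 (pixel units) when absent.
#' @return A `cell_feature_table` data.frame: `id`, `x`, `y` (full-resolution
#'   0-based pixels), `nucleus_area`, `cell_area` (um^2), `circularity`, and
#'   `<region>_<stain>_<stat>` density columns. Pixel size is carried as the
#'   `pixel_size` attribute.
#' @export
compute_features <- function(nuclei, cells, od, stains, pixel_size = NULL) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(cells, "cell_set"),
            inherits(od, "od_image"))
  psz <- pixel_size %||% od$pixel_size %||% 1
  tab <- nuclei$table
  dens <- stain_densities(od, stains)
  nl <- nuclei$labels; cl <- cells$cell_labels
  if (!identical(dim(nl), dim(cl)))
    stop("nucleus and cell masks must have identical dimensions")
  n <- nrow(tab)
  out <- data.frame(id = tab$id, x = tab$x, y = tab$y,
                    nucleus_area = tab$area_px * psz^2,
                    cell_area = NA_real_, circularity = NA_real_)
  circ <- 4 * pi * tab$area_px / pmax(tab$perimeter_px, 1e-9)^2
  out$circularity <- pmin(circ, 1)
  cell_area_px <- tabulate(cl[cl > 0], n)
  out$cell_area <- cell_area_px * psz^2
  regs <- list(nucleus = nl,
               cell = cl)
  cyto <- cl
  cyto[nl > 0] <- 0L
  regs$cytoplasm <- cyto
  for (reg in c("nucleus", "cytoplasm", "cell")) {
    m <- regs[[reg]]
    idx <- which(m > 0)
    lab <- m[idx]
    for (st in c("hema", "eosin")) {
      v <- if (st == "hema") dens$hematoxylin[idx] else dens$eosin[idx]
      mn <- rep(NA_real_, n); mx <- rep(NA_real_, n)
      if (length(lab)) {
        agg_m <- tapply(v, lab, mean)
        agg_x <- tapply(v, lab, max)
        ids <- as.integer(names(agg_m))
        mn[ids] <- as.numeric(agg_m)
        mx[ids] <- as.numeric(agg_x)
      }
      out[[paste0(reg, "_", st, "_mean")]] <- mn
      out[[paste0(reg, "_", st, "_max")]] <- mx
    }
  }
  attr(out, "pixel_size") <- psz
  class(out) <- c("cell_feature_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add distance-smoothed copies of every feature
#'
#' For each cell and each numeric feature, appends a Gaussian
#' distance-weighted mean over all cells within the smoothing support:
#' weight `exp(-d^2 / (2*sigma^2))` with `sigma = radius / 2` and support
#' `2 * radius`; the cell itself contributes with weight 1. Original
#' columns are retained; run once per radius (the conventional pair is
#' 25 um and 50 um).
#'
#' @param table a [compute_features()] result (or any data.frame with `x`,
#'   `y` and numeric feature columns).
#' @param radius smoothing radius in micrometres when the table carries a
#'   pixel size, else in pixels.
#' @param exclude columns never smoothed (ids and coordinates).
#' @return the table with `<feature>_smoothed_<radius>` columns appended.
#' @export
smooth_features <- function(table, radius,
                            exclude = c("id", "x", "y", "class")) {
  psz <- attr(table, "pixel_size") %||% 1
  n <- nrow(table)
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   exclude)
  suffix <- paste0("_smoothed_", radius)
  if (n == 0L) {
    for (f in feats) table[[paste0(f, suffix)]] <- numeric(0)
    return(table)
  }
  xu <- table$x * psz; yu <- table$y * psz
  sigma <- radius / 2
  support <- 2 * radius
  d2 <- outer(xu, xu, "-")^2 + outer(yu, yu, "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > support^2] <- 0
  diag(w) <- 1
  for (f in feats) {
    v <- table[[f]]
    ok <- is.finite(v)
    wm <- w
    wm[, !ok] <- 0
    num <- wm %*% ifelse(ok, v, 0)
    den <- rowSums(wm)
    sm <- as.numeric(num) / den
    sm[den == 0] <- NA_real_
    table[[paste0(f, suffix)]] <- sm
  }
  table
}
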