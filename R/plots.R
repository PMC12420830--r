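#' Plot a scene or image with per-cell class colouring
#'
#' Renders the RGB image with cell centroids overdrawn in the conventional
#' palette (tumor red, immune yellow, stroma blue), and optionally the spot
#' circles of a grid.
#'
#' @param image height x width x 3 array (0-255).
#' @param cells optional data.frame with `x`, `y`, `class`.
#' @param grid optional `spot_grid` in the same frame.
#' @param palette named colours per class.
#' @param ... passed to [graphics::rasterImage()]'s plot set-up.
#' @return invisibly `NULL`.
#' @export
plot_annotated_image <- function(image, cells = NULL, grid = NULL,
                                 palette = c(tumor = "red",
                                             immune = "gold",
                                             stroma = "blue"), ...) {
  h <- dim(image)[1]; w <- dim(image)[2]
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  graphics::rasterImage(image / 255, 0, h, w, 0)
  if (!is.null(cells) && nrow(cells))
    graphics::points(cells$x, cells$y, col = palette[cells$class],
                     pch = 16, cex = 0.5)
  if (!is.null(grid) && nrow(grid))
    graphics::symbols(grid$x, grid$y, circles = grid$radius, inches = FALSE,
                      add = TRUE, fg = "grey30")
  invisible(NULL)
}

#' Magnified crop of one spot with per-cell class colouring
#'
#' @param image height x width x 3 array (0-255).
#' @param grid `spot_grid` containing `barcode`.
#' @param barcode the spot to crop.
#' @param cells data.frame with `x`, `y`, `class`.
#' @param pad_px margin around the spot circle.
#' @inheritParams plot_annotated_image
#' @return invisibly `NULL`.
#' @export
plot_spot_crop <- function(image, grid, barcode, cells = NULL, pad_px = 20,
                           palette = c(tumor = "red", immune = "gold",
                                       stroma = "blue")) {
  i <- match(barcode, grid$barcode)
  if (is.na(i)) stop("unknown spot barcode: ", barcode)
  r <- grid$radius[i] + pad_px
  h <- dim(image)[1]; w <- dim(image)[2]
  x0 <- max(0, floor(grid$x[i] - r)); x1 <- min(w - 1, ceiling(grid$x[i] + r))
  y0 <- max(0, floor(grid$y[i] - r)); y1 <- min(h - 1, ceiling(grid$y[i] + r))
  crop <- image[(y0:y1) + 1, (x0:x1) + 1, , drop = FALSE]
  graphics::plot(NA, xlim = c(x0, x1), ylim = c(y1, y0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", main = barcode)
  graphics::rasterImage(crop / 255, x0, y1, x1, y0)
  graphics::symbols(grid$x[i], grid$y[i], circles = grid$radius[i],
                    inches = FALSE, add = TRUE, fg = "grey20", lwd = 2)
  if (!is.null(cells)) {
    sel <- cells$x >= x0 & cells$x <= x1 & cells$y >= y0 & cells$y <= y1
    graphics::points(cells$x[sel], cells$y[sel],
                     col = palette[cells$class[sel]], pch = 16)
  }
  invisible(NULL)
}

#' Heatmap of a CNV profile ordered by clone and chromosome
#'
#' @param profile a [infer_cnv_profile()] result.
#' @param clones optional [call_clones()] assignment ordering the rows.
#' @param zlim colour range (symmetric around 0).
#' @return invisibly `NULL`.
#' @export
plot_cnv_heatmap <- function(profile, clones = NULL, zlim = c(-0.5, 0.5)) {
  x <- profile$profile[profile$role == "query", , drop = FALSE]
  if (!is.null(clones))
    x <- x[clones$barcode[order(clones$clone)], , drop = FALSE]
  x[x < zlim[1]] <- zlim[1]; x[x > zlim[2]] <- zlim[2]
  cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(t(x)[, rev(seq_len(nrow(x))), drop = FALSE], col = cols,
                  zlim = zlim, axes = FALSE,
                  xlab = "genes (genomic order)", ylab = "query spots")
  bounds <- cumsum(table(profile$genes$chr)[unique(profile$genes$chr)])
  graphics::abline(v = utils::head(bounds, -1) / ncol(x), col = "grey40")
  invisible(NULL)
}
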