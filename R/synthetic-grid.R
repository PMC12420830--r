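#' Parameters for a hexagonal Visium-style spot lattice
#'
#' @param rows,cols array rows and columns.
#' @param pitch_um center-to-center distance within a row, in micrometres;
#'   adjacent rows are offset by half a pitch and spaced `pitch * sqrt(3)/2`
#'   apart, giving the hexagonal packing.
#' @param diameter_um spot diameter in micrometres (Visium spots are 55 um).
#' @param pixel_size micrometres per pixel of the target image frame.
#' @param origin_px `(x, y)` pixel offset of spot (row 0, col 0).
#' @return list of class `grid_params`.
#' @export
grid_params <- function(rows = 8, cols = 8, pitch_um = 100, diameter_um = 55,
                        pixel_size = 0.5, origin_px = c(150, 150)) {
  if (pitch_um <= diameter_um || diameter_um <= 0)
    stop("pitch must exceed the spot diameter, and both must be positive")
  if (pixel_size <= 0) stop("pixel size must be > 0")
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_um = pitch_um, diameter_um = diameter_um,
                 pixel_size = pixel_size, origin_px = origin_px),
            class = "grid_params")
}

#' Generate a hexagonally packed spot grid
#'
#' Spot centers follow the hexagonal lattice: within a row, centers are one
#' pitch apart; odd array rows are shifted right by half a pitch; row
#' spacing is `pitch * sqrt(3)/2`. The spot radius in pixels is
#' `diameter / (2 * pixel_size)`.
#'
#' @param params a [grid_params()].
#' @return A `spot_grid` data.frame: `barcode`, `array_row`, `array_col`,
#'   `x`, `y` (center, px), `radius` (px), `in_tissue`. Attributes: `frame`
#'   (`"fullres"`), `pixel_size`, `pitch_um`, `diameter_um`.
#' @export
generate_spot_grid <- function(params = grid_params()) {
  stopifnot(inherits(params, "grid_params"))
  p <- params
  pitch_px <- p$pitch_um / p$pixel_size
  ar <- rep(seq_len(p$rows) - 1L, each = p$cols)
  ac <- rep(seq_len(p$cols) - 1L, times = p$rows)
  x <- p$origin_px[1] + ac * pitch_px + (ar %% 2L) * pitch_px / 2
  y <- p$origin_px[2] + ar * pitch_px * sqrt(3) / 2
  g <- data.frame(
    barcode = sprintf("SPOT-%04d", seq_along(x)),
    array_row = ar, array_col = ac, x = x, y = y,
    radius = p$diameter_um / (2 * p$pixel_size),
    in_tissue = 1L, stringsAsFactors = FALSE)
  attr(g, "frame") <- "fullres"
  attr(g, "pixel_size") <- p$pixel_size
  attr(g, "pitch_um") <- p$pitch_um
  attr(g, "diameter_um") <- p$diameter_um
  class(g) <- c("spot_grid", "data.frame")
  g
}
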