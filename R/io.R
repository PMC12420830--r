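#' Read a Space Ranger `tissue_positions_list.csv`
#'
#' Accepts both the headerless dialect (older Space Ranger) and the
#' headered one. Columns are barcode, in_tissue, array_row, array_col,
#' pxl_row_in_fullres, pxl_col_in_fullres; pixel row maps to y and pixel
#' column to x.
#'
#' @param path CSV path.
#' @param scalefactors optional [read_scalefactors()] result supplying the
#'   spot radius (`spot_diameter_fullres / 2`).
#' @return a `spot_grid` data.frame in the full-resolution frame.
#' @export
read_tissue_positions <- function(path, scalefactors = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  g <- data.frame(barcode = df$barcode,
                  array_row = df$array_row, array_col = df$array_col,
                  x = df$pxl_col_in_fullres, y = df$pxl_row_in_fullres,
                  radius = if (is.null(scalefactors)) NA_real_ else
                    scalefactors$spot_diameter_fullres / 2,
                  in_tissue = df$in_tissue, stringsAsFactors = FALSE)
  attr(g, "frame") <- "fullres"
  class(g) <- c("spot_grid", "data.frame")
  g
}

#' Write a spot grid in the Space Ranger dialect
#'
#' Writes a headerless `tissue_positions_list.csv` plus a
#' `scalefactors_json.json` carrying `spot_diameter_fullres` and
#' `tissue_hires_scalef`.
#'
#' @param grid a `spot_grid` (full-resolution frame).
#' @param dir output directory.
#' @param tissue_hires_scalef scale factor recorded in the JSON.
#' @return invisibly, the two paths.
#' @export
write_spaceranger <- function(grid, dir, tissue_hires_scalef = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pos <- file.path(dir, "tissue_positions_list.csv")
  df <- data.frame(grid$barcode, grid$in_tissue, grid$array_row,
                   grid$array_col, grid$y, grid$x)
  utils::write.table(df, pos, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sf <- file.path(dir, "scalefactors_json.json")
  jsonlite::write_json(
    list(spot_diameter_fullres = unname(grid$radius[1] * 2),
         tissue_hires_scalef = tissue_hires_scalef),
    sf, auto_unbox = TRUE, digits = NA)
  invisible(c(positions = pos, scalefactors = sf))
}

#' Read a `scalefactors_json.json`
#'
#' @param path JSON path.
#' @return list with at least `spot_diameter_fullres` and
#'   `tissue_hires_scalef`.
#' @export
read_scalefactors <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read / write a 10x-style MTX triplet
#'
#' `matrix.mtx` (genes x spots), `features.tsv`, `barcodes.tsv` in a
#' directory.
#'
#' @param dir directory holding (or to receive) the triplet.
#' @return `read_mtx` returns a sparse `dgCMatrix` with gene rownames and
#'   barcode colnames.
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  methods::as(m, "CsparseMatrix")
}

#' @rdname read_mtx
#' @param counts gene x spot matrix to write.
#' @export
write_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "sparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write / read a cell feature table in the QuPath detection-export dialect
#'
#' Centroids are written in micrometres under the headers
#' `Centroid X µm` / `Centroid Y µm`, the class under `Class`; all other
#' feature columns are carried through. Reading converts the centroids
#' back to pixels with the supplied pixel size, so externally annotated
#' detection exports can enter the pipeline.
#'
#' @param table a [compute_features()] table (optionally with a `class`
#'   column).
#' @param path TSV path.
#' @param pixel_size micrometres per pixel; defaults to the table's
#'   attribute on write and must be given on read.
#' @return `read_cell_table` returns a `cell_feature_table`.
#' @export
write_cell_table <- function(table, path, pixel_size = NULL) {
  psz <- pixel_size %||% attr(table, "pixel_size") %||% 1
  out <- as.data.frame(table)
  out[["Centroid X µm"]] <- out$x * psz
  out[["Centroid Y µm"]] <- out$y * psz
  out$x <- NULL; out$y <- NULL
  if (!is.null(out$class)) {
    out$Class <- out$class
    out$class <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, pixel_size) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  xc <- grep("^Centroid X", names(df), value = TRUE)[1]
  yc <- grep("^Centroid Y", names(df), value = TRUE)[1]
  if (is.na(xc) || is.na(yc))
    stop("not a detection export: centroid columns missing")
  df$x <- df[[xc]] / pixel_size
  df$y <- df[[yc]] / pixel_size
  df[[xc]] <- NULL; df[[yc]] <- NULL
  if (!is.null(df$Class)) {
    df$class <- df$Class
    df$Class <- NULL
  }
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("cell_feature_table", "data.frame")
  df
}

#' Write / read a per-spot composition CSV
#'
#' The pipeline's central exchange file: barcode, per-class counts,
#' total, per-class fractions.
#'
#' @param comp a [compose_spots()] composition.
#' @param path CSV path.
#' @return `read_spot_composition` returns a `spot_composition`.
#' @export
write_spot_composition <- function(comp, path) {
  utils::write.csv(as.data.frame(comp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_composition
#' @export
read_spot_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  classes <- sub("^n_", "", grep("^n_(?!total)", names(df), value = TRUE,
                                 perl = TRUE))
  attr(df, "classes") <- classes
  class(df) <- c("spot_composition", "data.frame")
  df
}

#' Read a gene order TSV (`gene`, `chr`, `start`, `stop`)
#'
#' @param path TSV path.
#' @return data.frame sorted by (chromosome order, start, gene).
#' @export
read_gene_order <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chr", "start", "stop") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("gene names must be unique")
  ord <- .default_chrom_order(unique(df$chr))
  df[order(match(df$chr, ord), df$start, df$gene), , drop = FALSE]
}
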