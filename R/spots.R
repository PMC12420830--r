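#' Assign cells to Visium spots by square-window containment
#'
#' A cell belongs to a spot when its centroid falls in the square window
#' centred on the spot: `|x_cell - x_spot| <= r` and
#' `|y_cell - y_spot| <= r` (closed inequalities, so boundary cells are
#' included). With standard Visium geometry (radius below half the pitch)
#' the windows are disjoint; should several windows contain a cell, it goes
#' to the spot with the nearest center (Euclidean), ties broken by barcode
#' order. Cells in no window are reported as unassigned, not dropped.
#'
#' @param cells a data.frame with `id`, `x`, `y` (full-resolution pixels),
#'   e.g. a [compute_features()] table.
#' @param grid a `spot_grid` in the same full-resolution frame, with
#'   `barcode`, `x`, `y`, `radius`.
#' @return data.frame `id`, `barcode` (`NA` when unassigned).
#' @export
assign_cells_to_spots <- function(cells, grid) {
  fc <- attr(cells, "frame"); fg <- attr(grid, "frame")
  if (!is.null(fc) && !is.null(fg) && fc != fg)
    stop("cells and grid are in different coordinate frames: ", fc, " vs ", fg)
  n <- nrow(cells)
  best_bc <- rep(NA_character_, n)
  best_d2 <- rep(Inf, n)
  ord <- order(grid$barcode)
  for (j in ord) {
    r <- grid$radius[j]
    dx <- cells$x - grid$x[j]
    dy <- cells$y - grid$y[j]
    inside <- abs(dx) <= r & abs(dy) <= r
    if (!any(inside)) next
    d2 <- dx[inside]^2 + dy[inside]^2
    take <- d2 < best_d2[inside]   # strict: earlier barcode wins ties
    idx <- which(inside)[take]
    best_d2[idx] <- d2[take]
    best_bc[idx] <- grid$barcode[j]
  }
  data.frame(id = cells$id, barcode = best_bc, stringsAsFactors = FALSE)
}

#' Per-spot tumor/immune/stroma composition
#'
#' Counts the cells of each class assigned to every spot and derives the
#' class fractions (count over total). Spots with no assigned cells keep a
#' row with zero counts and missing fractions.
#'
#' @param assignment an [assign_cells_to_spots()] result.
#' @param labels cell class labels, parallel to `assignment` rows (or a
#'   named vector indexed by cell id).
#' @param barcodes the full spot set to report; defaults to the barcodes
#'   that received at least one cell.
#' @param classes the class set (default tumor / immune / stroma).
#' @return A `spot_composition` data.frame: `barcode`, `n_<class>` counts,
#'   `n_total`, `frac_<class>` fractions.
#' @export
compose_spots <- function(assignment, labels,
                          barcodes = NULL,
                          classes = c("tumor", "immune", "stroma")) {
  if (!is.null(names(labels)))
    labels <- unname(labels[as.character(assignment$id)])
  labels <- as.character(labels)
  if (length(labels) != nrow(assignment))
    stop("labels must be parallel to the assignment")
  assigned <- !is.na(assignment$barcode)
  if (anyNA(labels[assigned]))
    stop("assigned cell(s) without a class label")
  extra <- setdiff(unique(labels[assigned]), classes)
  if (length(extra))
    stop("label(s) outside the class set: ", paste(extra, collapse = ", "))
  if (is.null(barcodes)) barcodes <- sort(unique(assignment$barcode[assigned]))
  bc <- factor(assignment$barcode[assigned], levels = barcodes)
  lb <- factor(labels[assigned], levels = classes)
  cm <- table(bc, lb)
  out <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("n_", cl)]] <- as.integer(cm[, cl])
  out$n_total <- as.integer(rowSums(cm))
  for (cl in classes) {
    fr <- out[[paste0("n_", cl)]] / out$n_total
    fr[out$n_total == 0] <- NA_real_
    out[[paste0("frac_", cl)]] <- fr
  }
  attr(out, "classes") <- classes
  class(out) <- c("spot_composition", "data.frame")
  out
}

#' Spot quality-control thresholds
#'
#' Defaults follow common Visium practice: spots with fewer than 500
#' detected genes, more than 25 percent mitochondrial UMIs, or more than 20
#' percent hemoglobin UMIs are removed (strict comparisons, so a spot at
#' exactly a threshold is kept).
#'
#' @param min_genes minimum detected (nonzero) genes.
#' @param max_mito,max_hemo maximum mitochondrial / hemoglobin UMI fraction.
#' @param mito_pattern,hemo_pattern regular expressions matched against gene
#'   names.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500, max_mito = 0.25, max_hemo = 0.20,
                          mito_pattern = "^MT-", hemo_pattern = "^HB[AB]") {
  if (max_mito < 0 || max_mito > 1 || max_hemo < 0 || max_hemo > 1)
    stop("fraction thresholds must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_mito = max_mito,
                 max_hemo = max_hemo, mito_pattern = mito_pattern,
                 hemo_pattern = hemo_pattern),
            class = "qc_thresholds")
}

#' Filter spots on detected genes and mitochondrial / hemoglobin content
#'
#' @param counts gene x spot count matrix (rownames = gene names, colnames =
#'   barcodes); dense or `Matrix` sparse.
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (barcodes passing) and `report` (per-spot
#'   data.frame: barcode, detected genes, total UMIs, mito and hemoglobin
#'   fractions, pass flag, semicolon-separated removal reasons).
#' @export
qc_filter_spots <- function(counts, thresholds = qc_thresholds()) {
  thr <- thresholds
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and barcode colnames")
  if (anyDuplicated(colnames(counts))) stop("barcodes must be unique")
  genes <- rownames(counts)
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[grepl(thr$mito_pattern, genes), ,
                                 drop = FALSE]) / total
  hemo <- Matrix::colSums(counts[grepl(thr$hemo_pattern, genes), ,
                                 drop = FALSE]) / total
  reasons <- character(ncol(counts))
  add <- function(reasons, flag, msg)
    ifelse(flag, ifelse(reasons == "", msg, paste(reasons, msg, sep = ";")),
           reasons)
  no_counts <- total == 0
  reasons <- add(reasons, no_counts, "no counts")
  reasons <- add(reasons, !no_counts & detected < thr$min_genes,
                 sprintf("fewer than %d detected genes", thr$min_genes))
  reasons <- add(reasons, !no_counts & mito > thr$max_mito,
                 sprintf("mitochondrial fraction above %g", thr$max_mito))
  reasons <- add(reasons, !no_counts & hemo > thr$max_hemo,
                 sprintf("hemoglobin fraction above %g", thr$max_hemo))
  pass <- reasons == ""
  report <- data.frame(barcode = colnames(counts),
                       detected_genes = as.integer(detected),
                       total_umis = as.numeric(total),
                       mito_fraction = as.numeric(mito),
                       hemo_fraction = as.numeric(hemo),
                       pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE)
  list(kept = colnames(counts)[pass], report = report)
}

#' Cells per spot within spot groups
#'
#' The spot density of a group (e.g. a gene-expression cluster) is the total
#' number of annotated cells over the group's spots divided by the number of
#' spots in the group.
#'
#' @param comp a [compose_spots()] composition.
#' @param cluster_labels named vector (names = barcodes) or data.frame
#'   (`barcode`, `label`) giving each spot's group.
#' @return named numeric vector of cells/spot per group (`NA` for a group
#'   with no member spots).
#' @export
spot_density <- function(comp, cluster_labels) {
  lab <- .as_label_vector(cluster_labels)
  missing_bc <- setdiff(names(lab), comp$barcode)
  if (length(missing_bc))
    stop("labelled spot(s) absent from the composition: ",
         paste(utils::head(missing_bc, 5), collapse = ", "))
  tot <- comp$n_total[match(names(lab), comp$barcode)]
  groups <- sort(unique(unname(lab)))
  out <- vapply(groups, function(g) {
    sel <- lab == g
    if (!any(sel)) return(NA_real_)
    sum(tot[sel]) / sum(sel)
  }, numeric(1))
  names(out) <- groups
  out
}

.as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("barcode", "label") %in% names(labels)))
    stats::setNames(as.character(labels$label), labels$barcode)
  } else {
    if (is.null(names(labels))) stop("labels must be named by barcode")
    stats::setNames(as.character(labels), names(labels))
  }
}
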