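#' Inclusion rules for intrinsic-subtype calling
#'
#' Spots entering molecular subtype prediction must pass quality control,
#' contain a minimum epithelial content according to deconvolution
#' (cancer plus normal epithelial fine fractions), and carry at least one
#' annotated tumor cell.
#'
#' @param min_epithelial minimum epithelial fraction (default 0.20).
#' @param min_tumor_cells minimum annotated tumor cells (default 1).
#' @param require_qc whether QC passing is required (default `TRUE`).
#' @return list of class `subtype_inclusion`.
#' @export
subtype_inclusion <- function(min_epithelial = 0.20, min_tumor_cells = 1,
                              require_qc = TRUE) {
  if (min_epithelial < 0 || min_epithelial > 1)
    stop("min_epithelial must lie in [0, 1]")
  if (min_tumor_cells < 0) stop("min_tumor_cells must be >= 0")
  structure(list(min_epithelial = min_epithelial,
                 min_tumor_cells = min_tumor_cells,
                 require_qc = isTRUE(require_qc)),
            class = "subtype_inclusion")
}

#' Filter spots eligible for subtype prediction
#'
#' @param comp a [compose_spots()] composition.
#' @param epithelial_fraction named numeric vector (barcode -> epithelial
#'   fraction from a deconvolution output).
#' @param qc_pass barcodes passing quality control.
#' @param rules a [subtype_inclusion()].
#' @return list with `eligible` (barcodes) and `report` (barcode, eligible
#'   flag, semicolon-separated exclusion reasons).
#' @export
filter_spots_for_subtyping <- function(comp, epithelial_fraction, qc_pass,
                                       rules = subtype_inclusion()) {
  bc <- comp$barcode
  epi <- unname(epithelial_fraction[bc])
  tum <- comp$n_tumor
  reasons <- character(length(bc))
  add <- function(reasons, flag, msg)
    ifelse(flag, ifelse(reasons == "", msg, paste(reasons, msg, sep = ";")),
           reasons)
  reasons <- add(reasons, is.na(epi), "no deconvolution output")
  reasons <- add(reasons, !is.na(epi) & epi < rules$min_epithelial,
                 sprintf("epithelial fraction below %g", rules$min_epithelial))
  reasons <- add(reasons, tum < rules$min_tumor_cells,
                 sprintf("fewer than %d annotated tumor cell(s)",
                         rules$min_tumor_cells))
  if (rules$require_qc)
    reasons <- add(reasons, !bc %in% qc_pass, "failed quality control")
  eligible <- reasons == ""
  list(eligible = bc[eligible],
       report = data.frame(barcode = bc, eligible = eligible,
                           reasons = reasons, stringsAsFactors = FALSE))
}

#' Pooled composition of spot groups
#'
#' For each spot group (gene-expression cluster, subtype, clone, ...),
#' pools the annotated cell counts over member spots and reports class
#' percentages (`sum of class counts / sum of totals`), the spot count and
#' the spot density (cells per spot). Pooling over counts -- not averaging
#' per-spot fractions -- is the default; `pooled = FALSE` switches to the
#' mean of member-spot fractions.
#'
#' @param comp a [compose_spots()] composition.
#' @param labels spot group labels (named vector or `barcode`/`label`
#'   data.frame).
#' @param pooled pool counts (default) or average per-spot fractions.
#' @return data.frame: `group`, `n_spots`, `density`, `pct_<class>`
#'   (percentages; `NA` when the group has no annotated cells).
#' @export
summarize_composition_by_group <- function(comp, labels, pooled = TRUE) {
  lab <- .as_label_vector(labels)
  miss <- setdiff(names(lab), comp$barcode)
  if (length(miss))
    stop("labelled spot(s) absent from the composition: ",
         paste(utils::head(miss, 5), collapse = ", "))
  classes <- attr(comp, "classes") %||% c("tumor", "immune", "stroma")
  idx <- match(names(lab), comp$barcode)
  groups <- sort(unique(unname(lab)))
  rows <- lapply(groups, function(g) {
    gi <- idx[lab == g]
    tot <- sum(comp$n_total[gi])
    out <- data.frame(group = g, n_spots = length(gi),
                      density = tot / length(gi), stringsAsFactors = FALSE)
    for (cl in classes) {
      pct <- if (pooled) {
        if (tot == 0) NA_real_ else
          100 * sum(comp[[paste0("n_", cl)]][gi]) / tot
      } else {
        fr <- comp[[paste0("frac_", cl)]][gi]
        if (all(is.na(fr))) NA_real_ else 100 * mean(fr, na.rm = TRUE)
      }
      out[[paste0("pct_", cl)]] <- pct
    }
    out
  })
  do.call(rbind, rows)
}

#' Pseudo-bulk aggregation of a count matrix over spot groups
#'
#' Gene-wise raw-count sums per group, counts-per-million normalization
#' (columns scaled to 1e6), and a `log2(x + 1)` transform.
#'
#' @param counts gene x spot count matrix.
#' @param labels spot group labels (named vector or data.frame); only
#'   labelled spots are aggregated.
#' @return `pseudobulk_matrix`: list with `raw`, `cpm`, `log` (gene x group
#'   matrices) and `flagged` (groups whose column is all zero, for which
#'   CPM is undefined and left `NA`).
#' @export
pseudobulk <- function(counts, labels) {
  lab <- .as_label_vector(labels)
  miss <- setdiff(names(lab), colnames(counts))
  if (length(miss))
    stop("labelled spot(s) absent from the count matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  groups <- sort(unique(unname(lab)))
  raw <- vapply(groups, function(g) {
    as.numeric(Matrix::rowSums(counts[, names(lab)[lab == g], drop = FALSE]))
  }, numeric(nrow(counts)))
  raw <- matrix(raw, nrow = nrow(counts),
                dimnames = list(rownames(counts), groups))
  tot <- colSums(raw)
  flagged <- groups[tot == 0]
  cpm <- sweep(raw, 2, ifelse(tot == 0, NA, tot), "/") * 1e6
  lg <- log2(cpm + 1)
  structure(list(raw = raw, cpm = cpm, log = lg, flagged = flagged),
            class = "pseudobulk_matrix")
}

#' Per-spot report for selected spots
#'
#' For each requested spot (for instance the spots carrying a B- or T-cell
#' clone), reports the annotated class counts and fractions, the majority
#' annotated class, and the spot's full fine-type deconvolution fractions.
#'
#' @param spot_ids barcodes to report; unknown barcodes are an error.
#' @param comp a [compose_spots()] composition.
#' @param fine spots x fine-type deconvolution matrix (optional).
#' @return data.frame, one row per requested spot: composition columns,
#'   `majority_class`, and `fine.<type>` fraction columns when `fine` is
#'   given.
#' @export
clone_spot_report <- function(spot_ids, comp, fine = NULL) {
  unknown <- setdiff(spot_ids, comp$barcode)
  if (length(unknown))
    stop("unknown spot id(s): ", paste(unknown, collapse = ", "))
  classes <- attr(comp, "classes") %||% c("tumor", "immune", "stroma")
  idx <- match(spot_ids, comp$barcode)
  out <- comp[idx, , drop = FALSE]
  cnts <- as.matrix(out[, paste0("n_", classes), drop = FALSE])
  maj <- apply(cnts, 1, function(v) {
    if (sum(v) == 0) return(NA_character_)
    cand <- classes[v == max(v)]
    sort(cand)[1]
  })
  out$majority_class <- maj
  if (!is.null(fine)) {
    fmiss <- setdiff(spot_ids, rownames(fine))
    if (length(fmiss))
      stop("spot id(s) absent from the deconvolution matrix: ",
           paste(fmiss, collapse = ", "))
    f <- fine[spot_ids, , drop = FALSE]
    colnames(f) <- paste0("fine.", colnames(f))
    out <- cbind(out, as.data.frame(f))
  }
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Subsample transcript point sets to match cell-level annotation density
#'
#' On image-based in situ platforms, marker transcripts far outnumber
#' cells; plotting a fixed fraction of each marker's points (for example
#' 15, 50 and 100 percent for a tumor, immune and stroma marker) makes the
#' transcript display visually comparable to the per-cell annotation.
#' Sampling is uniform without replacement and deterministic under the
#' seed; points are returned in their original order.
#'
#' @param points named list of per-marker data.frames (any columns; rows
#'   are transcript points).
#' @param fractions named numeric vector in `(0, 1]`, aligned with
#'   `points` by name.
#' @param seed random seed.
#' @return named list of subsampled data.frames, `round(fraction * n)`
#'   rows each.
#' @export
transcript_match_subsample <- function(points, fractions, seed = 1) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.null(names(points)) || !all(names(points) %in% names(fractions)))
    stop("points and fractions must be named consistently")
  set.seed(seed)
  out <- lapply(names(points), function(mk) {
    df <- points[[mk]]
    n <- nrow(df)
    if (n == 0) {
      warning("marker ", mk, ": empty point set")
      return(df)
    }
    take <- round(fractions[[mk]] * n)
    if (take >= n) return(df)
    df[sort(sample.int(n, take)), , drop = FALSE]
  })
  names(out) <- names(points)
  out
}
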