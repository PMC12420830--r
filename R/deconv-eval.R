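#' Aggregate fine deconvolution fractions to tumor / immune / stroma
#'
#' Sums each spot's fine-type fractions within the three major classes.
#' Row sums are preserved exactly (the map is a partition of the fine
#' types).
#'
#' @param fine spots x fine-type fraction matrix (rownames = barcodes).
#' @param map named character vector fine type -> major class.
#' @return spots x major-class matrix, metadata attributes carried over.
#' @export
aggregate_fractions <- function(fine, map) {
  unmapped <- setdiff(colnames(fine), names(map))
  if (length(unmapped))
    stop("fine type(s) missing from the aggregation map: ",
         paste(unmapped, collapse = ", "))
  classes <- sort(unique(unname(map)))
  out <- vapply(classes, function(cl) {
    members <- intersect(colnames(fine), names(map)[map == cl])
    if (!length(members)) return(rep(0, nrow(fine)))
    rowSums(fine[, members, drop = FALSE])
  }, numeric(nrow(fine)))
  out <- matrix(out, nrow = nrow(fine),
                dimnames = list(rownames(fine), classes))
  attr(out, "method") <- attr(fine, "method")
  attr(out, "sample_id") <- attr(fine, "sample_id")
  out
}

#' Spearman correlation between deconvolved and annotation-derived fractions
#'
#' For each sample/section and each major class, computes Spearman's rank
#' correlation (average-rank tie handling) between the deconvolved class
#' fraction and the image-annotation class fraction, over the spots shared
#' by both sources that have at least one annotated cell. Records with too
#' few spots are emitted with a missing coefficient and a note.
#'
#' @param major spots x major-class matrix (from [aggregate_fractions()]).
#' @param comp a [compose_spots()] composition (the annotation truth).
#' @param classes classes to score (default the composition's class set).
#' @param keep_barcodes optional barcodes allowed in (e.g. QC-passing spots).
#' @param min_spots minimum spots for a valid coefficient (default 3).
#' @param method,sample_id metadata; default to the matrix attributes.
#' @return data.frame of correlation records: `sample`, `method`, `class`,
#'   `rho`, `n`, `note`.
#' @export
correlate_composition <- function(major, comp, classes = NULL,
                                  keep_barcodes = NULL, min_spots = 3,
                                  method = NULL, sample_id = NULL) {
  classes <- classes %||% attr(comp, "classes") %||%
    c("tumor", "immune", "stroma")
  method <- method %||% attr(major, "method") %||% "unknown"
  sample_id <- sample_id %||% attr(major, "sample_id") %||% "S1"
  shared <- intersect(rownames(major), comp$barcode[comp$n_total > 0])
  if (!is.null(keep_barcodes)) shared <- intersect(shared, keep_barcodes)
  recs <- lapply(classes, function(cl) {
    if (!length(shared))
      return(data.frame(sample = sample_id, method = method, class = cl,
                        rho = NA_real_, n = 0L, note = "no overlap",
                        stringsAsFactors = FALSE))
    a <- major[shared, cl]
    b <- comp[[paste0("frac_", cl)]][match(shared, comp$barcode)]
    n <- length(shared)
    if (n < min_spots)
      return(data.frame(sample = sample_id, method = method, class = cl,
                        rho = NA_real_, n = n, note = "too few spots",
                        stringsAsFactors = FALSE))
    rho <- stats::cor(a, b, method = "spearman")
    data.frame(sample = sample_id, method = method, class = cl, rho = rho,
               n = n, note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Dunn's post hoc test against a reference group
#'
#' Rank-based multiple-comparison z statistics after a Kruskal-Wallis
#' omnibus, with the usual tie correction; two-sided p-values from the
#' normal approximation.
#'
#' @param values numeric outcomes.
#' @param groups group membership, same length.
#' @param reference the reference group each other group is compared to.
#' @return data.frame `group`, `z`, `p` (one row per non-reference group).
#' @export
dunn_test <- function(values, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group absent from the data")
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  N <- length(values)
  r <- rank(values)  # average ranks for ties
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  others <- setdiff(names(rbar), reference)
  z <- vapply(others, function(g) {
    (rbar[[g]] - rbar[[reference]]) /
      sqrt(v0 * (1 / ns[[g]] + 1 / ns[[reference]]))
  }, numeric(1))
  data.frame(group = others, z = as.numeric(z),
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Compare deconvolution methods from their correlation records
#'
#' Per major class: a Kruskal-Wallis omnibus over the per-sample Spearman
#' coefficients grouped by method, followed by Dunn's test of every method
#' against the reference method, Benjamini-Hochberg adjustment across those
#' pairwise comparisons (one family per class), and significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001 on the adjusted values).
#'
#' @param records a [correlate_composition()] record table (rows with
#'   missing `rho` are ignored); methods with fewer than 2 records in a
#'   class are excluded from that class with a warning.
#' @param reference_method the method the others are compared against.
#' @param alpha significance level used in the printed summary.
#' @return list of class `method_comparison`: `omnibus` (class, H, df, p)
#'   and `pairwise` (class, method, z, p, p_adj, stars).
#' @export
compare_methods <- function(records, reference_method, alpha = 0.05) {
  records <- records[is.finite(records$rho), , drop = FALSE]
  if (!reference_method %in% records$method)
    stop("reference method has no usable records")
  omni <- list(); pw <- list()
  for (cl in unique(records$class)) {
    sub <- records[records$class == cl, , drop = FALSE]
    cnt <- table(sub$method)
    small <- names(cnt)[cnt < 2]
    if (length(small)) {
      warning("class ", cl, ": method(s) with fewer than 2 records excluded: ",
              paste(small, collapse = ", "))
      sub <- sub[!sub$method %in% small, , drop = FALSE]
    }
    if (length(unique(sub$method)) < 2 ||
        !reference_method %in% sub$method) next
    kw <- stats::kruskal.test(sub$rho, factor(sub$method))
    omni[[cl]] <- data.frame(class = cl,
                             H = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p = kw$p.value, stringsAsFactors = FALSE)
    dn <- dunn_test(sub$rho, sub$method, reference_method)
    dn$p_adj <- stats::p.adjust(dn$p, method = "BH")
    dn$stars <- ifelse(dn$p_adj < 0.001, "***",
                       ifelse(dn$p_adj < 0.01, "**",
                              ifelse(dn$p_adj < 0.05, "*", "")))
    pw[[cl]] <- cbind(class = cl, method = dn$group,
                      dn[, c("z", "p", "p_adj", "stars")])
  }
  structure(list(omnibus = do.call(rbind, omni),
                 pairwise = do.call(rbind, pw),
                 reference = reference_method, alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Deconvolution method comparison (reference:", x$reference, ")\n")
  cat("Kruskal-Wallis omnibus:\n")
  print(x$omnibus, row.names = FALSE)
  cat("Dunn vs reference (BH-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
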