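#' Select CNV reference spots from the annotation composition
#'
#' Reference (normal-baseline) spots are QC-passing spots with no annotated
#' tumor cell and at least one annotated cell of any class.
#'
#' @param comp a [compose_spots()] composition.
#' @param qc_pass optional barcodes passing quality control; `NULL` accepts
#'   all.
#' @return character vector of reference barcodes.
#' @export
select_reference_spots <- function(comp, qc_pass = NULL) {
  sel <- comp$n_tumor == 0 & comp$n_total >= 1
  if (!is.null(qc_pass)) sel <- sel & comp$barcode %in% qc_pass
  bc <- comp$barcode[sel]
  if (!length(bc))
    stop("no reference spots: every annotated spot contains tumor cells")
  bc
}

#' Select high-purity tumor spots
#'
#' Keeps QC-passing spots whose annotated tumor fraction is at least `tau`
#' (inclusive boundary). Stricter thresholds give nested subsets.
#'
#' @param comp a [compose_spots()] composition.
#' @param tau tumor-purity threshold in (0, 1]; conventional values are
#'   0.5, 0.7 and 0.9.
#' @param qc_pass optional QC-passing barcodes.
#' @return character vector of query barcodes.
#' @export
select_tumor_spots <- function(comp, tau, qc_pass = NULL) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  frac <- comp$frac_tumor
  sel <- comp$n_total > 0 & !is.na(frac) & frac >= tau
  if (!is.null(qc_pass)) sel <- sel & comp$barcode %in% qc_pass
  bc <- comp$barcode[sel]
  if (!length(bc))
    stop(sprintf("no tumor spots at purity threshold %.2f", tau))
  bc
}

#' CNV profiling parameters
#'
#' @param expr_floor minimum mean raw count (over reference and query) for
#'   a gene to enter the profile.
#' @param clip_max symmetric clip applied to centred log expression.
#' @param window running-mean window in genes (odd; truncated at chromosome
#'   ends).
#' @param denoise_sd profile values within this many reference standard
#'   deviations of zero are set to zero.
#' @param target_depth common depth each spot is normalized to; default the
#'   median spot total.
#' @param chrom_order chromosome order; default `chr1..chr22, chrX, chrY`
#'   (also accepts unprefixed names present in the gene order).
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(expr_floor = 0.1, clip_max = 3, window = 101,
                       denoise_sd = 1.3, target_depth = NULL,
                       chrom_order = NULL) {
  structure(list(expr_floor = expr_floor, clip_max = clip_max,
                 window = as.integer(window), denoise_sd = denoise_sd,
                 target_depth = target_depth, chrom_order = chrom_order),
            class = "cnv_params")
}

.default_chrom_order <- function(chroms) {
  canonical <- c(paste0("chr", c(1:22, "X", "Y")), c(1:22, "X", "Y"))
  known <- canonical[canonical %in% chroms]
  c(known, sort(setdiff(chroms, known)))
}

#' Genomically smoothed relative-expression CNV profile
#'
#' A simplified relative-expression profiler in the style of the
#' moving-average inferCNV family. Steps, in order: (1) library-size
#' normalize every spot to a common depth and take `log2(x + 1)`;
#' (2) drop genes below a mean-expression floor; (3) subtract the per-gene
#' reference mean; (4) clip to `+/- clip_max`; (5) running mean over a
#' `window`-gene window within each chromosome (truncated at the ends);
#' (6) centre each spot at its median; (7) denoise by zeroing values within
#' `denoise_sd` reference standard deviations of zero. The HMM, subcluster
#' and Bayesian-filtering machinery of the full method is deliberately not
#' reproduced; this profile is intended for clone clustering.
#'
#' @param counts gene x spot count matrix.
#' @param reference,query disjoint barcode sets; reference spots define the
#'   normal baseline.
#' @param gene_order gene order table (`gene`, `chr`, `start`, `stop`);
#'   genes are intersected with the matrix rows and sorted by (chromosome
#'   order, start, gene name).
#' @param params a [cnv_params()].
#' @return `cnv_profile`: list with `profile` (spots x genes, reference
#'   rows first), `genes` (ordered gene table), `role` (named vector
#'   barcode -> reference/query), `sd_ref`, `params`.
#' @export
infer_cnv_profile <- function(counts, reference, query, gene_order,
                              params = cnv_params()) {
  p <- params
  if (length(intersect(reference, query)))
    stop("reference and query spots must be disjoint")
  miss <- setdiff(c(reference, query), colnames(counts))
  if (length(miss))
    stop("spot(s) absent from the count matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ord <- gene_order[gene_order$gene %in% rownames(counts), , drop = FALSE]
  chrord <- p$chrom_order %||% .default_chrom_order(unique(ord$chr))
  ord <- ord[order(match(ord$chr, chrord), ord$start, ord$gene), ,
             drop = FALSE]
  # drop chromosomes that cannot support smoothing
  n_by_chr <- table(ord$chr)
  bad <- names(n_by_chr)[n_by_chr < 2]
  if (length(bad)) {
    warning("chromosome(s) with fewer than 2 genes skipped: ",
            paste(bad, collapse = ", "))
    ord <- ord[!ord$chr %in% bad, , drop = FALSE]
  }
  spots <- c(reference, query)
  m <- as.matrix(counts[ord$gene, spots, drop = FALSE])
  # (2) expression floor on raw means, before normalization
  keep <- rowMeans(m) >= p$expr_floor
  ord <- ord[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) stop("no genes left above the expression floor")
  # (1) common-depth normalization, log2
  depth <- p$target_depth %||% stats::median(colSums(m))
  tot <- colSums(m)
  tot[tot == 0] <- 1
  m <- sweep(m, 2, depth / tot, "*")
  m <- log2(m + 1)
  # (3) subtract per-gene reference mean
  refmean <- rowMeans(m[, reference, drop = FALSE])
  m <- m - refmean
  # (4) clip
  m[m > p$clip_max] <- p$clip_max
  m[m < -p$clip_max] <- -p$clip_max
  # (5) running mean within chromosome, truncated at the ends
  half <- (p$window - 1L) %/% 2L
  sm <- m
  for (ch in unique(ord$chr)) {
    idx <- which(ord$chr == ch)
    n <- length(idx)
    cs <- rbind(0, apply(m[idx, , drop = FALSE], 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  prof <- t(sm)  # spots x genes
  # (6) centre each spot at its median
  prof <- prof - apply(prof, 1, stats::median)
  # (7) denoise against the reference spread
  sd_ref <- stats::sd(prof[reference, , drop = FALSE])
  prof[abs(prof) <= p$denoise_sd * sd_ref] <- 0
  role <- stats::setNames(c(rep("reference", length(reference)),
                            rep("query", length(query))), spots)
  structure(list(profile = prof, genes = ord, role = role,
                 sd_ref = sd_ref, params = p),
            class = "cnv_profile")
}

#' Cluster query spots into copy-number clones
#'
#' Scales the profile per gene (z-score across spots, optional), clusters
#' the query spots by agglomerative Ward linkage on Euclidean distances,
#' and cuts the dendrogram either into `k` clusters or at height `h`.
#' Clones are relabelled `A`, `B`, ... by decreasing size.
#'
#' @param profile a [infer_cnv_profile()] result.
#' @param k number of clones; exactly one of `k` and `h` must be given.
#' @param h dendrogram cut height; a height above the root yields a single
#'   clone with a warning.
#' @param scale_genes z-score each gene across query spots before
#'   clustering (default `TRUE`).
#' @param method `"ward.D"` (classical Ward on the supplied Euclidean
#'   distances, as commonly used with this profile type) or `"ward.D2"`.
#' @return `clone_assignment`: data.frame `barcode`, `clone`, with the
#'   `hclust` tree, cut parameters and linkage recorded as attributes.
#' @export
call_clones <- function(profile, k = NULL, h = NULL, scale_genes = TRUE,
                        method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "cnv_profile"))
  if (is.null(k) == is.null(h))
    stop("give exactly one of k (cluster count) or h (cut height)")
  qbc <- names(profile$role)[profile$role == "query"]
  if (length(qbc) < 2) stop("clone calling needs at least 2 query spots")
  x <- profile$profile[qbc, , drop = FALSE]
  if (scale_genes) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    x <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  }
  hc <- stats::hclust(stats::dist(x), method = method)
  if (!is.null(h) && h > max(hc$height)) {
    warning("cut height above the dendrogram root; returning a single clone")
    cl <- rep(1L, length(qbc))
  } else {
    cl <- stats::cutree(hc, k = k, h = h)
  }
  # relabel by decreasing size, ties by first occurrence
  sizes <- table(cl)
  ord <- order(-as.numeric(sizes), match(names(sizes), unique(as.character(cl))))
  relab <- stats::setNames(LETTERS[seq_along(ord)], names(sizes)[ord])
  out <- data.frame(barcode = qbc, clone = unname(relab[as.character(cl)]),
                    stringsAsFactors = FALSE)
  attr(out, "hclust") <- hc
  attr(out, "cut") <- list(k = k, h = h)
  attr(out, "method") <- method
  class(out) <- c("clone_assignment", "data.frame")
  out
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxind <- (sum_a + sum_b) / 2
  if (maxind == expected) return(1)
  (sum_ij - expected) / (maxind - expected)
}
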