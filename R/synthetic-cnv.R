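#' Synthetic gene order table
#'
#' A genomic gene-order table (gene, chromosome, start, stop) for CNV
#' simulations: `genes_per_chr` genes evenly spaced on each chromosome,
#' sorted by (chromosome order, start).
#'
#' @param n_chr number of chromosomes (named `chr1`, `chr2`, ...).
#' @param genes_per_chr genes per chromosome (scalar or vector).
#' @param gene_width,gap gene span and intergenic gap in bases.
#' @return data.frame `gene`, `chr`, `start`, `stop`.
#' @export
make_gene_order <- function(n_chr = 6, genes_per_chr = 250,
                            gene_width = 2e4, gap = 8e4) {
  genes_per_chr <- rep_len(genes_per_chr, n_chr)
  res <- lapply(seq_len(n_chr), function(ci) {
    n <- genes_per_chr[ci]
    start <- (seq_len(n) - 1) * (gene_width + gap) + 1
    data.frame(gene = sprintf("chr%d_g%04d", ci, seq_len(n)),
               chr = paste0("chr", ci), start = start,
               stop = start + gene_width - 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Specify a copy-number clone
#'
#' @param id clone identifier.
#' @param segments data.frame with columns `chr`, `start_index`,
#'   `end_index` (1-based gene indices within the chromosome, inclusive)
#'   and `log2fc` (finite log2 fold-change of the segment).
#' @param spots barcodes carrying the clone.
#' @return list of class `clone_spec`.
#' @export
clone_spec <- function(id, segments, spots) {
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(chr = character(0), start_index = integer(0),
                           end_index = integer(0), log2fc = numeric(0))
  }
  stopifnot(all(c("chr", "start_index", "end_index", "log2fc") %in%
                  names(segments)))
  if (any(!is.finite(segments$log2fc)))
    stop("segment fold-changes must be finite")
  if (any(segments$start_index < 1 | segments$end_index < segments$start_index))
    stop("segment indices must satisfy 1 <= start <= end")
  structure(list(id = id, segments = segments, spots = as.character(spots)),
            class = "clone_spec")
}

#' Simulate clone-structured spot x gene counts
#'
#' Counts are Poisson (optionally negative-binomial) with per-spot mean
#' `baseline * 2^log2fc` inside a clone's altered segments, scaled so every
#' spot's expected total equals `depth`. Reference spots carry no
#' alterations.
#'
#' @param gene_order a [make_gene_order()]-style table.
#' @param clones list of [clone_spec()]s; spot sets must be disjoint.
#' @param reference_barcodes barcodes of unaltered reference spots.
#' @param baseline_expression per-gene relative expression; defaults to a
#'   seeded gamma draw so all genes are expressed at varying levels.
#' @param depth expected total UMIs per spot (default 1e4).
#' @param seed random seed.
#' @param dispersion when non-`NULL`, negative-binomial size parameter
#'   `1/dispersion` instead of Poisson.
#' @return gene x spot integer matrix (rownames = genes, colnames =
#'   barcodes) with attribute `clone_of` (named vector: barcode -> clone id
#'   or `"reference"`).
#' @export
generate_cnv_counts <- function(gene_order, clones, reference_barcodes,
                                baseline_expression = NULL, depth = 1e4,
                                seed = 1, dispersion = NULL) {
  set.seed(seed)
  genes <- gene_order$gene
  n_genes <- length(genes)
  all_clone_spots <- unlist(lapply(clones, `[[`, "spots"))
  if (anyDuplicated(all_clone_spots))
    stop("clone spot sets must be disjoint")
  if (length(intersect(all_clone_spots, reference_barcodes)))
    stop("reference spots cannot belong to a clone")
  if (is.null(baseline_expression))
    baseline_expression <- stats::rgamma(n_genes, shape = 2, rate = 2) + 0.05
  if (length(baseline_expression) != n_genes)
    stop("baseline_expression must have one value per gene")
  # per-gene multiplier for each clone
  mult <- list()
  for (cl in clones) {
    m <- rep(1, n_genes)
    if (nrow(cl$segments)) {
      for (si in seq_len(nrow(cl$segments))) {
        seg <- cl$segments[si, ]
        idx <- which(gene_order$chr == seg$chr)
        if (!length(idx))
          stop("unknown chromosome in segment: ", seg$chr)
        if (seg$end_index > length(idx))
          stop("segment extends beyond the genes of ", seg$chr)
        m[idx[seg$start_index:seg$end_index]] <-
          m[idx[seg$start_index:seg$end_index]] * 2^seg$log2fc
      }
    }
    mult[[cl$id]] <- m
  }
  barcodes <- c(reference_barcodes, all_clone_spots)
  clone_of <- c(rep("reference", length(reference_barcodes)),
                rep(vapply(clones, `[[`, character(1), "id"),
                    times = vapply(clones, function(cl) length(cl$spots),
                                   integer(1))))
  names(clone_of) <- barcodes
  counts <- matrix(0L, n_genes, length(barcodes),
                   dimnames = list(genes, barcodes))
  for (j in seq_along(barcodes)) {
    mu <- baseline_expression
    cid <- clone_of[j]
    if (cid != "reference") mu <- mu * mult[[cid]]
    mu <- mu / sum(mu) * depth
    counts[, j] <- if (is.null(dispersion)) {
      stats::rpois(n_genes, mu)
    } else {
      stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
  }
  attr(counts, "clone_of") <- clone_of
  counts
}
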