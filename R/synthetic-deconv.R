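#' The default fine-type to major-class aggregation map
#'
#' Ships as an editable TSV (`extdata/aggregation_map.tsv`): epithelial
#' fine types map to tumor; lymphoid and myeloid types to immune;
#' fibroblast, perivascular and endothelial types to stroma. The fine-type
#' vocabulary follows the minor-level cell states of the public breast
#' tumor single-cell reference commonly used for Visium deconvolution.
#'
#' @return named character vector: fine type -> major class.
#' @export
default_aggregation_map <- function() {
  path <- system.file("extdata", "aggregation_map.tsv", package = "spotCTA")
  read_aggregation_map(path)
}

#' Read an aggregation map TSV (columns `fine_type`, `major_class`)
#'
#' @param path TSV path.
#' @return named character vector: fine type -> major class.
#' @export
read_aggregation_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fine_type", "major_class") %in% names(df)))
  stats::setNames(df$major_class, df$fine_type)
}

#' Simulate fine-grained deconvolution fractions consistent with a truth
#'
#' For each spot, the true tumor/immune/stroma composition is perturbed
#' with Dirichlet noise (`alpha = concentration * truth`), then each major
#' class's share is split across its fine types with uniform Dirichlet
#' weights. Aggregating the result through the map therefore recovers the
#' true composition up to the Dirichlet noise; with
#' `concentration = Inf` the noise is switched off and the aggregation is
#' exact. Spots with no annotated cells are emitted as uniform fractions
#' and flagged.
#'
#' @param truth a [compose_spots()] composition (the ground truth).
#' @param map fine type -> major class, e.g. [default_aggregation_map()].
#' @param concentration Dirichlet concentration; larger is less noisy;
#'   `Inf` disables the noise.
#' @param seed random seed.
#' @param method,sample_id metadata recorded on the result.
#' @return matrix spots x fine types (rows sum to 1), rownames = barcodes,
#'   with attributes `method`, `sample_id`, `flagged_uniform` (barcodes of
#'   empty spots).
#' @export
generate_deconv_fractions <- function(truth, map, concentration = Inf, seed = 1,
                                      method = "synthetic", sample_id = "S1") {
  classes <- attr(truth, "classes") %||% c("tumor", "immune", "stroma")
  if (!all(classes %in% unique(map)))
    stop("every major class needs at least one fine type in the map")
  set.seed(seed)
  fine <- names(map)
  n <- nrow(truth)
  out <- matrix(0, n, length(fine), dimnames = list(truth$barcode, fine))
  flagged <- character(0)
  for (i in seq_len(n)) {
    p <- vapply(classes, function(cl) truth[[paste0("frac_", cl)]][i],
                numeric(1))
    if (truth$n_total[i] == 0 || anyNA(p)) {
      out[i, ] <- 1 / length(fine)
      flagged <- c(flagged, truth$barcode[i])
      next
    }
    q <- if (is.finite(concentration)) .rdirichlet(concentration * p) else p
    for (k in seq_along(classes)) {
      members <- fine[map == classes[k]]
      nm <- length(members)
      w <- if (is.finite(concentration)) {
        .rdirichlet(rep(1, nm))
      } else {
        # power-of-two weights keep products and sums exact, so the
        # noiseless aggregation identity holds bit for bit
        sample(.dyadic_weights(nm))
      }
      out[i, members] <- q[k] * w
    }
  }
  attr(out, "method") <- method
  attr(out, "sample_id") <- sample_id
  attr(out, "flagged_uniform") <- flagged
  out
}

# 1/2, 1/4, ..., 1/2^(n-1), 1/2^(n-1): sums to 1 exactly in binary
.dyadic_weights <- function(n) {
  if (n == 1) return(1)
  c(2^-(seq_len(n - 1)), 2^-(n - 1))
}

# one Dirichlet draw; zero-alpha components stay exactly zero
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}
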