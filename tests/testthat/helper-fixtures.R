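# Shared fixture builders; everything is generated in code under fixed seeds.

# a spot_composition built directly from count triplets
make_composition <- function(counts, barcodes = NULL,
                             classes = c("tumor", "immune", "stroma")) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(barcodes)) barcodes <- sprintf("BC-%04d", seq_len(n))
  comp <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  for (i in seq_along(classes))
    comp[[paste0("n_", classes[i])]] <- as.integer(counts[, i])
  comp$n_total <- as.integer(rowSums(counts))
  for (i in seq_along(classes)) {
    fr <- counts[, i] / comp$n_total
    fr[comp$n_total == 0] <- NA_real_
    comp[[paste0("frac_", classes[i])]] <- fr
  }
  attr(comp, "classes") <- classes
  class(comp) <- c("spot_composition", "data.frame")
  comp
}

random_composition <- function(n, seed, lambda = 5, empty = 0) {
  set.seed(seed)
  cnt <- matrix(stats::rpois(3 * n, lambda), n, 3)
  if (empty > 0) cnt[sample(n, empty), ] <- 0L
  make_composition(cnt)
}

# small scene shared by the image-pipeline tests (built once per run)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_he_scene(scene_params(
        width = 640, height = 640,
        counts = c(tumor = 20, immune = 20, stroma = 20), seed = 42))
    cache
  }
})

# brute-force square-window assignment oracle (independent of the package's
# vectorized path): all cell-spot pairs, closed inequalities, nearest center
# on multi-containment, barcode order on ties
brute_force_assign <- function(cells, grid) {
  bc <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    best <- Inf; best_bc <- NA_character_
    for (j in seq_len(nrow(grid))) {
      if (abs(cells$x[i] - grid$x[j]) <= grid$radius[j] &&
          abs(cells$y[i] - grid$y[j]) <= grid$radius[j]) {
        d <- (cells$x[i] - grid$x[j])^2 + (cells$y[i] - grid$y[j])^2
        if (d < best || (d == best && grid$barcode[j] < best_bc)) {
          best <- d; best_bc <- grid$barcode[j]
        }
      }
    }
    bc[i] <- best_bc
  }
  data.frame(id = cells$id, barcode = bc, stringsAsFactors = FALSE)
}

# counts fixture with controllable QC failures
make_qc_counts <- function() {
  genes <- c(paste0("G", 1:600), paste0("MT-", 1:5), "HBA1", "HBB")
  barcodes <- c("ok", "few_genes", "hi_mito", "hi_hemo", "boundary", "empty")
  m <- matrix(0, length(genes), length(barcodes),
              dimnames = list(genes, barcodes))
  m[1:600, "ok"] <- 2
  m[1:499, "few_genes"] <- 1            # 499 detected genes
  m[1:600, "hi_mito"] <- 1; m["MT-1", "hi_mito"] <- 209  # 209/809 > 0.25
  m[1:600, "hi_hemo"] <- 1; m["HBA1", "hi_hemo"] <- 151  # 151/751 > 0.20
  # exactly 500 genes detected, total 1000 UMIs, mito exactly 25%,
  # hemoglobin exactly 20% -> kept under strict thresholds
  m[1:52, "boundary"] <- 2
  m[53:498, "boundary"] <- 1            # 52*2 + 446 = 550 regular UMIs
  m["MT-1", "boundary"] <- 250
  m["HBB", "boundary"] <- 200
  m
}
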