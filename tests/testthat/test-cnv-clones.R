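# shared CNV fixture: two clones with disjoint altered chromosomes + reference
cnv_fixture <- function(n_ref = 40, n_clone = 40, depth = 1e4, seed = 11,
                        genes_per_chr = 200, log2fc = 1) {
  go <- make_gene_order(4, genes_per_chr)
  ref <- sprintf("REF-%03d", seq_len(n_ref))
  a <- clone_spec("gain", data.frame(chr = "chr1", start_index = 26,
                                     end_index = 175, log2fc = log2fc),
                  sprintf("GA-%03d", seq_len(n_clone)))
  b <- clone_spec("loss", data.frame(chr = "chr3", start_index = 26,
                                     end_index = 175, log2fc = -log2fc),
                  sprintf("LO-%03d", seq_len(n_clone)))
  cnt <- generate_cnv_counts(go, list(a, b), ref, depth = depth, seed = seed)
  list(gene_order = go, counts = cnt, reference = ref,
       query = c(a$spots, b$spots), clone_of = attr(cnt, "clone_of"))
}

test_that("reference and tumor spot selection rules", {
  comp <- make_composition(rbind(c(0, 3, 2),    # reference
                                 c(1, 9, 0),    # tumor present
                                 c(0, 0, 0),    # no annotated cells
                                 c(7, 2, 1),    # purity 0.7
                                 c(69, 31, 0),  # purity 0.69
                                 c(10, 0, 0)))  # purity 1
  ref <- select_reference_spots(comp)
  expect_identical(ref, comp$barcode[1])
  q7 <- select_tumor_spots(comp, 0.7)
  expect_setequal(q7, comp$barcode[c(4, 6)])    # 0.70 inclusive, 0.69 out
  q5 <- select_tumor_spots(comp, 0.5)
  q9 <- select_tumor_spots(comp, 0.9)
  expect_true(all(q9 %in% q7) && all(q7 %in% q5))
  # QC interaction and empty-set errors
  expect_error(select_tumor_spots(comp, 0.7, qc_pass = comp$barcode[1]),
               "0.70")
  expect_error(select_reference_spots(comp, qc_pass = comp$barcode[2]),
               "reference")
})

test_that("purity threshold nesting holds on random compositions", {
  for (seed in c(2, 5, 9)) {
    comp <- random_composition(300, seed = seed, lambda = 8)
    sets <- lapply(c(0.5, 0.7, 0.9), function(tau)
      tryCatch(select_tumor_spots(comp, tau), error = function(e) character(0)))
    expect_true(all(sets[[3]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[1]]))
  }
})

test_that("null query spots are flat after denoising", {
  go <- make_gene_order(4, 200)
  ref <- sprintf("REF-%03d", 1:40)
  null_clone <- clone_spec("null", NULL, sprintf("NU-%03d", 1:40))
  cnt <- generate_cnv_counts(go, list(null_clone), ref, depth = 1e4, seed = 3)
  prof <- infer_cnv_profile(cnt, ref, null_clone$spots, go)
  q <- prof$profile[prof$role == "query", ]
  expect_lt(mean(abs(q)), 0.02)
})

test_that("an amplified segment stands out in the smoothed profile", {
  fx <- cnv_fixture(seed = 7)
  prof <- infer_cnv_profile(fx$counts, fx$reference, fx$query, fx$gene_order)
  gain_spots <- names(fx$clone_of)[fx$clone_of == "gain"]
  genes <- prof$genes
  # segment interior: stay away from the smoothing window's edge taper
  chr1 <- which(genes$chr == "chr1")
  interior <- intersect(chr1, which(seq_len(nrow(genes)) %in%
                                      chr1[76:125]))
  inseg <- mean(prof$profile[gain_spots, interior])
  outseg <- mean(abs(prof$profile[gain_spots, genes$chr %in%
                                    c("chr2", "chr4")]))
  expect_gte(inseg, 0.3)
  expect_gte(inseg, 5 * outseg)
})

test_that("profile magnitude responds monotonically to fold change", {
  resp <- sapply(c(0.5, 1, 2), function(fc) {
    fx <- cnv_fixture(n_ref = 25, n_clone = 25, seed = 19, log2fc = fc)
    prof <- infer_cnv_profile(fx$counts, fx$reference, fx$query,
                              fx$gene_order)
    gain <- names(fx$clone_of)[fx$clone_of == "gain"]
    chr1 <- prof$genes$chr == "chr1"
    mean(prof$profile[gain, chr1][, 76:125])
  })
  expect_true(all(diff(resp) > 0))
})

test_that("reference profiles are sparser than altered-clone profiles", {
  fx <- cnv_fixture(seed = 29)
  prof <- infer_cnv_profile(fx$counts, fx$reference, fx$query, fx$gene_order)
  zero_frac <- function(rows) mean(prof$profile[rows, ] == 0)
  expect_gt(zero_frac(fx$reference),
            zero_frac(names(fx$clone_of)[fx$clone_of != "reference"]))
})

test_that("short chromosomes: window truncation and skipping", {
  go <- rbind(make_gene_order(2, 60),
              data.frame(gene = "lonely", chr = "chr9", start = 1,
                         stop = 100))
  ref <- sprintf("R%02d", 1:10); qry <- sprintf("Q%02d", 1:10)
  cnt <- generate_cnv_counts(go, list(clone_spec("q", NULL, qry)), ref,
                             depth = 5e3, seed = 4)
  expect_warning(prof <- infer_cnv_profile(cnt, ref, qry, go,
                                           cnv_params(window = 101)),
                 "chr9")
  # 60-gene chromosomes with a 101-gene window: defined everywhere
  expect_equal(ncol(prof$profile), 120)
  expect_true(all(is.finite(prof$profile)))
})

test_that("clone clustering recovers the planted structure exactly", {
  fx <- cnv_fixture(seed = 11)
  prof <- infer_cnv_profile(fx$counts, fx$reference, fx$query, fx$gene_order)
  ca <- call_clones(prof, k = 2)
  truth <- fx$clone_of[ca$barcode]
  expect_equal(adjusted_rand_index(ca$clone, truth), 1)
  # clones are relabelled by decreasing size from A
  expect_setequal(unique(ca$clone), c("A", "B"))
  # determinism: identical input, identical assignment
  ca2 <- call_clones(prof, k = 2)
  expect_identical(as.data.frame(ca), as.data.frame(ca2))
})

test_that("degenerate cuts: k = 1 and a height above the root", {
  fx <- cnv_fixture(n_ref = 15, n_clone = 15, seed = 13)
  prof <- infer_cnv_profile(fx$counts, fx$reference, fx$query, fx$gene_order)
  ca <- call_clones(prof, k = 1)
  expect_true(all(ca$clone == "A"))
  expect_warning(ch <- call_clones(prof, h = 1e9), "single clone")
  expect_true(all(ch$clone == "A"))
  expect_error(call_clones(prof, k = 2, h = 3), "exactly one")
})

test_that("adjusted rand index agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(41)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("profile rejects overlapping or unknown spots", {
  fx <- cnv_fixture(n_ref = 10, n_clone = 10, seed = 2)
  expect_error(infer_cnv_profile(fx$counts, fx$reference,
                                 c(fx$reference[1], fx$query),
                                 fx$gene_order), "disjoint")
  expect_error(infer_cnv_profile(fx$counts, fx$reference, c("ghost"),
                                 fx$gene_order), "absent")
})
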