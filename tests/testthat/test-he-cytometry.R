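test_that("optical density transform: background, decades, clipping", {
  img <- array(255, dim = c(2, 3, 3))
  img[1, 1, ] <- 25.5        # one decade below background
  img[1, 2, ] <- 0           # saturated black
  od <- rgb_to_od(img, background = c(255, 255, 255), od_max = 3)
  expect_equal(od$od[2, 1, ], c(0, 0, 0))                 # background pixel
  expect_equal(od$od[1, 1, ], c(1, 1, 1), tolerance = 1e-12)
  expect_equal(od$od[1, 2, ], c(3, 3, 3))                 # clipped at od_max
  expect_error(rgb_to_od(matrix(1, 2, 2)), "RGB")
  expect_error(rgb_to_od(img, background = c(0, 255, 255)), "> 0")
})

test_that("od is monotone decreasing in pixel intensity", {
  v <- seq(1, 255, length.out = 50)
  img <- array(rep(v, 3), dim = c(1, 50, 3))
  od <- rgb_to_od(img)
  expect_true(all(diff(od$od[1, , 1]) <= 0))
})

test_that("stain vectors are recovered from a Beer-Lambert synthesized image", {
  sc <- small_scene()
  sm <- estimate_stain_vectors(sc$image)
  expect_gte(sum(sm$hematoxylin * sc$stains$hematoxylin), 0.999)
  expect_gte(sum(sm$eosin * sc$stains$eosin), 0.999)
  expect_equal(sqrt(sum(sm$hematoxylin^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(sm$eosin^2)), 1, tolerance = 1e-12)
})

test_that("blank-background-only image yields the stained-pixel error", {
  img <- array(255, dim = c(50, 50, 3))
  expect_error(estimate_stain_vectors(img), "insufficient stained pixels")
})

test_that("stain model validates its invariants", {
  expect_error(stain_model(hematoxylin = c(1, 0, 0), eosin = c(2, 0, 0)),
               "collinear")
  expect_error(stain_model(hematoxylin = c(-1, 1, 0)), "non-negative")
})

test_that("segmentation finds non-overlapping synthetic nuclei near truth", {
  sc <- small_scene()
  od <- rgb_to_od(sc$image, pixel_size = sc$params$pixel_size)
  nuc <- segment_nuclei(od, sc$stains)
  expect_equal(nrow(nuc$table), nrow(sc$truth), tolerance = 0.05)
  m <- match_centroids(nuc$table, sc$truth, gate_um = 5,
                       pixel_size = sc$params$pixel_size)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
  # matched centroids are tight, well under the gate
  expect_lt(m$mean_distance_um, 2)
})

test_that("blank image segments to zero nuclei", {
  img <- array(255, dim = c(64, 64, 3))
  od <- rgb_to_od(img, pixel_size = 0.5)
  nuc <- segment_nuclei(od, stain_model())
  expect_equal(nrow(nuc$table), 0)
  expect_true(all(nuc$labels == 0))
})

test_that("watershed splits two touching intensity peaks", {
  # two disks 16 px apart, radii 9 px, overlapping slightly
  img <- array(255, dim = c(64, 64, 3))
  sm <- stain_model()
  hema <- matrix(0, 64, 64)
  for (ctr in list(c(24, 32), c(40, 32))) {
    xs <- outer(rep(1, 64), 1:64); ys <- outer(1:64, rep(1, 64))
    d2 <- (xs - ctr[1])^2 + (ys - ctr[2])^2
    hema <- hema + exp(-d2 / (2 * 4.5^2))
  }
  for (c in 1:3) img[, , c] <- 255 * 10^-(hema * sm$hematoxylin[c])
  od <- rgb_to_od(img, pixel_size = 1)
  nuc <- segment_nuclei(od, sm, segmentation_params(sigma_um = 1,
                                                    min_area_um2 = 10,
                                                    max_area_um2 = 2000))
  expect_equal(nrow(nuc$table), 2)
})

test_that("cell expansion: identity at zero, analytic disk area, disjointness", {
  sc <- small_scene()
  od <- rgb_to_od(sc$image, pixel_size = sc$params$pixel_size)
  nuc <- segment_nuclei(od, sc$stains)
  c0 <- expand_cells(nuc, 0)
  expect_identical(c0$cell_labels, nuc$labels)

  # isolated circular nucleus radius 4 um at 0.5 um/px, expansion 5 um
  img <- array(255, dim = c(100, 100, 3))
  sm <- stain_model()
  hema <- matrix(0, 100, 100)
  xs <- outer(rep(1, 100), 1:100); ys <- outer(1:100, rep(1, 100))
  hema[(xs - 50)^2 + (ys - 50)^2 <= 8^2] <- 1        # 8 px = 4 um
  for (c in 1:3) img[, , c] <- 255 * 10^-(hema * sm$hematoxylin[c])
  odd <- rgb_to_od(img, pixel_size = 0.5)
  nd <- segment_nuclei(odd, sm, segmentation_params(sigma_um = 0.5,
                                                    max_area_um2 = 500))
  expect_equal(nrow(nd$table), 1)
  cs <- expand_cells(nd, 5)
  cell_area_um2 <- sum(cs$cell_labels == 1) * 0.25
  expect_equal(cell_area_um2, pi * 9^2, tolerance = 0.05)
  # cell contains its nucleus
  expect_true(all(cs$cell_labels[nd$labels == 1] == 1))
})

test_that("nearby nuclei expansions never overlap", {
  # two disks 6 um apart (12 px at 0.5 um/px), expansion 5 um
  img <- array(255, dim = c(80, 80, 3))
  sm <- stain_model()
  hema <- matrix(0, 80, 80)
  xs <- outer(rep(1, 80), 1:80); ys <- outer(1:80, rep(1, 80))
  hema[(xs - 34)^2 + (ys - 40)^2 <= 4^2] <- 1
  hema[(xs - 46)^2 + (ys - 40)^2 <= 4^2] <- 1
  for (c in 1:3) img[, , c] <- 255 * 10^-(hema * sm$hematoxylin[c])
  odd <- rgb_to_od(img, pixel_size = 0.5)
  nd <- segment_nuclei(odd, sm, segmentation_params(sigma_um = 0.5))
  expect_equal(nrow(nd$table), 2)
  cs <- expand_cells(nd, 5)
  # each pixel belongs to at most one cell by construction of the label
  # matrix; check both cells are present and adjacent, not merged
  expect_setequal(unique(as.vector(cs$cell_labels[cs$cell_labels > 0])),
                  c(1, 2))
  # claimed regions partition: nucleus pixels keep their own id
  expect_true(all(cs$cell_labels[nd$labels > 0] == nd$labels[nd$labels > 0]))
})

test_that("feature table: areas, circularity, uniform-od regions", {
  # single rasterized disk with uniform stain
  img <- array(255, dim = c(60, 60, 3))
  sm <- stain_model()
  hema <- matrix(0, 60, 60)
  xs <- outer(rep(1, 60), 1:60); ys <- outer(1:60, rep(1, 60))
  hema[(xs - 30)^2 + (ys - 30)^2 <= 10^2] <- 0.8
  for (c in 1:3) img[, , c] <- 255 * 10^-(hema * sm$hematoxylin[c])
  od <- rgb_to_od(img, pixel_size = 0.5)
  nuc <- segment_nuclei(od, sm,
                        segmentation_params(sigma_um = 0, threshold = 0.1,
                                            max_area_um2 = 500))
  expect_equal(nrow(nuc$table), 1)
  cells <- expand_cells(nuc, 0)
  ft <- compute_features(nuc, cells, od, sm)
  expect_equal(nrow(ft), 1)
  # area: pixel count times pixel_size^2
  expect_equal(ft$nucleus_area, nuc$table$area_px * 0.25)
  # a disk is the maximum-circularity shape
  expect_gte(ft$circularity, 0.9)
  expect_lte(ft$circularity, 1.0)
  # uniform stain: mean equals max equals the constant
  expect_equal(ft$nucleus_hema_mean, 0.8, tolerance = 1e-6)
  expect_equal(ft$nucleus_hema_max, ft$nucleus_hema_mean, tolerance = 1e-6)
  # zero expansion: empty cytoplasm features are missing, row kept
  expect_true(is.na(ft$cytoplasm_hema_mean))
  expect_equal(ft$cell_area, ft$nucleus_area)
})

test_that("feature smoothing: isolated cells, equal values, two-cell weights", {
  tab <- data.frame(id = 1:2, x = c(0, 10), y = c(0, 0),
                    val = c(0, 1))
  attr(tab, "pixel_size") <- 1
  # isolated: neighbour outside the 2*radius support
  sm1 <- smooth_features(tab, radius = 4)
  expect_equal(sm1$val_smoothed_4, c(0, 1))
  # two cells with identical values stay put
  tab2 <- tab; tab2$val <- c(5, 5)
  sm2 <- smooth_features(tab2, radius = 10)
  expect_equal(sm2$val_smoothed_10, c(5, 5))
  # hand-evaluated two-term weighted mean at distance d = sigma
  # sigma = radius/2 = 10 when radius 20; put cells 10 apart
  sm3 <- smooth_features(tab, radius = 20)
  w <- exp(-0.5)
  expect_equal(sm3$val_smoothed_20[1], w / (1 + w), tolerance = 1e-12)
  expect_equal(sm3$val_smoothed_20[2], 1 / (1 + w), tolerance = 1e-12)
})

test_that("smoothed means equal raw means when all pairwise distances agree", {
  # equilateral triangle: every pairwise distance equal
  tab <- data.frame(id = 1:3, x = c(0, 10, 5), y = c(0, 0, 5 * sqrt(3)),
                    val = c(1, 2, 6))
  attr(tab, "pixel_size") <- 1
  sm <- smooth_features(tab, radius = 30)
  expect_equal(mean(sm$val_smoothed_30), mean(tab$val), tolerance = 1e-12)
})

test_that("cell table survives the QuPath-dialect round trip", {
  sc <- small_scene()
  od <- rgb_to_od(sc$image, pixel_size = sc$params$pixel_size)
  nuc <- segment_nuclei(od, sc$stains)
  cells <- expand_cells(nuc, 3)
  ft <- compute_features(nuc, cells, od, sc$stains)
  ft$class <- sample(c("tumor", "immune", "stroma"), nrow(ft), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(ft, path)
  back <- read_cell_table(path, pixel_size = sc$params$pixel_size)
  expect_equal(back$x, ft$x, tolerance = 1e-9)
  expect_equal(back$y, ft$y, tolerance = 1e-9)
  expect_equal(back$class, ft$class)
  expect_equal(back$nucleus_area, ft$nucleus_area, tolerance = 1e-9)
})
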