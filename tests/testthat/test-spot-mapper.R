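test_that("scale factor arithmetic and validation", {
  expect_equal(compute_scale_factor(20000, 6000), 0.3)
  expect_equal(compute_scale_factor(5000, 5000), 1)
  expect_error(compute_scale_factor(20000, 0), "> 0")
  expect_error(compute_scale_factor(100, 200), "taller")
})

test_that("registration-to-fullres transform: flip, scaling, involution", {
  g <- data.frame(barcode = "s1", x = 10, y = 30, radius = 5)
  attr(g, "frame") <- "registered"
  geom <- image_geometry(100, 100, scale = 1, y_flip = TRUE)
  t1 <- registered_to_fullres(g, geom)
  expect_equal(t1$x, 10)
  expect_equal(t1$y, 70)                       # H - y
  # applying the inverse recovers the input exactly
  back <- fullres_to_registered(t1, geom)
  expect_equal(back$y, 30)
  # scale 0.3, no flip
  g2 <- data.frame(barcode = "s1", x = 30, y = 60, radius = 16.5)
  attr(g2, "frame") <- "registered"
  geom2 <- image_geometry(1000, 1000, scale = 0.3, y_flip = FALSE)
  t2 <- registered_to_fullres(g2, geom2)
  expect_equal(t2$x, 100)
  expect_equal(t2$y, 200)
  expect_equal(t2$radius, 55)
})

test_that("transform round trip is exact to 1e-9 px on random geometries", {
  set.seed(21)
  for (r in 1:20) {
    H <- runif(1, 500, 30000); W <- runif(1, 500, 30000)
    s <- runif(1, 0.05, 1)
    flip <- r %% 2 == 0
    geom <- image_geometry(W, H, scale = s, y_flip = flip)
    g <- data.frame(barcode = sprintf("s%d", 1:50),
                    x = runif(50, 0, W * s), y = runif(50, 0, H * s),
                    radius = runif(50, 1, 40))
    attr(g, "frame") <- "registered"
    fwd <- suppressWarnings(registered_to_fullres(g, geom))
    back <- fullres_to_registered(fwd, geom)
    expect_lt(max(abs(back$x - g$x)), 1e-9)
    expect_lt(max(abs(back$y - g$y)), 1e-9)
  }
})

test_that("out-of-bounds transformed spots are kept and flagged", {
  g <- data.frame(barcode = "s1", x = 90, y = 10, radius = 1)
  attr(g, "frame") <- "registered"
  geom <- image_geometry(50, 50, scale = 0.5, y_flip = FALSE)
  expect_warning(t1 <- registered_to_fullres(g, geom), "flagged")
  expect_true(t1$out_of_bounds)
  expect_equal(nrow(t1), 1)
})

test_that("square-window assignment containment and exclusion", {
  grid <- data.frame(barcode = "A", x = 50, y = 50, radius = 10)
  cells <- data.frame(id = 1:3, x = c(45, 61, 60), y = c(58, 50, 60))
  a <- assign_cells_to_spots(cells, grid)
  expect_equal(a$barcode, c("A", NA, "A"))   # boundary (60,60) included
})

test_that("assignment equals the brute-force oracle on random geometries", {
  for (seed in c(1, 2, 3, 17, 33)) {
    set.seed(seed)
    n_cells <- sample(100:500, 1); n_spots <- sample(10:50, 1)
    cells <- data.frame(id = seq_len(n_cells),
                        x = runif(n_cells, 0, 1000),
                        y = runif(n_cells, 0, 1000))
    # adversarial: large overlapping radii exercise multi-containment
    grid <- data.frame(barcode = sprintf("S%03d", sample(n_spots)),
                       x = runif(n_spots, 0, 1000),
                       y = runif(n_spots, 0, 1000),
                       radius = runif(n_spots, 20, 120))
    expect_identical(assign_cells_to_spots(cells, grid),
                     brute_force_assign(cells, grid))
  }
})

test_that("frame mismatch between cells and grid errors", {
  cells <- data.frame(id = 1, x = 1, y = 1)
  attr(cells, "frame") <- "registered"
  grid <- data.frame(barcode = "A", x = 0, y = 0, radius = 5)
  attr(grid, "frame") <- "fullres"
  expect_error(assign_cells_to_spots(cells, grid), "frames")
})

test_that("composition: fractions, empty spots, conservation", {
  asn <- data.frame(id = 1:12,
                    barcode = c(rep("S1", 10), "S2", NA))
  lab <- c(rep("tumor", 7), "immune", "immune", "stroma", "tumor", "immune")
  comp <- compose_spots(asn, lab, barcodes = c("S1", "S2", "S3"))
  s1 <- comp[comp$barcode == "S1", ]
  expect_equal(c(s1$frac_tumor, s1$frac_immune, s1$frac_stroma),
               c(0.7, 0.2, 0.1))
  s3 <- comp[comp$barcode == "S3", ]
  expect_equal(s3$n_total, 0L)
  expect_true(is.na(s3$frac_tumor))
  # conservation: class counts over spots = assigned cells of that class
  expect_equal(sum(comp$n_tumor), sum(lab[!is.na(asn$barcode)] == "tumor"))
  expect_equal(sum(comp$n_immune), sum(lab[!is.na(asn$barcode)] == "immune"))
  # unlabeled assigned cell errors
  lab2 <- lab; lab2[1] <- NA
  expect_error(compose_spots(asn, lab2), "without a class label")
})

test_that("composition invariants hold over random fixtures", {
  set.seed(77)
  for (r in 1:25) {
    n_cells <- sample(50:200, 1)
    grid <- generate_spot_grid(grid_params(rows = 4, cols = 4,
                                           origin_px = c(50, 50)))
    cells <- data.frame(id = seq_len(n_cells),
                        x = runif(n_cells, 0, 900),
                        y = runif(n_cells, 0, 900))
    lab <- sample(c("tumor", "immune", "stroma"), n_cells, replace = TRUE)
    asn <- assign_cells_to_spots(cells, grid)
    comp <- compose_spots(asn, lab, barcodes = grid$barcode)
    nonempty <- comp$n_total > 0
    sums <- comp$frac_tumor[nonempty] + comp$frac_immune[nonempty] +
      comp$frac_stroma[nonempty]
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_equal(comp$n_tumor + comp$n_immune + comp$n_stroma, comp$n_total)
    expect_equal(sum(comp$n_total), sum(!is.na(asn$barcode)))
  }
})

test_that("qc filter applies the strict thresholds and reports reasons", {
  m <- make_qc_counts()
  qc <- qc_filter_spots(m)
  rep_ <- qc$report
  expect_setequal(qc$kept, c("ok", "boundary"))
  expect_match(rep_$reasons[rep_$barcode == "few_genes"], "500 detected")
  expect_match(rep_$reasons[rep_$barcode == "hi_mito"], "mitochondrial")
  expect_match(rep_$reasons[rep_$barcode == "hi_hemo"], "hemoglobin")
  expect_match(rep_$reasons[rep_$barcode == "empty"], "no counts")
  # the boundary spot sits exactly at 500 genes / 25% mito / 20% hemo
  b <- rep_[rep_$barcode == "boundary", ]
  expect_equal(b$detected_genes, 500L)
  expect_equal(b$mito_fraction, 0.25)
  expect_equal(b$hemo_fraction, 0.20)
  expect_true(b$pass)
})

test_that("spot density: per-cluster cells per spot", {
  comp <- make_composition(rbind(c(5, 3, 2), c(10, 5, 5), c(0, 0, 0),
                                 c(3, 1, 1)))
  lab <- c("c1", "c1", "c2", "c1")
  names(lab) <- comp$barcode
  d <- spot_density(comp, lab)
  expect_equal(unname(d["c1"]), (10 + 20 + 5) / 3)
  expect_equal(unname(d["c2"]), 0)
  # single spot
  d1 <- spot_density(comp, stats::setNames("solo", comp$barcode[1]))
  expect_equal(unname(d1), 10)
  expect_error(spot_density(comp, c(nope = "x")), "absent")
})
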