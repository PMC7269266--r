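test_that("local-mean binarization handles flat, disk and inverted images", {
  # constant image: nothing is darker than its neighbourhood
  flat <- matrix(0.5, 80, 80)
  expect_true(all(!binarize_local_mean(flat, 15)))
  # one dark disk on bright background: compare against a global midpoint
  # threshold oracle via intersection-over-union
  img <- matrix(0.9, 120, 120)
  img[disk_mask(120, 120, 60, 60, 18)] <- 0.2
  mask <- binarize_local_mean(img, 65)
  oracle <- img < 0.55
  iou <- sum(mask & oracle) / sum(mask | oracle)
  expect_gte(iou, 0.95)
  # polarity symmetry: bright-mode on the inverted image equals dark-mode
  inv <- 1.1 - img
  expect_identical(binarize_local_mean(inv, 65, polarity = "bright"), mask)
  expect_error(binarize_local_mean(img, 201), "larger than the image")
  expect_error(binarize_local_mean(img, 10), "odd")
})

test_that("watershed reproduces connected components for disjoint objects", {
  m <- disk_mask(100, 160, 50, 40, 15) | disk_mask(100, 160, 50, 120, 15)
  lab <- segment_watershed(m)
  expect_identical(attr(lab, "n_objects"), 2L)
  cc <- matrix(as.integer(EBImage::bwlabel(m * 1)), 100)
  # same pixel partition (labels may be permuted)
  expect_true(all((lab > 0) == (cc > 0)))
  for (k in 1:2) expect_equal(length(unique(cc[lab == k])), 1L)
  one <- segment_watershed(disk_mask(60, 60, 30, 30, 12))
  expect_identical(attr(one, "n_objects"), 1L)
  empty <- segment_watershed(matrix(FALSE, 20, 20))
  expect_identical(attr(empty, "n_objects"), 0L)
})

test_that("watershed splits a two-disk fusion at the neck bisector", {
  r <- 20
  m <- disk_mask(120, 160, 60, 60, r) | disk_mask(120, 160, 60, 90, r)  # 1.5 r apart
  lab <- segment_watershed(m)
  expect_identical(attr(lab, "n_objects"), 2L)
  # the analytic bisector of two equal disks is the vertical line x = 75;
  # every pixel farther than 2 px from it must carry its own side's label
  left_lab <- lab[60, 60]; right_lab <- lab[60, 90]
  expect_true(left_lab != right_lab && left_lab > 0 && right_lab > 0)
  cols <- col(lab)
  expect_true(all(lab[cols < 73 & lab > 0] == left_lab))
  expect_true(all(lab[cols > 77 & lab > 0] == right_lab))
  # label conservation: watershed assigns every foreground pixel exactly once
  expect_equal(sum(lab > 0), sum(m))
})

test_that("region measurement arithmetic is exact on known shapes", {
  # single pixel at 4.5 um/px
  lab1 <- matrix(0L, 7, 7); lab1[4, 4] <- 1L
  m1 <- measure_regions(lab1, 4.5)
  expect_equal(m1$area_um2, 20.25)
  expect_equal(m1$equivalent_diameter_um, sqrt(4 * 20.25 / pi), tolerance = 1e-9)
  # axis-aligned square: Feret extremes a and a*sqrt(2)
  a <- 11
  lab2 <- matrix(0L, 20, 20); lab2[5:(4 + a), 6:(5 + a)] <- 1L
  m2 <- measure_regions(lab2, 1)
  expect_equal(m2$feret_min_um, a, tolerance = 1e-9)
  expect_equal(m2$feret_max_um, a * sqrt(2), tolerance = 1e-9)
  expect_equal(m2$feret_ratio, sqrt(0.5), tolerance = 1e-9)
  # rasterized disk of radius 20 px: equivalent diameter within 2% of 180 um
  lab3 <- matrix(0L, 60, 60); lab3[disk_mask(60, 60, 30, 30, 20)] <- 1L
  m3 <- measure_regions(lab3, 4.5)
  d_oracle <- sqrt(4 * sum(lab3) / pi) * 4.5      # pixel-count oracle
  expect_equal(m3$equivalent_diameter_um, d_oracle, tolerance = 1e-12)
  expect_lt(abs(m3$equivalent_diameter_um - 180) / 180, 0.02)
  expect_gt(m3$circularity, 0.9)
  expect_lt(m3$circularity, 1.1)
})

test_that("circularity matches closed forms for circle, square and ellipse", {
  r <- 3.7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  a <- 2.2
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-12)
  # 2:1 ellipse: perimeter by quadrature of the arc-length integral
  A <- 2; B <- 1
  arc <- function(t) sqrt(A^2 * sin(t)^2 + B^2 * cos(t)^2)
  per <- 4 * stats::integrate(arc, 0, pi / 2, rel.tol = 1e-12)$value
  expect_equal(circularity(pi * A * B, per), 0.8411, tolerance = 1e-4)
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
})

test_that("area and edge filters drop exactly the standard exclusions and are idempotent", {
  lab <- matrix(0L, 40, 40)
  lab[2:4, 2:4] <- 1L                  # 9 px = 182.25 um^2 -> removed
  lab[10:11, 10:14] <- 2L              # 10 px = 202.5 um^2 -> kept
  lab[30:40, 30:36] <- 3L              # large but touches the border -> removed
  meas <- measure_regions(lab, 4.5)
  f1 <- filter_regions(meas, lab, quiet = TRUE)
  expect_equal(nrow(f1$measurements), 1L)
  expect_equal(f1$measurements$area_um2, 202.5)
  expect_equal(sort(unique(as.vector(f1$labels))), c(0L, 1L))
  f2 <- filter_regions(f1$measurements, f1$labels, quiet = TRUE)
  expect_equal(f2$measurements, f1$measurements, ignore_attr = TRUE)
  expect_true(all(f2$labels == f1$labels))
})

test_that("measurements scale correctly with pixel size", {
  lab <- matrix(0L, 50, 50)
  lab[disk_mask(50, 50, 25, 25, 13) ] <- 1L
  m1 <- measure_regions(lab, 2)
  m2 <- measure_regions(lab, 4)
  expect_equal(m2$equivalent_diameter_um, 2 * m1$equivalent_diameter_um)
  expect_equal(m2$feret_max_um, 2 * m1$feret_max_um)
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$circularity, m1$circularity)
  expect_equal(m2$feret_ratio, m1$feret_ratio)
})

test_that("size distributions normalize and weight volume as d cubed", {
  # all equal: a single occupied bin with q0 * width = 1
  eq <- size_distributions(rep(150, 20), 20)
  occ <- which(eq$q0 > 0)
  expect_length(occ, 1L)
  expect_equal(eq$q0[occ] * 20, 1, tolerance = 1e-12)
  # two sizes 100 and 200 um, equal counts: q3 mass ratio 1:8
  two <- size_distributions(c(100, 200), 50)
  m100 <- two$q3[findInterval(100, two$bin_edges_um, left.open = TRUE)]
  m200 <- two$q3[findInterval(200, two$bin_edges_um, left.open = TRUE)]
  expect_equal(m200 / m100, 8, tolerance = 1e-12)
  # log-normal sample vs the independently coded histogram oracle
  set.seed(42)
  d <- rlnorm(1e4, log(150), 0.3)
  sd_ <- size_distributions(d, 20)
  expect_equal(sd_$q0, histogram_density_oracle(d, rep(1, length(d)), sd_$bin_edges_um),
               tolerance = 1e-12)
  expect_equal(sd_$q3, histogram_density_oracle(d, d^3, sd_$bin_edges_um),
               tolerance = 1e-12)
  expect_equal(sum(sd_$q0 * 20), 1, tolerance = 1e-9)
  expect_equal(sum(sd_$q3 * 20), 1, tolerance = 1e-9)
  expect_error(size_distributions(numeric(0), 20), "no diameters")
})

test_that("full pipeline recovers the synthetic truth per object", {
  p <- image_gen_params(image_width_px = 1024L, image_height_px = 768L,
                        n_pellets = 30L, noise_sd = 0, seed = 21L)
  g <- generate_pellet_image(p)
  res <- analyze_pellet_image(g$image)
  mt <- match_truth(res$measurements, g$truth)
  expect_true(all(mt$matched))
  tol <- pmax(2 * 4.5, 0.03 * mt$true_d)
  expect_true(all(abs(mt$measured_d - mt$true_d) <= tol))
  # label conservation through filtering
  expect_equal(sum(res$labels > 0),
               sum(res$measurements$area_um2) / 4.5^2, tolerance = 1e-9)
})

test_that("rendered circles keep circularity above 0.9 through the pipeline", {
  p <- image_gen_params(image_width_px = 900L, image_height_px = 700L,
                        n_pellets = 15L, eccentricity_max = 0, noise_sd = 0,
                        seed = 3L)
  g <- generate_pellet_image(p)
  m <- analyze_pellet_image(g$image)$measurements
  expect_equal(nrow(m), 15L)
  expect_true(all(m$circularity >= 0.9))
})
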