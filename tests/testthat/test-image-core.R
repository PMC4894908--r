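test_that("color-threshold segmentation follows inclusive per-channel windows", {
  win <- threshold_window(red = c(0, 255), green = c(0, 115), blue = c(0, 255))
  expect_true(segment_by_window(flat_image(c(100, 100, 100)), win)$pixels[1, 1])
  expect_false(segment_by_window(flat_image(c(100, 130, 100)), win)$pixels[1, 1])
  # boundary value is included on both ends
  expect_true(segment_by_window(flat_image(c(100, 115, 100)), win)$pixels[1, 1])
  # an all-black image is outside the birefringence window (0 < every min)
  dark <- segment_by_window(flat_image(c(0, 0, 0)), birefringence_window())
  expect_false(any(dark$pixels))
})

test_that("segmentation is idempotent on window-extreme binarized images", {
  win <- threshold_window(red = c(0, 120), green = c(0, 255), blue = c(0, 255))
  set.seed(11)
  arr <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), dim = c(32, 32, 3))
  m1 <- segment_by_window(rgb_image(arr), win)
  # rebuild an image at the window extremes from the mask
  arr2 <- array(0L, dim = c(32, 32, 3))
  arr2[, , 1] <- ifelse(m1$pixels, 0L, 255L)
  m2 <- segment_by_window(rgb_image(arr2), win)
  expect_identical(m1$pixels, m2$pixels)
})

test_that("masks from disjoint green windows are disjoint", {
  set.seed(12)
  arr <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), dim = c(24, 24, 3))
  img <- rgb_image(arr)
  lo <- segment_by_window(img, threshold_window(green = c(0, 100)))
  hi <- segment_by_window(img, threshold_window(green = c(101, 255)))
  expect_false(any(lo$pixels & hi$pixels))
})

test_that("image constructor and reader enforce the invariants", {
  expect_error(rgb_image(array(0L, dim = c(4, 4, 3))), "8 x 8")
  expect_error(rgb_image(array(300L, dim = c(8, 8, 3))), "0, 255")
  expect_error(rgb_image(array(0L, dim = c(8, 8, 3)), pixel_size = 0),
               "positive")
  # PNG round trip, including grayscale replication
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64 * 64), 64, 64), tmp)
  img <- read_image(tmp, pixel_size = 2)
  expect_equal(dim(img$pixels), c(64, 64, 3))
  expect_identical(img$pixels[, , 1], img$pixels[, , 3])
  expect_error(read_image("no/such/file.png"), "cannot read")
})

test_that("particle labeling matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(runif(256) < runif(1, 0.2, 0.7), 16, 16)
    expect_identical(package_labels(m), flood_fill_label(m, 8))
  }
})

test_that("two disjoint squares give two particles; filled ring gives one", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 8:10] <- TRUE
  p <- label_particles(binary_mask(m))
  expect_equal(nrow(p), 2L)
  expect_equal(p$area_px, c(9L, 9L))
  ring <- matrix(FALSE, 11, 11)
  ring[2:10, 2:10] <- TRUE
  ring[5:7, 5:7] <- FALSE
  filled <- label_particles(binary_mask(ring), fill_holes = TRUE)
  expect_equal(nrow(filled), 1L)
  expect_equal(filled$area_px, 81L)
  # without filling, the hole stays background
  open <- label_particles(binary_mask(ring), fill_holes = FALSE)
  expect_equal(open$area_px, 81L - 9L)
  expect_equal(nrow(label_particles(binary_mask(matrix(FALSE, 8, 8)))), 0L)
})

test_that("particle areas sum to the foreground pixel count", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    p <- label_particles(binary_mask(m), fill_holes = TRUE)
    filled <- fill_holes(binary_mask(m))
    expect_identical(sum(p$area_px), sum(filled$pixels))
  }
})

test_that("circularity follows the closed form and is clamped at 1", {
  r <- 12.5
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1.0)
  s <- 9
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  expect_equal(circularity(100, 1), 1.0)  # clamp
  expect_error(circularity(10, 0), "positive")
  expect_error(circularity(0, 10), ">= 1")
})

test_that("rasterized disk scores near-circular, thin line scores far below 0.5", {
  p <- label_particles(binary_mask(raster_disk(20)))
  expect_equal(nrow(p), 1L)
  expect_gte(p$circularity, 0.85)
  expect_lte(p$circularity, 1.0)
  # frozen regression value for the Crofton estimator on a radius-20 disk
  expect_equal(p$perimeter_px, 127.7137, tolerance = 1e-6)
  line <- matrix(FALSE, 5, 34)
  line[3, 3:32] <- TRUE
  pl <- label_particles(binary_mask(line))
  expect_lt(pl$circularity, 0.5)
})

test_that("area calibration scales exactly with pixel_size squared", {
  m <- raster_disk(10)
  p1 <- label_particles(binary_mask(m, pixel_size = 1))
  p2 <- label_particles(binary_mask(m, pixel_size = 2.5))
  expect_equal(p2$area_um2, p1$area_um2 * 2.5^2)
  expect_identical(p1$area_px, p2$area_px)
})

test_that("particle filter applies circularity, size and edge rules", {
  m <- matrix(FALSE, 40, 60)
  m[10:20, 5:15] <- TRUE          # big block
  m[30, 20:49] <- TRUE            # thin line, low circularity
  m[1:5, 40:44] <- TRUE           # edge-touching block
  p <- label_particles(binary_mask(m))
  keep <- apply_filter(p, particle_filter(area_min_px = 1, area_max_px = 1e6))
  expect_equal(nrow(keep), 1L)    # line fails circularity, edge block dropped
  expect_false(any(keep$touches_edge))
  keep2 <- apply_filter(p, particle_filter(circularity_min = 0,
                                           area_min_px = 1,
                                           area_max_px = 1e6,
                                           exclude_edges = FALSE))
  expect_equal(nrow(keep2), 3L)
  # default extreme-size rule: [0.25x, 4x] the median area
  areas <- c(4, 100, 100, 100, 1000)
  pp <- tibble::tibble(
    label = 1:5, area_px = areas, area_um2 = areas, perimeter_px = rep(10, 5),
    circularity = rep(1, 5), centroid_row = rep(1, 5), centroid_col = rep(1, 5),
    touches_edge = rep(FALSE, 5), row0 = 0L, col0 = 0L, row1 = 1L, col1 = 1L)
  expect_equal(apply_filter(pp, particle_filter())$area_px, c(100, 100, 100))
})

test_that("threshold config round-trips through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "capsule_window:",
    "  red_min: 0", "  red_max: 255",
    "  green_min: 0", "  green_max: 115",
    "  blue_min: 0", "  blue_max: 255",
    "filter:",
    "  circularity_min: 0.5", "  circularity_max: 1.0",
    "  exclude_edges: true"), tmp)
  cfg <- read_threshold_config(tmp)
  expect_equal(cfg$capsule_window$green, c(0L, 115L))
  expect_equal(cfg$seed_window$red, c(0L, 120L))       # default
  expect_equal(cfg$birefringence_window$green, c(140L, 255L))
  expect_true(cfg$filter$exclude_edges)
})
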