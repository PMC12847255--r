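test_that("segmentation finds each planted blob and nothing else", {
  img <- array(10, c(200, 200, 3))
  put_ellipse <- function(img, cr, cc, a, b) {
    for (i in max(1, cr - a):min(200, cr + a))
      for (j in max(1, cc - b):min(200, cc + b))
        if (((i - cr) / a)^2 + ((j - cc) / b)^2 <= 1) img[i, j, ] <- 200
    img
  }
  img <- put_ellipse(img, 40, 50, 15, 12)
  img <- put_ellipse(img, 120, 60, 18, 13)
  img <- put_ellipse(img, 150, 150, 14, 16)
  regions <- segment_seeds(img, segmentation_config(min_area = 100))
  ## oracle: flood-fill component count on a plain threshold
  expect_equal(flood_count(img[, , 1] > 100), 3)
  expect_length(regions, 3)
  ## sorted by (row0, col0)
  r0 <- vapply(regions, function(r) r$bbox[["row0"]], numeric(1))
  expect_equal(r0, sort(r0))
})

test_that("all-background and invalid inputs are handled", {
  expect_length(segment_seeds(array(0, c(50, 50, 3))), 0)
  expect_error(segment_seeds(array(0, c(50, 50, 2))), "3 channels")
  ## uniform foreground after opening smaller than min_area -> empty
  img <- array(10, c(80, 80, 3)); img[40:42, 40:42, ] <- 200
  expect_length(segment_seeds(img, segmentation_config(min_area = 200)), 0)
})

test_that("margin expansion grows the bounding box and clips to bounds", {
  m <- disk_mask(30, size = 200, center = 100)
  regions <- segment_seeds(gray_board(m),
                           segmentation_config(margin_px = 15))
  expect_length(regions, 1)
  r <- regions[[1]]
  side <- r$bbox[["row1"]] - r$bbox[["row0"]]
  expect_lt(abs(side - 60), 2.5)
  side_exp <- r$bbox_expanded[["row1"]] - r$bbox_expanded[["row0"]]
  expect_lt(abs(side_exp - 90), 2.5)
  expect_equal(dim(r$crop), dim(r$mask))
})

test_that("geometric descriptors match circle and rectangle identities", {
  g <- geometric_features(region_from_mask(disk_mask(50)))
  expect_equal(g[["C"]], 1, tolerance = 0.05)
  expect_equal(g[["K"]], 1, tolerance = 0.02)
  expect_equal(g[["E"]], 0, tolerance = 0.02)
  expect_equal(g[["Ed"]], 100, tolerance = 0.02)
  expect_equal(g[["r"]], 50, tolerance = 0.03)
  g2 <- geometric_features(region_from_mask(rect_mask(20, 60)))
  expect_equal(g2[["R"]], 1, tolerance = 0.05)
  expect_equal(g2[["K"]], 3, tolerance = 0.1 / 3)
  expect_equal(g2[["A"]], 1200)
})

test_that("geometric descriptors are exactly translation invariant", {
  m <- disk_mask(20, size = 90, center = 30)
  shifted <- matrix(FALSE, 90, 90)
  shifted[8:90, 12:90] <- m[1:83, 1:79]   # translate by (7, 11)
  g1 <- geometric_features(region_from_mask(m))
  g2 <- geometric_features(region_from_mask(shifted))
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("shape ratios and Hu moments are stable under 90-degree rotation", {
  m <- rect_mask(20, 60)
  g1 <- geometric_features(region_from_mask(m))
  g2 <- geometric_features(region_from_mask(t(m)))
  for (f in c("C", "K", "E", "R", paste0("H", 0:3)))
    expect_equal(g1[[f]], g2[[f]], tolerance = 0.02)
})

test_that("degenerate one-pixel-wide masks raise an error", {
  m <- matrix(FALSE, 20, 20); m[10, 3:18] <- TRUE
  expect_error(geometric_features(region_from_mask(m)), "degenerate")
})

test_that("texture statistics collapse correctly on a constant crop", {
  reg <- region_from_mask(matrix(TRUE, 10, 10),
                          crop = matrix(0.5, 10, 10))
  tx <- suppressMessages(texture_features(reg))
  expect_equal(tx[["Con"]], 0)
  expect_equal(tx[["Dis"]], 0)
  expect_equal(tx[["Hom"]], 1)
  expect_equal(tx[["ASM"]], 1)
  expect_equal(tx[["Ene"]], 1)
  expect_equal(tx[["Corr"]], 0)   # zero-variance convention
  ## constant crop: every interior pixel is the all-ones uniform pattern
  expect_equal(tx[["hist8"]], 1)
  expect_equal(sum(tx[paste0("hist", 0:9)]), 1, tolerance = 1e-9)
})

test_that("horizontal GLCM contrast of a two-level checkerboard is (levels-1)^2", {
  cb <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 0, 31))
  tx <- texture_features(region_from_mask(matrix(TRUE, 8, 8), crop = cb),
                         angles = 0)
  ## every horizontal neighbour pair spans the full quantized range
  expect_equal(tx[["Con"]], 961)
})

test_that("the feature vector has the 34 canonical entries in fixed order", {
  expect_length(morph_feature_names(), 34)
  v <- morph_features(region_from_mask(disk_mask(15),
                                       crop = matrix(runif(2500), 50)))
  expect_identical(names(v), morph_feature_names())
  expect_equal(v[["Ene"]]^2, v[["ASM"]], tolerance = 1e-9)
  expect_true(all(v[paste0("hist", 0:9)] >= 0))
})

test_that("segmentation recovers the planted seed count on fixture boards", {
  spec <- fixture_spec("easy", seeds_per_image = 5,
                       image_size = c(300, 300))
  hits <- 0; n_img <- 40
  for (s in seq_len(n_img)) {
    im <- make_seed_image(spec, (s %% 4) + 1, seed = s)
    found <- length(segment_seeds(im$image))
    hits <- hits + (found == nrow(im$truth))
  }
  expect_gte(hits / n_img, 0.95)
})

test_that("extracted aspect ratio separates elongated from round classes", {
  spec <- fixture_spec("easy", seeds_per_image = 10,
                       image_size = c(350, 350))
  k_of <- function(cl) {
    im <- make_seed_image(spec, cl, seed = 42 + cl)
    tab <- extract_morphology(im$image)
    mean(tab$K)
  }
  expect_gt(k_of(3) - k_of(1), 1.0)  # axis ratio ~3 vs ~1.2
})
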