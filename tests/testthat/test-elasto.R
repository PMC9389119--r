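test_that("hue map follows the 0-180 half-circle convention", {
  px <- function(r, g, b) {
    a <- array(0, c(1, 1, 3)); a[1, 1, ] <- c(r, g, b); a
  }
  expect_equal(to_hue_map(px(0, 0, 255))[1, 1], 120)    # pure blue
  expect_equal(to_hue_map(px(255, 0, 0))[1, 1], 0)      # pure red
  expect_equal(to_hue_map(px(0, 255, 0))[1, 1], 60)     # pure green
  expect_equal(to_hue_map(px(128, 128, 128))[1, 1], 0)  # achromatic
})

test_that("stiff area ratio counts the closed stiff band", {
  hm <- matrix(160, 4, 4)
  roi <- matrix(TRUE, 4, 4)
  expect_equal(stiff_area_ratio(hm, roi), 1)
  hm[1:2, ] <- 90
  expect_equal(stiff_area_ratio(hm, roi), 0.5)
  # boundary values are included (closed interval)
  expect_equal(stiff_area_ratio(matrix(145, 1, 1), matrix(TRUE, 1, 1)), 1)
  expect_error(stiff_area_ratio(hm, matrix(FALSE, 4, 4)), "empty")
})

test_that("mean hue is the arithmetic mean after clamping", {
  roi <- matrix(TRUE, 1, 2)
  expect_equal(mean_hue(matrix(c(100, 200), 1, 2), roi), 140)
  expect_equal(mean_hue(matrix(145, 3, 3), matrix(TRUE, 3, 3)), 145)
  expect_error(mean_hue(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("band masks assign nearest colormap entries to density bands", {
  cm <- elasto_colormap()
  img <- array(0L, c(1, 3, 3))
  img[1, 1, ] <- cm[11, ]   # index 10 -> blue band [0, 49]
  img[1, 2, ] <- cm[101, ]  # index 100 -> green band [50, 152]
  img[1, 3, ] <- cm[201, ]  # index 200 -> red band [153, 255]
  mb <- colormap_band_masks(img)
  expect_true(mb$blue[1, 1] && mb$green[1, 2] && mb$red[1, 3])
  expect_error(
    colormap_band_masks(img, list(blue = c(0, 60), green = c(50, 152))),
    "overlap")
})

test_that("a full-colormap test strip yields band counts 50/103/103", {
  cm <- elasto_colormap()
  strip <- array(0L, c(1, 256, 3))
  for (j in 1:256) strip[1, j, ] <- cm[j, ]
  mb <- colormap_band_masks(strip)
  expect_equal(sum(mb$blue), 50)
  expect_equal(sum(mb$green), 103)
  expect_equal(sum(mb$red), 103)
})

test_that("color ratios use pixel counts with an Inf sentinel", {
  roi <- matrix(TRUE, 2, 30)
  masks <- list(blue = roi & FALSE, green = roi & FALSE, red = roi)
  masks$blue[1, ] <- TRUE; masks$green[2, ] <- TRUE
  expect_equal(color_ratio(masks, roi, "blue", "green"), 1)
  masks$blue[] <- FALSE
  expect_equal(color_ratio(masks, roi, "blue", "red"), 0)
  masks$red[] <- FALSE
  expect_message(r <- color_ratio(masks, roi, "blue", "red"), "Inf")
  expect_identical(r, Inf)
})

test_that("mean gray: stiffness index scores blue 255, luma scores white 255", {
  cm <- elasto_colormap()
  img <- array(0L, c(2, 2, 3))
  for (i in 1:2) for (j in 1:2) img[i, j, ] <- cm[1, ]  # deepest blue
  roi <- matrix(TRUE, 2, 2)
  expect_equal(mean_gray(img, roi, "stiffness_index"), 255)
  white <- array(255L, c(2, 2, 3))
  expect_equal(mean_gray(white, roi, "luma"), 255)
})

test_that("pixel statistics agree with per-pixel loop oracles", {
  set.seed(101)
  cm <- elasto_colormap()
  bands <- default_band_table()
  for (k in 1:100) {
    h <- sample(4:20, 1); w <- sample(4:20, 1)
    img <- random_rgb_image(h, w)
    roi <- random_roi(h, w)
    hm <- to_hue_map(img)
    expect_identical(stiff_area_ratio(hm, roi), oracle_sar(hm, roi))
    expect_equal(mean_hue(hm, roi), oracle_mean_hue(hm, roi),
                 tolerance = 1e-12)
    masks <- colormap_band_masks(img)
    idx <- attr(masks, "index")
    expect_identical(idx, oracle_nearest_index(img, cm))
    expect_identical(
      suppressMessages(color_ratio(masks, roi, "blue", "green")),
      oracle_band_ratio(idx, roi, bands$blue, bands$green))
    expect_identical(mean_gray(img, roi, "stiffness_index"),
                     mean(255 - idx[roi]))
  }
})

test_that("pixel statistics are invariant under ROI permutation and upsampling", {
  set.seed(7)
  img <- random_rgb_image(16, 16)
  roi <- random_roi(16, 16)
  hm <- to_hue_map(img)
  # permuting ROI pixel values leaves SAR unchanged
  vals <- hm[roi]
  hm2 <- hm; hm2[roi] <- sample(vals)
  expect_equal(stiff_area_ratio(hm2, roi), stiff_area_ratio(hm, roi))
  # nearest-neighbour upsampling x3 leaves all statistics unchanged
  k <- 3
  up <- function(m) m[rep(seq_len(nrow(m)), each = k),
                      rep(seq_len(ncol(m)), each = k)]
  img_up <- array(0L, c(16 * k, 16 * k, 3))
  for (ch in 1:3) img_up[, , ch] <- up(img[, , ch])
  roi_up <- up(roi)
  hm_up <- to_hue_map(img_up)
  expect_equal(stiff_area_ratio(hm_up, roi_up),
               stiff_area_ratio(hm, roi), tolerance = 1e-12)
  expect_equal(mean_hue(hm_up, roi_up), mean_hue(hm, roi),
               tolerance = 1e-12)
  m1 <- colormap_band_masks(img); m2 <- colormap_band_masks(img_up)
  expect_equal(suppressMessages(color_ratio(m2, roi_up, "blue", "red")),
               suppressMessages(color_ratio(m1, roi, "blue", "red")),
               tolerance = 1e-12)
})

test_that("consensus grading uses majority then median, on final reads", {
  expect_identical(consensus_grade(c(4, 4, 2)), 4L)
  expect_identical(consensus_grade(c(2, 3, 5)), 3L)
  expect_identical(consensus_grade(c(5, 5, 5)), 5L)
  # matrix input: the last column (second read) is each rater's final
  reads <- rbind(c(1, 4), c(2, 4), c(3, 2))
  expect_identical(consensus_grade(reads), 4L)
  expect_error(consensus_grade(numeric(0)), "no rater scores")
  expect_error(consensus_grade(c(0, 3, 3)), "1-5")
})

test_that("dichotomized grade call is monotone in the consensus grade", {
  calls <- grade_call(1:5)
  expect_identical(calls, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(diff(calls) >= 0))
})
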