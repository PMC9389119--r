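#' Convert an RGB elastogram to a hue map on the 0-180 scale
#'
#' Standard RGB -> HSV hue, linearly rescaled so the full hue circle maps
#' to `[0, 180)` (the half-degree convention common in medical image
#' analysis). Achromatic pixels (R = G = B) are assigned hue 0 by
#' convention.
#'
#' @param image An `H x W x 3` array with 8-bit channel values in 0-255.
#' @return An `H x W` numeric matrix of hues in `[0, 180)`.
#' @export
#' @examples
#' px <- array(0, c(1, 1, 3)); px[1, 1, 3] <- 255
#' to_hue_map(px)  # pure blue -> 120
to_hue_map <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  rgb <- rbind(as.numeric(image[, , 1]),
               as.numeric(image[, , 2]),
               as.numeric(image[, , 3]))
  h <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1L, ]
  matrix(h * 180, nrow = dim(image)[1], ncol = dim(image)[2])
}

check_roi <- function(roi, dims = NULL) {
  stopifnot(is.matrix(roi))
  roi <- roi > 0
  if (!any(roi)) stop("ROI mask is empty: at least one pixel is required")
  if (!is.null(dims) && !all(dim(roi) == dims[1:2]))
    stop("ROI mask dimensions do not match the image")
  roi
}

#' Stiff area ratio (SAR)
#'
#' Fraction of ROI pixels whose hue falls in the stiff (blue) band. The
#' band is the closed interval `[145, 180]` on the 0-180 hue scale by
#' default and is configurable.
#'
#' @param hue_map Matrix of hues from [to_hue_map()].
#' @param roi Logical/binary matrix, same dimensions; the node region.
#' @param stiff_band Closed hue interval `c(lo, hi)` counted as stiff.
#' @return A proportion in `[0, 1]`.
#' @export
stiff_area_ratio <- function(hue_map, roi, stiff_band = c(145, 180)) {
  roi <- check_roi(roi, dim(hue_map))
  h <- hue_map[roi]
  mean(h >= stiff_band[1] & h <= stiff_band[2])
}

#' Mean hue over the ROI
#'
#' Arithmetic (non-circular) mean of pixel hue over the ROI, after
#' clamping values into `[0, 180]`. Circular averaging is deliberately not
#' used: all hues of interest live far from the wrap point under this
#' scale convention.
#'
#' @inheritParams stiff_area_ratio
#' @return Mean hue in `[0, 180]`.
#' @export
mean_hue <- function(hue_map, roi) {
  roi <- check_roi(roi, dim(hue_map))
  mean(pmin(pmax(hue_map[roi], 0), 180))
}

#' Blue/green/red band membership masks
#'
#' Assigns every pixel to its nearest entry of the elastography colormap
#' (Euclidean distance in RGB space, index 0 = deepest blue through 255 =
#' deepest red) and then to the color-density band whose closed interval
#' contains that index.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param band_table Named list of closed index intervals; see
#'   [default_band_table()]. Intervals must not overlap.
#' @param colormap 256 x 3 colormap matrix; see [elasto_colormap()].
#' @return List of logical `H x W` masks, one per band, plus the integer
#'   index matrix as attribute `"index"`.
#' @export
colormap_band_masks <- function(image, band_table = default_band_table(),
                                colormap = elasto_colormap()) {
  iv <- do.call(rbind, band_table)
  if (any(iv[, 1] > iv[, 2])) stop("band interval with lo > hi")
  o <- order(iv[, 1])
  if (nrow(iv) > 1 && any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
    stop("color-density bands overlap")
  idx <- nearest_colormap_index(image, colormap)
  masks <- lapply(band_table, function(b) idx >= b[1] & idx <= b[2])
  attr(masks, "index") <- idx
  masks
}

#' Band pixel-count ratio within the ROI
#'
#' Ratio of pixel counts of two color-density bands inside the ROI, e.g.
#' blue/green (B/G) or blue/red (B/R). A zero denominator count returns
#' `Inf` as a sentinel (with a message); a zero numerator returns 0.
#'
#' @param masks Band masks from [colormap_band_masks()].
#' @param roi ROI mask.
#' @param numerator,denominator Band names present in `masks`.
#' @return Nonnegative ratio (possibly `Inf`).
#' @export
color_ratio <- function(masks, roi, numerator = "blue",
                        denominator = "green") {
  roi <- check_roi(roi)
  num <- sum(masks[[numerator]] & roi)
  den <- sum(masks[[denominator]] & roi)
  if (den == 0L) {
    message("color_ratio: zero '", denominator,
            "' pixel count in ROI; returning Inf sentinel")
    return(Inf)
  }
  num / den
}

#' Mean gray value over the ROI
#'
#' Two conventions are offered. `"stiffness_index"` (default) remaps the
#' nearest-colormap index so that the deepest blue (hardest) scores 255
#' and the deepest red (softest) scores 0, making harder tissue score
#' higher. `"luma"` is the ordinary Rec.601 luminance
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param roi ROI mask.
#' @param mode `"stiffness_index"` or `"luma"`.
#' @param colormap Colormap used for the stiffness index.
#' @return Mean gray in `[0, 255]`.
#' @export
mean_gray <- function(image, roi, mode = c("stiffness_index", "luma"),
                      colormap = elasto_colormap()) {
  mode <- match.arg(mode)
  roi <- check_roi(roi, dim(image))
  if (mode == "luma") {
    g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(mean(g[roi]))
  }
  idx <- nearest_colormap_index(image, colormap)
  mean(255 - idx[roi])
}

#' Consensus elastography grading score
#'
#' Each rater's final score is their second (last) read. The consensus is
#' the majority of the rater-final scores; when all raters disagree, the
#' median is taken as the documented tie-break.
#'
#' @param scores Either a vector of per-rater final scores (1-5) or a
#'   matrix with one row per rater and one column per read (the last
#'   column is each rater's final score).
#' @return Integer consensus score in 1-5.
#' @export
#' @examples
#' consensus_grade(c(4, 4, 2))  # majority -> 4
#' consensus_grade(c(2, 3, 5))  # all differ -> median 3
consensus_grade <- function(scores) {
  if (is.matrix(scores)) scores <- scores[, ncol(scores)]
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no rater scores supplied")
  if (!all(scores %in% 1:5)) stop("grading scores must be integers 1-5")
  tab <- table(scores)
  if (max(tab) > 1L) {
    as.integer(names(tab)[which.max(tab)])
  } else {
    as.integer(stats::median(scores))
  }
}

#' Dichotomize a grading score
#'
#' Scores of 1-3 denote benign appearance, 4-5 malignant-suspicious; the
#' positive call is strict (`score > cutoff`).
#'
#' @param grade Integer score(s) 1-5.
#' @param cutoff Dichotomization threshold (default 3).
#' @return Logical; `TRUE` = malignant-suspicious.
#' @export
grade_call <- function(grade, cutoff = 3) {
  grade > cutoff
}

#' Quantify one elastogram
#'
#' Computes the full set of quantitative elastography indicators for a
#' node: stiff area ratio, blue/green and blue/red pixel-count ratios,
#' mean hue and mean gray value.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param roi ROI mask.
#' @param stiff_band Stiff hue band for SAR.
#' @param band_table Color-density bands for B/G and B/R.
#' @param gray_mode Mode passed to [mean_gray()].
#' @return One-row `data.frame` with columns `sar`, `bg_ratio`,
#'   `br_ratio`, `mean_hue`, `mean_gray`.
#' @export
quantify_elastogram <- function(image, roi, stiff_band = c(145, 180),
                                band_table = default_band_table(),
                                gray_mode = "stiffness_index") {
  roi <- check_roi(roi, dim(image))
  hmap <- to_hue_map(image)
  masks <- colormap_band_masks(image, band_table)
  idx <- attr(masks, "index")
  gray <- if (gray_mode == "stiffness_index") mean(255 - idx[roi])
          else mean_gray(image, roi, "luma")
  data.frame(
    sar = stiff_area_ratio(hmap, roi, stiff_band),
    bg_ratio = suppressMessages(color_ratio(masks, roi, "blue", "green")),
    br_ratio = suppressMessages(color_ratio(masks, roi, "blue", "red")),
    mean_hue = mean_hue(hmap, roi),
    mean_gray = gray
  )
}
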