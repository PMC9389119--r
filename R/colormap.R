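#' Elastography display colormap
#'
#' A 256-entry blue-to-red colormap standing in for the (proprietary)
#' ultrasound-host elastography palette. Index 0 is the deepest blue
#' (hardest tissue on the display convention), index 255 the deepest red
#' (softest). Entries interpolate linearly in HSV hue from 240 degrees
#' (blue) down to 0 degrees (red) at full saturation and value.
#'
#' Color-density band analyses (blue/green/red pixel counting) assign each
#' image pixel to its nearest entry of this map; see
#' [colormap_band_masks()].
#'
#' @return An integer matrix with 256 rows and columns `r`, `g`, `b`
#'   (0-255).
#' @export
#' @examples
#' cm <- elasto_colormap()
#' cm[1, ]    # deepest blue
#' cm[256, ]  # deepest red
elasto_colormap <- function() {
  idx <- 0:255
  deg <- 240 * (255 - idx) / 255
  rgb <- hue_deg_to_rgb(deg)
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Default color-density bands on the colormap index axis
#'
#' Blue is defined as colormap indices 0-49 (the color-density convention
#' for stiff pixels); the remaining axis is split into green (50-152) and
#' red (153-255).
#'
#' @return Named list of closed integer intervals `c(lo, hi)`.
#' @export
default_band_table <- function() {
  list(blue = c(0L, 49L), green = c(50L, 152L), red = c(153L, 255L))
}

# Vectorised hue (degrees, full 0-360 circle) -> 8-bit RGB at S = V = 1.
hue_deg_to_rgb <- function(deg) {
  deg <- deg %% 360
  hp <- deg / 60
  x <- 1 - abs(hp %% 2 - 1)
  sector <- pmin(floor(hp), 5)
  r <- g <- b <- numeric(length(deg))
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2
  s3 <- sector == 3; s4 <- sector == 4; s5 <- sector == 5
  r[s0] <- 1;     g[s0] <- x[s0]; b[s0] <- 0
  r[s1] <- x[s1]; g[s1] <- 1;     b[s1] <- 0
  r[s2] <- 0;     g[s2] <- 1;     b[s2] <- x[s2]
  r[s3] <- 0;     g[s3] <- x[s3]; b[s3] <- 1
  r[s4] <- x[s4]; g[s4] <- 0;     b[s4] <- 1
  r[s5] <- 1;     g[s5] <- 0;     b[s5] <- x[s5]
  cbind(as.integer(round(255 * r)),
        as.integer(round(255 * g)),
        as.integer(round(255 * b)))
}

# Nearest colormap index (0-based) for every pixel of an H x W x 3 image,
# by Euclidean distance in RGB space. Ties resolve to the lowest index.
nearest_colormap_index <- function(image, colormap = elasto_colormap()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  px <- cbind(as.numeric(image[, , 1]),
              as.numeric(image[, , 2]),
              as.numeric(image[, , 3]))
  cm <- colormap
  # argmin_k |p - c_k|^2 = argmax_k (2 p.c_k - |c_k|^2)
  score <- 2 * (px %*% t(cm))
  score <- sweep(score, 2L, rowSums(cm^2), "-")
  idx <- max.col(score, ties.method = "first") - 1L
  matrix(idx, nrow = dim(image)[1], ncol = dim(image)[2])
}
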