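#' Standardized uptake value map
#'
#' SUV = tissue concentration (MBq/g) / (injected dose (MBq) / body
#' weight (g)). Applied voxel-wise, so the result is dimensionless and
#' invariant under simultaneous scaling of dose and weight.
#'
#' @param activity Numeric array (any shape) of tissue activity
#'   concentration in MBq/g; all values must be nonnegative.
#' @param dose_mbq Injected dose in MBq (> 0).
#' @param weight_g Body weight in g (> 0).
#' @return Array of SUV values, same shape as `activity`.
#' @export
#' @examples
#' suv_map(0.01, dose_mbq = 370, weight_g = 74000)  # 2.0
suv_map <- function(activity, dose_mbq, weight_g) {
  if (!is.numeric(dose_mbq) || length(dose_mbq) != 1L || dose_mbq <= 0)
    stop("injected dose must be a single positive number")
  if (!is.numeric(weight_g) || length(weight_g) != 1L || weight_g <= 0)
    stop("body weight must be a single positive number")
  if (any(activity < 0)) stop("activity concentrations must be >= 0")
  activity / (dose_mbq / weight_g)
}

check_mask <- function(mask, suv) {
  mask <- mask > 0
  if (!identical(dim(mask), dim(suv)) || length(mask) != length(suv))
    stop("mask dimensions do not match the SUV grid")
  if (!any(mask)) stop("delineation mask is empty")
  mask
}

#' Maximum and mean SUV over a delineation
#'
#' @param suv SUV array from [suv_map()].
#' @param mask Binary delineation aligned to `suv`.
#' @return A single number.
#' @export
suv_max <- function(suv, mask) {
  mask <- check_mask(mask, suv)
  max(suv[mask])
}

#' @rdname suv_max
#' @export
suv_mean <- function(suv, mask) {
  mask <- check_mask(mask, suv)
  mean(suv[mask])
}

# Voxels qualifying for MTV: masked and at/above the SUV threshold
# (boundary values are included).
mtv_select <- function(suv, mask, threshold_mode, threshold_value) {
  mask <- check_mask(mask, suv)
  if (threshold_value < 0) stop("threshold_value must be >= 0")
  thr <- switch(threshold_mode,
    absolute = threshold_value,
    fraction_of_max = threshold_value * max(suv[mask]),
    stop("unknown threshold_mode: ", threshold_mode)
  )
  mask & suv >= thr
}

#' Metabolic tumor volume (MTV)
#'
#' Volume, in cubic centimeters, of delineated voxels whose SUV is at or
#' above a segmentation threshold. The default is an absolute SUV of 2.5
#' (the usual PET positivity criterion); `"fraction_of_max"` thresholds at
#' `threshold_value * SUVmax` instead.
#'
#' @param suv SUV array.
#' @param mask Binary delineation.
#' @param voxel_mm Voxel pitch `c(dx, dy, dz)` in mm.
#' @param threshold_mode `"absolute"` or `"fraction_of_max"`.
#' @param threshold_value Threshold (SUV units, or fraction of SUVmax).
#' @return Volume in cm^3.
#' @export
mtv <- function(suv, mask, voxel_mm, threshold_mode = "absolute",
                threshold_value = 2.5) {
  if (any(voxel_mm <= 0)) stop("voxel dimensions must be positive")
  sel <- mtv_select(suv, mask, threshold_mode, threshold_value)
  sum(sel) * prod(voxel_mm) / 1000
}

#' Total lesion glycolysis (TLG)
#'
#' TLG = SUVmean x MTV, with SUVmean computed over the MTV-qualifying
#' voxels so the identity holds by construction. When no voxel qualifies
#' (MTV = 0) the TLG is 0.
#'
#' @inheritParams mtv
#' @return TLG in SUV x cm^3.
#' @export
tlg <- function(suv, mask, voxel_mm, threshold_mode = "absolute",
                threshold_value = 2.5) {
  sel <- mtv_select(suv, mask, threshold_mode, threshold_value)
  if (!any(sel)) return(0)
  vol <- sum(sel) * prod(voxel_mm) / 1000
  mean(suv[sel]) * vol
}

#' CT short axis of a delineated node
#'
#' On the axial slice with the largest delineated area, the minimum
#' caliper (Feret) diameter of the region, in mm. Pixels are treated as
#' squares (their four corners enter the convex hull), so a rectangle
#' measures its exact short side and a circle its diameter to within one
#' pixel pitch.
#'
#' @param mask Binary array, either `nx x ny` (single slice) or
#'   `nx x ny x nz` (axial slices along the third axis).
#' @param voxel_mm Voxel pitch; the first two entries are the in-plane
#'   pitch.
#' @return Short axis in mm.
#' @export
short_axis <- function(mask, voxel_mm) {
  mask <- mask > 0
  if (any(voxel_mm <= 0)) stop("voxel dimensions must be positive")
  if (length(dim(mask)) == 3L) {
    areas <- apply(mask, 3L, sum)
    if (max(areas) == 0L) stop("delineation mask is empty")
    slice <- mask[, , which.max(areas)]
  } else {
    slice <- mask
    if (!any(slice)) stop("delineation mask is empty")
  }
  ij <- which(slice, arr.ind = TRUE)
  dx <- voxel_mm[1]; dy <- voxel_mm[2]
  cx <- ij[, 1] * dx; cy <- ij[, 2] * dy
  # four corners of each pixel square
  pts <- cbind(c(cx - dx / 2, cx - dx / 2, cx + dx / 2, cx + dx / 2),
               c(cy - dy / 2, cy + dy / 2, cy - dy / 2, cy + dy / 2))
  min_feret(pts)
}

# Minimum caliper width of a 2-D point set: the minimum over convex-hull
# edge directions of the projection extent onto the edge normal.
min_feret <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 2L) return(0)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- hp %*% nrm
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

#' Quantify one PET volume of interest
#'
#' @param voi A list with elements `activity` (3-D array, MBq/g), `mask`
#'   (binary array, same shape), `voxel_mm`, `dose_mbq`, `weight_g` --
#'   as produced by [render_pet_voi()] or read from disk.
#' @param threshold_mode,threshold_value MTV segmentation settings.
#' @return One-row `data.frame` with `suv_max`, `suv_mean` (whole
#'   delineation), `suv_mean_mtv` (over MTV voxels), `mtv_cm3`, `tlg`,
#'   `short_axis_mm`.
#' @export
quantify_pet <- function(voi, threshold_mode = "absolute",
                         threshold_value = 2.5) {
  suv <- suv_map(voi$activity, voi$dose_mbq, voi$weight_g)
  sel <- mtv_select(suv, voi$mask, threshold_mode, threshold_value)
  vol <- sum(sel) * prod(voi$voxel_mm) / 1000
  data.frame(
    suv_max = suv_max(suv, voi$mask),
    suv_mean = suv_mean(suv, voi$mask),
    suv_mean_mtv = if (any(sel)) mean(suv[sel]) else NA_real_,
    mtv_cm3 = vol,
    tlg = if (any(sel)) mean(suv[sel]) * vol else 0,
    short_axis_mm = short_axis(voi$mask, voi$voxel_mm)
  )
}
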