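# Reference cohort composition (model-group diagnosis and station
# counts) used for default sampling proportions.
MALIGNANT_DIAGNOSES <- c(
  adenocarcinoma = 42, squamous_carcinoma = 18,
  nsclc_not_otherwise_specified = 6, small_cell_lung_cancer = 16,
  neuroendocrine_tumor_nos = 3, lymphoepithelioma_like_carcinoma = 1,
  lung_cancer_unknown_type = 2, metastatic_non_lung = 4
)
BENIGN_DIAGNOSES <- c(
  nonspecific_lymphadenitis = 52, sarcoidosis = 7, tuberculosis = 2,
  ntm_infection = 1
)
STATION_COUNTS <- c(
  "2R" = 1, "3P" = 1, "4L" = 12, "4R" = 47, "7" = 51,
  "10L" = 3, "10R" = 6, "11L" = 16, "11Ri" = 9, "11Rs" = 8
)

#' Is a diagnosis label malignant?
#' @param diagnosis Character vector of diagnosis labels.
#' @return Logical vector.
#' @export
is_malignant_diagnosis <- function(diagnosis) {
  diagnosis %in% c(names(MALIGNANT_DIAGNOSES), "lymphoma")
}

#' Cohort simulation configuration
#'
#' Defaults encode the class-conditional feature distributions of the
#' reference cohort: node mean hue is normal with mean 145.00 (sd 16.16)
#' for malignant and 119.66 (sd 17.74) for benign nodes; SUVmax is normal
#' with mean 11.00 (sd 5.36) for nodes with short axis > 1 cm and 6.01
#' (sd 3.53) for <= 1 cm, overridden for the granulomatous benign
#' subgroups sarcoidosis (13.53, sd 8.37) and tuberculosis (17.57,
#' sd 10.89), which are the classic PET false-positive confounders.
#' Draws are clamped to the physical ranges (`[0, 180]` hue, SUV >= 0).
#'
#' @param n_nodes Number of lymph nodes.
#' @param malignant_fraction Proportion of malignant nodes.
#' @param diagnosis_mix Named probability vector over diagnosis labels;
#'   defaults to the reference composition (e.g. adenocarcinoma 42/154).
#' @param hue_params List with `malignant`/`benign` `c(mean, sd)` of
#'   latent node mean hue (0-180 scale).
#' @param suvmax_params List with `large_node`/`small_node`/`sarcoidosis`/
#'   `tuberculosis` `c(mean, sd)` of latent SUVmax.
#' @param grade_probs List with `malignant`/`benign` probability vectors
#'   over grading scores 1-5.
#' @param rater_error Probability that a rater's single read perturbs the
#'   latent grade by one level.
#' @param short_axis_lognorm `c(meanlog, sdlog)` of the short-axis
#'   distribution in mm.
#' @param stratified If `TRUE`, class and diagnosis counts are fixed
#'   quotas (largest-remainder rounding) rather than random draws.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_nodes = 154,
                          malignant_fraction = 92 / 154,
                          diagnosis_mix = NULL,
                          hue_params = list(malignant = c(145.00, 16.16),
                                            benign = c(119.66, 17.74)),
                          suvmax_params = list(
                            large_node = c(11.00, 5.36),
                            small_node = c(6.01, 3.53),
                            sarcoidosis = c(13.53, 8.37),
                            tuberculosis = c(17.57, 10.89)),
                          grade_probs = list(
                            malignant = c(0.02, 0.05, 0.12, 0.36, 0.45),
                            benign = c(0.30, 0.35, 0.22, 0.10, 0.03)),
                          rater_error = 0.05,
                          short_axis_lognorm = c(log(13), 0.35),
                          stratified = TRUE,
                          seed = 1L) {
  if (is.null(diagnosis_mix)) {
    counts <- c(MALIGNANT_DIAGNOSES, BENIGN_DIAGNOSES)
    diagnosis_mix <- counts / sum(counts)
  }
  if (n_nodes < 0 || n_nodes != round(n_nodes))
    stop("n_nodes must be a nonnegative integer")
  if (malignant_fraction < 0 || malignant_fraction > 1)
    stop("malignant_fraction must be in [0, 1]")
  if (abs(sum(diagnosis_mix) - 1) > 1e-9)
    stop("diagnosis_mix probabilities must sum to 1")
  if (any(diagnosis_mix < 0)) stop("diagnosis_mix probabilities must be >= 0")
  sds <- c(vapply(hue_params, `[`, numeric(1), 2),
           vapply(suvmax_params, `[`, numeric(1), 2))
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  for (p in grade_probs)
    if (length(p) != 5L || abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("grade_probs must be length-5 probability vectors")
  structure(list(
    n_nodes = as.integer(n_nodes),
    malignant_fraction = malignant_fraction,
    diagnosis_mix = diagnosis_mix,
    hue_params = hue_params, suvmax_params = suvmax_params,
    grade_probs = grade_probs, rater_error = rater_error,
    short_axis_lognorm = short_axis_lognorm,
    stratified = isTRUE(stratified), seed = as.integer(seed)
  ), class = "cohort_config")
}

# Largest-remainder quota: integer counts summing to n, proportional to p.
quota_counts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic lymph-node cohort
#'
#' Draws per-node class labels, diagnoses, stations, short axes and
#' latent imaging features (mean hue, SUVmax, grading score) from the
#' configured class-conditional distributions, plus a 3-rater x 2-read
#' grading panel. Deterministic given the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return List of class `ln_cohort` with elements `nodes` (one row per
#'   node) and `raters` (long table: node_id, rater, read, score).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  empty <- data.frame(
    node_id = character(), patient_id = character(), station = character(),
    short_axis_mm = numeric(), true_class = character(),
    diagnosis = character(), latent_mean_hue = numeric(),
    latent_suvmax = numeric(), latent_grade = integer(),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(nodes = empty,
                          raters = data.frame(node_id = character(),
                                              rater = integer(),
                                              read = integer(),
                                              score = integer()),
                          config = config), class = "ln_cohort"))
  }
  mix <- config$diagnosis_mix
  mal_labels <- names(mix)[is_malignant_diagnosis(names(mix))]
  ben_labels <- setdiff(names(mix), mal_labels)
  if (config$stratified) {
    n_mal <- round(n * config$malignant_fraction)
    n_ben <- n - n_mal
    diag_mal <- rep(mal_labels, quota_counts(n_mal, mix[mal_labels]))
    diag_ben <- rep(ben_labels, quota_counts(n_ben, mix[ben_labels]))
    diagnosis <- c(diag_mal, diag_ben)
  } else {
    is_mal <- stats::runif(n) < config$malignant_fraction
    diagnosis <- character(n)
    if (any(is_mal))
      diagnosis[is_mal] <- sample(mal_labels, sum(is_mal), replace = TRUE,
                                  prob = mix[mal_labels])
    if (any(!is_mal))
      diagnosis[!is_mal] <- sample(ben_labels, sum(!is_mal), replace = TRUE,
                                   prob = mix[ben_labels])
  }
  true_class <- ifelse(is_malignant_diagnosis(diagnosis),
                       "malignant", "benign")
  station <- sample(names(STATION_COUNTS), n, replace = TRUE,
                    prob = STATION_COUNTS)
  short_axis_mm <- pmin(pmax(stats::rlnorm(
    n, config$short_axis_lognorm[1], config$short_axis_lognorm[2]), 4), 40)

  hue <- numeric(n); suv <- numeric(n); grade <- integer(n)
  mal <- true_class == "malignant"
  hp <- config$hue_params
  hue[mal] <- rnorm_clamped(sum(mal), hp$malignant[1], hp$malignant[2],
                            0, 180)
  hue[!mal] <- rnorm_clamped(sum(!mal), hp$benign[1], hp$benign[2], 0, 180)
  sp <- config$suvmax_params
  grp <- ifelse(diagnosis == "sarcoidosis", "sarcoidosis",
         ifelse(diagnosis == "tuberculosis", "tuberculosis",
         ifelse(short_axis_mm > 10, "large_node", "small_node")))
  for (g in unique(grp)) {
    sel <- grp == g
    suv[sel] <- rnorm_clamped(sum(sel), sp[[g]][1], sp[[g]][2], 0, Inf)
  }
  gp <- config$grade_probs
  grade[mal] <- sample(1:5, sum(mal), replace = TRUE, prob = gp$malignant)
  grade[!mal] <- sample(1:5, sum(!mal), replace = TRUE, prob = gp$benign)

  # roughly 0.88 patients per node: some patients contribute several nodes
  n_pat <- max(1L, ceiling(n * 0.875))
  patient_id <- sprintf("P%04d", sample(seq_len(n_pat), n, replace = TRUE))

  ord <- sample.int(n)  # interleave classes
  nodes <- data.frame(
    node_id = sprintf("LN%04d", seq_len(n)),
    patient_id = patient_id[ord], station = station[ord],
    short_axis_mm = round(short_axis_mm[ord], 2),
    true_class = true_class[ord], diagnosis = diagnosis[ord],
    latent_mean_hue = hue[ord], latent_suvmax = suv[ord],
    latent_grade = grade[ord], stringsAsFactors = FALSE)

  raters <- expand.grid(node_id = nodes$node_id, rater = 1:3, read = 1:2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  raters <- raters[order(raters$node_id, raters$rater, raters$read), ]
  base <- nodes$latent_grade[match(raters$node_id, nodes$node_id)]
  flip <- stats::runif(nrow(raters)) < config$rater_error
  dir <- sample(c(-1L, 1L), nrow(raters), replace = TRUE)
  raters$score <- pmin(pmax(base + ifelse(flip, dir, 0L), 1L), 5L)
  rownames(raters) <- NULL
  structure(list(nodes = nodes, raters = raters, config = config),
            class = "ln_cohort")
}

#' @export
print.ln_cohort <- function(x, ...) {
  n <- nrow(x$nodes)
  nm <- sum(x$nodes$true_class == "malignant")
  cat(sprintf("Synthetic lymph-node cohort: %d nodes (%d malignant, %d benign)\n",
              n, nm, n - nm))
  invisible(x)
}

#' Consensus grades for a cohort's rater panel
#'
#' Applies [consensus_grade()] per node: each rater's final score is the
#' second read; consensus is majority, else median.
#'
#' @param raters Long rater table from [generate_cohort()].
#' @return `data.frame` with `node_id` and `grade`.
#' @export
panel_consensus <- function(raters) {
  finals <- raters[raters$read == max(raters$read), ]
  ids <- unique(finals$node_id)
  grade <- vapply(ids, function(id)
    consensus_grade(finals$score[finals$node_id == id]), integer(1))
  data.frame(node_id = ids, grade = grade, stringsAsFactors = FALSE)
}

#' Render a synthetic elastogram for one node
#'
#' Produces an RGB still with an elliptical node ROI whose pixel hues are
#' sampled so that the ROI mean hue matches the node's latent mean hue to
#' within +/- 1 hue unit, and -- when `target_sar` is given -- so that the
#' fraction of ROI pixels in the stiff band matches `target_sar` to
#' within +/- 0.02. Hue is converted to RGB with the standard HSV mapping
#' on the 0-180 half-circle scale, so [to_hue_map()] round-trips it.
#' Pixels outside the ROI are dark gray background.
#'
#' When `target_sar` and the latent mean hue are jointly infeasible (e.g.
#' `target_sar = 1` with a soft latent hue) the SAR constraint takes
#' precedence and the mean saturates.
#'
#' @param record One-row `data.frame` (or list) with `latent_mean_hue`.
#' @param width,height Frame size in pixels, both >= 32.
#' @param target_sar Optional stiff-area fraction in `[0, 1]`.
#' @param stiff_band Stiff hue band (closed, on the 0-180 scale).
#' @param hue_sd Pixel-level hue texture standard deviation.
#' @return List with `image` (`H x W x 3` integer array, 0-255) and
#'   `mask` (logical `H x W` ROI).
#' @export
render_elastogram <- function(record, width = 64, height = 64,
                              target_sar = NULL, stiff_band = c(145, 180),
                              hue_sd = 8) {
  if (width < 32 || height < 32) stop("frame must be at least 32 x 32")
  latent <- as.numeric(record$latent_mean_hue %||%
                         record[["latent_mean_hue"]])
  if (!is.finite(latent)) stop("record must carry latent_mean_hue")
  if (!is.null(target_sar) && (target_sar < 0 || target_sar > 1))
    stop("target_sar must be in [0, 1]")

  # elliptical ROI, ~49.5% of the frame (>= 25% required)
  xs <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height), nrow = height, ncol = width)
  a <- 0.45 * width; b <- 0.35 * height
  roi <- ((xs - (width + 1) / 2) / a)^2 + ((ys - (height + 1) / 2) / b)^2 <= 1
  n_roi <- sum(roi)

  clamp_iter <- function(h, target, lo, hi, iters = 8L) {
    for (k in seq_len(iters)) h <- pmin(pmax(h + (target - mean(h)), lo), hi)
    h
  }
  if (is.null(target_sar)) {
    # pixel hues stay strictly below the 180 wrap point: a pixel clamped
    # to exactly 180 would re-quantify as hue 0
    h <- clamp_iter(stats::rnorm(n_roi, latent, hue_sd), latent, 0, 179.5)
  } else {
    n_stiff <- round(target_sar * n_roi)
    lo_s <- stiff_band[1] + 1; hi_s <- stiff_band[2] - 1
    stiff <- clamp_iter(stats::rnorm(n_stiff, (lo_s + hi_s) / 2, hue_sd),
                        (lo_s + hi_s) / 2, lo_s, hi_s)
    n_soft <- n_roi - n_stiff
    if (n_soft > 0L) {
      m_soft <- (n_roi * latent - sum(stiff)) / n_soft
      soft <- clamp_iter(stats::rnorm(n_soft, m_soft, hue_sd), m_soft,
                         1, stiff_band[1] - 2)
    } else soft <- numeric(0)
    h <- c(stiff, soft)[sample.int(n_roi)]
  }

  img <- array(40L, dim = c(height, width, 3L))  # background gray
  rgb <- hue_deg_to_rgb(h * 2)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[roi] <- rgb[, ch]
    img[, , ch] <- plane
  }
  list(image = img, mask = roi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic PET volume of interest for one node
#'
#' Builds a voxel grid containing an ellipsoidal node delineation whose
#' in-plane short axis matches the record's `short_axis_mm` (within one
#' voxel pitch) and whose activity is chosen so that the computed SUVmax
#' equals the record's `latent_suvmax` exactly: the central voxel is the
#' deterministic peak at the latent SUV, the rest of the node sits at
#' half the peak, and background voxels at one tenth.
#'
#' @param record One-row `data.frame` (or list) with `latent_suvmax` and
#'   `short_axis_mm`.
#' @param voxel_mm Voxel pitch `c(dx, dy, dz)` in mm.
#' @param dose_mbq Injected dose in MBq.
#' @param weight_g Body weight in g.
#' @return List of class `pet_voi` with `activity`, `mask`, `voxel_mm`,
#'   `dose_mbq`, `weight_g`.
#' @export
render_pet_voi <- function(record, voxel_mm = c(2, 2, 2),
                           dose_mbq = 370, weight_g = 70000) {
  if (any(voxel_mm <= 0)) stop("voxel dimensions must be positive")
  if (dose_mbq <= 0 || weight_g <= 0)
    stop("dose and weight must be positive")
  s <- as.numeric(record$latent_suvmax %||% record[["latent_suvmax"]])
  sa <- as.numeric(record$short_axis_mm %||% record[["short_axis_mm"]])
  if (!is.finite(s) || !is.finite(sa) || sa <= 0)
    stop("record must carry latent_suvmax and a positive short_axis_mm")
  # ellipsoid: long in-plane axis 1.4 x short axis, z extent 1.2 x
  semi <- c(0.7 * sa, 0.5 * sa, 0.6 * sa)
  dims <- pmax(ceiling(2 * semi / voxel_mm) + 4L, 5L)
  ctr <- (dims + 1) / 2
  gx <- (seq_len(dims[1]) - ctr[1]) * voxel_mm[1]
  gy <- (seq_len(dims[2]) - ctr[2]) * voxel_mm[2]
  gz <- (seq_len(dims[3]) - ctr[3]) * voxel_mm[3]
  d2 <- outer(outer((gx / semi[1])^2, (gy / semi[2])^2, "+"),
              (gz / semi[3])^2, "+")
  mask <- d2 <= 1
  suv <- array(0.1 * s, dim = dims)
  suv[mask] <- 0.5 * s
  pk <- matrix(round(ctr), nrow = 1)
  suv[pk] <- s
  mask[pk] <- TRUE
  structure(list(activity = suv * (dose_mbq / weight_g), mask = mask,
                 voxel_mm = voxel_mm, dose_mbq = dose_mbq,
                 weight_g = weight_g),
            class = "pet_voi")
}
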