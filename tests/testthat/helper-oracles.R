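# Independent brute-force oracles used to cross-check the vectorised
# implementations. These deliberately use naive per-element loops.

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

random_roi <- function(h, w) {
  roi <- matrix(runif(h * w) < 0.5, h, w)
  if (!any(roi)) roi[1, 1] <- TRUE
  roi
}

# per-pixel loop: stiff-area ratio
oracle_sar <- function(hue_map, roi, band = c(145, 180)) {
  n_in <- 0L; n_roi <- 0L
  for (i in seq_len(nrow(hue_map))) for (j in seq_len(ncol(hue_map))) {
    if (roi[i, j]) {
      n_roi <- n_roi + 1L
      if (hue_map[i, j] >= band[1] && hue_map[i, j] <= band[2])
        n_in <- n_in + 1L
    }
  }
  n_in / n_roi
}

oracle_mean_hue <- function(hue_map, roi) {
  acc <- 0; n <- 0L
  for (i in seq_len(nrow(hue_map))) for (j in seq_len(ncol(hue_map))) {
    if (roi[i, j]) {
      acc <- acc + min(max(hue_map[i, j], 0), 180); n <- n + 1L
    }
  }
  acc / n
}

# per-pixel nearest colormap index by explicit distance loop
oracle_nearest_index <- function(image, colormap) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px <- image[i, j, ]
    d <- colSums((t(colormap) - as.numeric(px))^2)
    out[i, j] <- which.min(d) - 1L
  }
  out
}

oracle_band_ratio <- function(index, roi, num_band, den_band) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(index))) for (j in seq_len(ncol(index))) {
    if (roi[i, j]) {
      if (index[i, j] >= num_band[1] && index[i, j] <= num_band[2])
        num <- num + 1L
      if (index[i, j] >= den_band[1] && index[i, j] <= den_band[2])
        den <- den + 1L
    }
  }
  if (den == 0L) Inf else num / den
}

# Mann-Whitney pairwise-comparison AUC
oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# exhaustive threshold scan for the maximal Youden index
oracle_youden_scan <- function(scores, labels) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (t in cand) {
    sens <- mean(scores[labels] > t)
    spec <- mean(scores[!labels] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# two-sided Fisher p by enumeration of the hypergeometric distribution
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimum caliper width by scanning all point-pair directions
oracle_min_feret <- function(pts) {
  pts <- unique(pts)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  best <- Inf
  n <- nrow(hp)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hp %*% nrm
    best <- min(best, max(proj) - min(proj))
  }
  best
}

# random cohort of joint calls + truth for fusion property tests
random_calls_cohort <- function(n = 40) {
  truth <- c(rep("malignant", max(2, rbinom(1, n - 4, 0.5) + 2)))
  truth <- c(truth, rep("benign", n - length(truth)))
  data.frame(truth = truth,
             pet = runif(n) < runif(1),
             ela = runif(n) < runif(1),
             stringsAsFactors = FALSE)
}
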