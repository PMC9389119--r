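as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  l <- as.character(labels)
  if (!all(l %in% c("malignant", "benign")))
    stop("labels must be logical, 0/1, or 'malignant'/'benign'")
  l == "malignant"
}

#' Empirical ROC curve
#'
#' Thresholds are placed at midpoints between adjacent distinct score
#' values, with -Inf/+Inf anchors; the positive call is strict
#' (`score > threshold`), malignant being the positive class. The AUC is
#' the trapezoidal area, which for this construction equals the
#' Mann-Whitney concordance probability; a DeLong 95% confidence
#' interval is attached.
#'
#' @param scores Numeric per-node values (higher = more malignant).
#' @param labels Truth: logical, 0/1, or `"malignant"`/`"benign"`.
#' @return Object of class `roc_curve`: list with `points` (threshold,
#'   sensitivity, specificity), `auc`, `auc_ci95`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  if (!any(y) || all(y))
    stop("both classes must be present to form a ROC curve")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[y] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!y] <= t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  structure(list(
    points = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
    auc = auc,
    auc_ci95 = auc_ci_delong(scores, y),
    n_pos = sum(y), n_neg = sum(!y)
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives / %d negatives, AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$n_pos, x$n_neg, x$auc, x$auc_ci95[1], x$auc_ci95[2]))
  invisible(x)
}

#' DeLong 95% confidence interval for the AUC
#'
#' Placement-based (DeLong) variance estimate of the empirical AUC with a
#' normal-approximation 95% interval, truncated to `[0, 1]`. A degenerate
#' (zero) variance yields a point interval, with a message.
#'
#' @inheritParams roc_points
#' @return Numeric `c(lower, upper)`.
#' @export
auc_ci_delong <- function(scores, labels) {
  y <- as_binary_labels(labels)
  x1 <- scores[y]; x0 <- scores[!y]
  m <- length(x1); n <- length(x0)
  if (m < 2 || n < 2)
    stop("DeLong interval needs at least 2 observations per class")
  r_all <- rank(c(x1, x0))
  v10 <- (r_all[seq_len(m)] - rank(x1)) / n            # placements of positives
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(x0)) / m    # placements of negatives
  auc <- mean(v10)
  v <- stats::var(v10) / m + stats::var(v01) / n
  if (v <= 0) {
    message("auc_ci_delong: degenerate variance; returning point interval")
    return(c(auc, auc))
  }
  ci <- auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)
  pmin(pmax(ci, 0), 1)
}

#' Youden-index optimal cutoff
#'
#' Selects the threshold maximizing J = sensitivity + specificity - 1.
#' Ties are broken toward higher specificity (fewer false positives) and
#' then toward the lower cutoff, making the choice deterministic.
#'
#' @param curve A `roc_curve` from [roc_points()].
#' @return Object of class `cutoff_result`: list with `cutoff`,
#'   `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  j <- p$sensitivity + p$specificity - 1
  o <- order(-j, -p$specificity, p$threshold)
  best <- o[1]
  structure(list(cutoff = p$threshold[best], youden_j = j[best],
                 sensitivity = p$sensitivity[best],
                 specificity = p$specificity[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden cutoff %.4g (J = %.3f; sens %.3f, spec %.3f)\n",
              x$cutoff, x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' Univariate screening of dichotomized predictors
#'
#' For each binary predictor, forms the 2x2 table against the class label
#' and tests association with the chi-squared test (with continuity
#' correction) when all expected cell counts are >= 5, otherwise with
#' Fisher's exact test.
#'
#' @param calls `data.frame` (or named list) of logical predictor calls.
#' @param labels Truth labels.
#' @return `data.frame` with `feature`, `test`, `p_value`.
#' @export
univariate_screen <- function(calls, labels) {
  y <- as_binary_labels(labels)
  calls <- as.data.frame(calls)
  res <- lapply(names(calls), function(nm) {
    x <- calls[[nm]]
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("empty margin in 2x2 table for predictor '", nm, "'")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
      p <- stats::chisq.test(tab, correct = TRUE)$p.value
      test <- "chi-squared"
    } else {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    }
    data.frame(feature = nm, test = test, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multivariable logistic regression of dichotomized predictors
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`glm`, binomial family; tolerance 1e-8, up to 100 iterations) with
#' Wald z-tests per coefficient. Complete or quasi-complete separation is
#' detected (fitted probabilities numerically 0/1 or runaway
#' coefficients) and flagged rather than silently reported.
#'
#' @param predictors `data.frame` of logical/0-1 predictors; constant
#'   columns are rejected.
#' @param labels Truth labels.
#' @return Object of class `logistic_model`: list with `coefficients`
#'   (term, estimate, std_error, z, p_value), `converged`, `separation`.
#' @export
fit_logistic <- function(predictors, labels) {
  y <- as_binary_labels(labels)
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) > 0) {
    const <- vapply(predictors, function(x) length(unique(x)) < 2, logical(1))
    if (any(const))
      stop("constant predictor(s) excluded from the model: ",
           paste(names(predictors)[const], collapse = ", "))
  }
  dat <- cbind(predictors, .y = as.integer(y))
  fm <- if (ncol(predictors) == 0) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(names(predictors), collapse = "+")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (any(abs(stats::coef(fit)[-1]) > 15)) sep <- TRUE
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              std_error = sm[, 2], z = sm[, 3],
                              p_value = sm[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    converged = fit$converged, separation = sep
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model (IRLS)",
      if (!x$converged) "[DID NOT CONVERGE]" else "",
      if (x$separation) "[SEPARATION DETECTED]" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Cohen's kappa for paired ratings
#'
#' Unweighted kappa on an arbitrary (default 5-level) category set:
#' kappa = (po - pe) / (1 - pe), where po is the observed agreement
#' proportion and pe the chance agreement from the marginal
#' distributions.
#'
#' @param ratings_a,ratings_b Equal-length paired ratings.
#' @param categories Category levels (default: union of observed values).
#' @return Object of class `kappa_result`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b,
                         categories = sort(unique(c(ratings_a, ratings_b)))) {
  if (length(ratings_a) != length(ratings_b))
    stop("ratings must be paired (equal length)")
  if (length(ratings_a) == 0L) stop("empty ratings")
  a <- factor(ratings_a, levels = categories)
  b <- factor(ratings_b, levels = categories)
  if (anyNA(a) || anyNA(b)) stop("ratings outside the category set")
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  k <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(kappa = k, observed_agreement = po,
                 expected_agreement = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.3f (po %.3f, pe %.3f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}
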