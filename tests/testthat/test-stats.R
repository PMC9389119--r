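test_that("ROC handles separated, degenerate and random score sets", {
  expect_equal(suppressMessages(
    roc_points(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE)))$auc, 1)
  expect_equal(suppressMessages(
    roc_points(rep(2, 10), rep(c(TRUE, FALSE), 5)))$auc, 0.5)
  expect_error(roc_points(1:5, rep(TRUE, 5)), "both classes")
  set.seed(41)
  for (k in 1:100) {
    n <- sample(8:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    rc <- suppressMessages(roc_points(s, y))
    expect_equal(rc$auc, oracle_auc_mw(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (k in 1:10) {
    y <- c(TRUE, FALSE, runif(28) < 0.5)
    s <- rnorm(30)
    rc <- suppressMessages(roc_points(s, y))
    ref <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                     direction = "<")
    expect_equal(rc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(rc$auc_ci95, pmin(pmax(as.numeric(ci[c(1, 3)]), 0), 1),
                 tolerance = 1e-8)
  }
})

test_that("DeLong interval is symmetric under label swap and truncated", {
  set.seed(47)
  s <- rnorm(40); y <- c(TRUE, FALSE, runif(38) < 0.5)
  ci <- auc_ci_delong(s, y)
  ci_swap <- auc_ci_delong(-s, y)
  expect_equal(ci_swap, sort(1 - ci), tolerance = 1e-12)
  # perfect separation at large n: upper end truncates to 1
  s2 <- c(rnorm(50, 5), rnorm(50, -5)); y2 <- rep(c(TRUE, FALSE), each = 50)
  ci2 <- auc_ci_delong(s2, y2)
  expect_equal(ci2[2], 1)
  expect_message(auc_ci_delong(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
                 "degenerate")
})

test_that("Youden cutoff maximizes J with the documented tie-break", {
  rc <- suppressMessages(
    roc_points(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  cut <- youden_cutoff(rc)
  expect_equal(cut$cutoff, 2.5)
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$youden_j, cut$sensitivity + cut$specificity - 1,
               tolerance = 1e-12)
  rc0 <- suppressMessages(roc_points(rep(1, 6), rep(c(TRUE, FALSE), 3)))
  expect_equal(youden_cutoff(rc0)$youden_j, 0)
  set.seed(53)
  for (k in 1:50) {
    y <- c(TRUE, FALSE, runif(28) < 0.5)
    s <- round(rnorm(30), 1)
    rc <- suppressMessages(roc_points(s, y))
    expect_equal(youden_cutoff(rc)$youden_j, oracle_youden_scan(s, y),
                 tolerance = 1e-12)
  }
})

test_that("univariate screen picks chi-squared or Fisher appropriately", {
  # perfect association, big counts -> chi-squared, tiny p
  x <- rep(c(TRUE, FALSE), each = 50)
  y <- rep(c("malignant", "benign"), each = 50)
  res <- univariate_screen(data.frame(f = x), y)
  expect_equal(res$test, "chi-squared")
  expect_lt(res$p_value, 1e-10)
  # identical rows with small counts -> Fisher, p = 1
  x2 <- rep(c(TRUE, FALSE), 4)
  y2 <- rep(c("malignant", "benign"), each = 4)
  res2 <- univariate_screen(data.frame(f = x2), y2)
  expect_equal(res2$test, "fisher")
  expect_equal(res2$p_value, 1)
  # Fisher p equals the hypergeometric-tail enumeration oracle
  set.seed(59)
  for (k in 1:20) {
    x3 <- runif(12) < 0.5; y3 <- c(TRUE, FALSE, runif(10) < 0.5)
    x3[1:2] <- c(TRUE, FALSE)  # avoid empty predictor margins
    tab <- table(factor(x3, c(FALSE, TRUE)), factor(y3, c(FALSE, TRUE)))
    res3 <- univariate_screen(data.frame(f = x3), y3)
    if (res3$test == "fisher")
      expect_equal(res3$p_value, oracle_fisher_p(tab), tolerance = 1e-7)
  }
  expect_error(univariate_screen(data.frame(f = rep(TRUE, 6)),
                                 rep(c("malignant", "benign"), 3)),
               "empty margin")
})

test_that("logistic fit matches closed-form identities", {
  # single binary predictor: slope = log odds ratio of the 2x2 table
  set.seed(61)
  x <- runif(200) < 0.5
  y <- runif(200) < ifelse(x, 0.7, 0.3)
  fit <- fit_logistic(data.frame(x = x), y)
  tab <- table(x, y)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(fit$coefficients$estimate[2], lor, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # intercept-only: logit of prevalence
  fit0 <- fit_logistic(data.frame()[seq_along(y), , drop = FALSE], y)
  expect_equal(fit0$coefficients$estimate[1], qlogis(mean(y)),
               tolerance = 1e-8)
  # constant predictor is rejected
  expect_error(fit_logistic(data.frame(z = rep(TRUE, 200)), y),
               "constant predictor")
})

test_that("logistic fit recovers generating coefficients and flags separation", {
  set.seed(67)
  n <- 2000
  x1 <- runif(n) < 0.5; x2 <- runif(n) < 0.4
  eta <- -0.5 + 1.2 * x1 + 0.8 * x2
  y <- runif(n) < plogis(eta)
  fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  est <- fit$coefficients
  truth <- c(-0.5, 1.2, 0.8)
  for (i in 1:3)
    expect_lt(abs(est$estimate[i] - truth[i]), 3 * est$std_error[i])
  # complete separation is flagged, not silently reported
  ys <- rep(c(TRUE, FALSE), each = 20)
  xs <- ys
  fit_sep <- fit_logistic(data.frame(x = xs), ys)
  expect_true(fit_sep$separation)
})

test_that("Cohen's kappa matches the contingency-table formula", {
  expect_equal(cohens_kappa(1:5, 1:5)$kappa, 1)
  # po == pe -> kappa 0
  a <- rep(c(1, 2), each = 2); b <- c(1, 2, 1, 2)
  k0 <- cohens_kappa(a, b)
  expect_equal(k0$observed_agreement, k0$expected_agreement)
  expect_equal(k0$kappa, 0)
  set.seed(71)
  for (rep in 1:10) {
    a <- sample(1:5, 50, replace = TRUE)
    b <- ifelse(runif(50) < 0.7, a, sample(1:5, 50, replace = TRUE))
    k <- cohens_kappa(a, b, categories = 1:5)
    tab <- table(factor(a, 1:5), factor(b, 1:5))
    po <- sum(diag(tab)) / 50
    pe <- sum(rowSums(tab) * colSums(tab)) / 50^2
    expect_equal(k$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    # invariant under category relabeling
    perm <- sample(1:5)
    k2 <- cohens_kappa(perm[a], perm[b], categories = 1:5)
    expect_equal(k2$kappa, k$kappa, tolerance = 1e-12)
  }
  expect_error(cohens_kappa(1:3, 1:2), "paired")
  expect_error(cohens_kappa(integer(0), integer(0)), "empty")
})

test_that("kappa agrees with the e1071 cross-check", {
  skip_if_not_installed("e1071")
  set.seed(73)
  a <- sample(1:5, 80, replace = TRUE)
  b <- ifelse(runif(80) < 0.8, a, sample(1:5, 80, replace = TRUE))
  tab <- table(factor(a, 1:5), factor(b, 1:5))
  expect_equal(cohens_kappa(a, b, 1:5)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})
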