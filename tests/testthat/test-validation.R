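in_sample_confusion <- function(fit, feats) {
  predict_out_of_sample(fit, feats)
}

test_that("classifier separates strongly separated synthetic classes", {
  set.seed(101)
  feats <- sim_feature_table(300, shift = 3)
  fit <- suppressWarnings(fit_late_classifier(feats))  # separable limit
  expect_s3_class(fit, "lans_classifier")
  cm <- in_sample_confusion(fit, feats)
  expect_gt(cm$balanced_accuracy, 0.9)
})

test_that("permuted labels give chance-level balanced accuracy", {
  set.seed(102)
  feats <- sim_feature_table(400, shift = 2)
  feats$late_present <- sample(feats$late_present)
  fit <- fit_late_classifier(feats)
  cm <- in_sample_confusion(fit, feats)
  # in-sample optimism at 7 fitted parameters / 400 cases is small
  expect_lt(abs(cm$balanced_accuracy - 0.5), 0.12)
})

test_that("logistic coefficients match a hand-rolled IRLS oracle", {
  set.seed(103)
  for (n in c(120, 200, 500)) {
    feats <- sim_feature_table(n, shift = 1)
    fit <- fit_late_classifier(feats)
    X <- cbind(1, as.matrix(feats[, c("age", "cdr_sb",
                                      "hippocampal_volume_adj", "imt_ratio",
                                      "fdg_meta_roi_suvr", "tau_positive")]))
    beta <- oracle_irls_logistic(X, as.numeric(feats$late_present))
    expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-6)
  }
})

test_that("classifier refuses underpopulated classes and separation warns", {
  feats <- sim_feature_table(30)
  expect_error(fit_late_classifier(feats[1:12, ]), "insufficient")
  # a perfectly separating predictor triggers the separation warning
  set.seed(104)
  feats2 <- sim_feature_table(60, shift = 0)
  feats2$imt_ratio <- ifelse(feats2$late_present, 2, 1)
  expect_warning(fit_late_classifier(feats2), "separation")
})

test_that("out-of-sample prediction is consistent and threshold-sensitive", {
  set.seed(105)
  train <- sim_feature_table(240, shift = 1.5)
  fit <- fit_late_classifier(train)
  # applying the fit to its own training data reproduces in-sample calls
  p <- predict(fit, train)
  cm <- predict_out_of_sample(fit, train)
  expect_equal(cm$tp, sum(p > 0.5 & train$late_present))
  expect_equal(cm$tn, sum(p <= 0.5 & !train$late_present))
  # threshold 0 calls everyone positive
  cm0 <- predict_out_of_sample(fit, train, threshold = 0)
  expect_equal(cm0$sensitivity, 1)
  expect_equal(cm0$specificity, 0)
  expect_equal(cm0$balanced_accuracy, 0.5)
  # train and test balanced accuracy agree within sampling error when the
  # generating process is identical
  test <- sim_feature_table(240, shift = 1.5)
  cmt <- predict_out_of_sample(fit, test)
  expect_lt(abs(cmt$balanced_accuracy - cm$balanced_accuracy), 0.15)
  expect_error(predict_out_of_sample(fit, train[, 1:3]), "predictor")
})

test_that("confusion metrics satisfy their defining identities", {
  set.seed(106)
  for (i in 1:25) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0) tp <- 1
    if (tn + fp == 0) tn <- 1
    m <- confusion_metrics(tp, fp, tn, fn)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  }
  perfect <- confusion_metrics(10, 0, 12, 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_error(confusion_metrics(0, 5, 5, 0), "both classes")
})

test_that("likelihood distribution reproduces hand-computed chi-square", {
  lk <- rep(rep(c("LOW", "MODERATE", "HIGH"), 2), c(20, 10, 5, 8, 12, 15))
  grp <- rep(c("ADNC", "LATE"), c(35, 35))
  d <- likelihood_distribution(likelihood_factor_vec(lk), grp)
  tab <- rbind(c(20, 10, 5), c(8, 12, 15))
  expect_equal(unname(d$omnibus$statistic), oracle_chisq(tab),
               tolerance = 1e-10)
  expect_equal(as.vector(d$counts), as.vector(tab))
  # row percentages within group
  expect_equal(unname(d$row_pct["ADNC", "LOW"]), 100 * 20 / 35)
})

test_that("extreme 2x2 separation is overwhelmingly significant", {
  lk <- rep(c("LOW", "HIGH", "LOW", "HIGH"), c(10, 0, 0, 10))
  grp <- rep(c("A", "B"), each = 10)
  d <- likelihood_distribution(likelihood_factor_vec(lk), grp)
  expect_lt(d$omnibus$p.value, 0.001)
  expect_false(is.null(d$posthoc))
})

test_that("identical category distributions are rarely flagged", {
  set.seed(107)
  pvals <- replicate(40, {
    lk <- sample(c("LOW", "MODERATE", "HIGH"), 120, replace = TRUE)
    grp <- rep(c("A", "B"), 60)
    likelihood_distribution(likelihood_factor_vec(lk),
                            grp)$omnibus$p.value
  })
  # null p-values: about alpha of them fall below alpha
  expect_lte(sum(pvals < 0.05), 7)
  expect_gt(mean(pvals), 0.3)
})

test_that("category mix under configured rates matches exact enumeration", {
  # independence mode: category probabilities enumerate over 2^6 weighted
  # feature combinations
  cfg <- sim_config(group_sizes = c(ADNC = 20000), latent_rho = 0,
                    seed = 301)
  p <- cfg$feature_rates$ADNC
  probs <- c(p[["age"]], p[["mild"]], p[["atrophy"]],
             p[["limbic"]], p[["no_neocortical"]], p[["low_tau"]])
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), 6))
  enum <- c(LOW = 0, MODERATE = 0, HIGH = 0, HIGHEST = 0)
  for (i in seq_len(nrow(combos))) {
    on <- unlist(combos[i, ])
    w <- prod(ifelse(on, probs, 1 - probs))
    cat_i <- oracle_likelihood(TRUE, sum(on[1:3]), sum(on[4:6]), 3)
    enum[cat_i] <- enum[cat_i] + w
  }
  expect_equal(sum(enum), 1, tolerance = 1e-12)
  # low likelihood is the plurality outcome for the ADNC profile
  expect_identical(names(which.max(enum)), "LOW")

  tt <- truth_table(generate_cohort(cfg, trajectories = FALSE))
  emp_cat <- vapply(seq_len(nrow(tt)), function(i) {
    oracle_likelihood(TRUE,
                      tt$age_met[i] + tt$mild_met[i] + tt$atrophy_met[i],
                      tt$limbic_met[i] + tt$no_neocortical_met[i] +
                        tt$low_tau_met[i], 3)
  }, character(1))
  emp <- table(factor(emp_cat, levels = names(enum))) / nrow(tt)
  for (lv in names(enum)) {
    expect_lt(abs(emp[[lv]] - enum[[lv]]), 0.02)
  }
})

test_that("trajectory model recovers known group slope differences", {
  set.seed(108)
  recs <- c(sim_traj_group("A", 50, slope = 1.0),
            sim_traj_group("B", 50, slope = 1.5))
  grouping <- setNames(rep(c("A", "B"), each = 50),
                       vapply(recs, `[[`, character(1), "patient_id"))
  fit <- suppressMessages(suppressWarnings(
    fit_trajectory_model(recs, grouping, reference = "A")))
  inter <- fit$interactions
  expect_equal(nrow(inter), 1L)
  expect_lt(abs(inter$estimate - 0.5), 3 * inter$se)

  # noiseless linear data: exact recovery
  recs0 <- c(sim_traj_group("A", 15, slope = 1.0, noise = 0, slope_sd = 0),
             sim_traj_group("B", 15, slope = 1.5, noise = 0, slope_sd = 0))
  g0 <- setNames(rep(c("A", "B"), each = 15),
                 vapply(recs0, `[[`, character(1), "patient_id"))
  fit0 <- suppressMessages(suppressWarnings(
    fit_trajectory_model(recs0, g0, reference = "A", random_slope = FALSE)))
  expect_equal(fit0$interactions$estimate, 0.5, tolerance = 1e-6)
})

test_that("equal generating slopes are rarely declared different", {
  set.seed(109)
  hits <- replicate(30, {
    recs <- c(sim_traj_group("A", 40, slope = 1.2),
              sim_traj_group("B", 40, slope = 1.2))
    g <- setNames(rep(c("A", "B"), each = 40),
                  vapply(recs, `[[`, character(1), "patient_id"))
    fit <- suppressMessages(suppressWarnings(
      fit_trajectory_model(recs, g, reference = "A")))
    abs(fit$interactions$z[1]) > 1.96
  })
  expect_lte(sum(hits), 7)  # near-nominal type-I behaviour
})
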