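# Validation machinery: logistic classification of LATE-NC presence from
# the operationalized features, confusion metrics, likelihood-by-pathology
# distribution tests, and the time x group mixed model of CDR-SB.

#' Assemble the classifier feature table for a cohort
#'
#' One row per patient with the operationalized predictors: age at
#' examination, baseline CDR-SB, adjusted hippocampal volume at the last
#' MRI, FDG-PET IMT ratio, FDG-PET meta-ROI SUVR (continuous) and tau
#' positivity (binary, from the tau-biomarker cascade: positive when the
#' low-neocortical-tau feature is not met, NA when no tau workup is
#' available), plus \code{late_present} (LATE-NC or comorbid ADNC/LATE-NC
#' at autopsy; NA for other/unknown groups).
#'
#' @param records a \code{lans_cohort}.
#' @param cfg a \code{lans_config}.
#' @return Data frame with columns \code{patient_id}, \code{age},
#'   \code{cdr_sb}, \code{hippocampal_volume_adj}, \code{imt_ratio},
#'   \code{fdg_meta_roi_suvr}, \code{tau_positive}, \code{late_present}.
#' @export
classifier_features <- function(records, cfg) {
  rows <- lapply(records, function(r) {
    v <- r$visits
    vol <- NA_real_
    ok <- !is.na(v$hippocampal_volume_adj)
    if (any(ok)) vol <- v$hippocampal_volume_adj[max(which(ok))]
    tau <- evaluate_tau_cascade(r$imaging, r$fluids, cfg)
    tau_positive <- switch(tau$status, MET = 0, NOT_MET = 1, NA)
    late <- if (r$pathology_group %in% c("LATE", "ADNC_LATE")) TRUE
            else if (r$pathology_group == "ADNC") FALSE else NA
    data.frame(patient_id = r$patient_id,
               age = r$age_first_visit,
               cdr_sb = if (nrow(v)) v$cdr_sb[1L] else NA_real_,
               hippocampal_volume_adj = vol,
               imt_ratio = imt_from_panel(r$imaging, cfg),
               fdg_meta_roi_suvr = scalar_or_na(r$imaging$fdg_meta_roi_suvr),
               tau_positive = tau_positive,
               late_present = late,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

CLASSIFIER_PREDICTORS <- c("age", "cdr_sb", "hippocampal_volume_adj",
                           "imt_ratio", "fdg_meta_roi_suvr", "tau_positive")

#' Logistic classifier of LATE-NC presence
#'
#' Maximum-likelihood logistic regression of LATE-NC presence (pure LATE-NC
#' or comorbid ADNC/LATE-NC, versus ADNC) on the operationalized features.
#' Only tau positivity enters as categorical; the other predictors are
#' continuous. Fit on complete cases only, mirroring the reduced
#' denominators of biomarker availability.
#'
#' @param features table from \code{\link{classifier_features}} (or any data
#'   frame containing the predictor columns).
#' @param labels logical LATE-NC-present labels; defaults to
#'   \code{features$late_present}.
#' @param min_per_class minimum complete cases per class (default 10).
#' @return Object of class \code{lans_classifier} wrapping the \code{glm}
#'   fit, with \code{coefficients}, \code{se}, \code{n_complete_cases},
#'   \code{separation} flag.
#' @export
fit_late_classifier <- function(features, labels = features$late_present,
                                min_per_class = 10L) {
  dat <- features[, CLASSIFIER_PREDICTORS, drop = FALSE]
  dat$late <- as.logical(labels)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_pos <- sum(dat$late)
  n_neg <- sum(!dat$late)
  if (n_pos < min_per_class || n_neg < min_per_class) {
    stop("insufficient complete cases per class (", n_pos, " positive, ",
         n_neg, " negative; need >= ", min_per_class, " each)",
         call. = FALSE)
  }
  form <- stats::as.formula(paste("late ~",
                                  paste(CLASSIFIER_PREDICTORS,
                                        collapse = " + ")))
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  p <- stats::fitted(fit)
  separation <- any(p > 1 - 1e-8) || any(p < 1e-8) || !fit$converged
  if (separation) {
    warning("possible (quasi-)separation in logistic fit; coefficients may ",
            "be unstable", call. = FALSE)
  }
  structure(list(model = fit,
                 coefficients = stats::coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 n_complete_cases = nrow(dat),
                 n_positive = n_pos, n_negative = n_neg,
                 separation = separation),
            class = "lans_classifier")
}

#' @export
print.lans_classifier <- function(x, ...) {
  cat(sprintf("Logistic LATE-NC classifier (%d complete cases: %d+/%d-%s)\n",
              x$n_complete_cases, x$n_positive, x$n_negative,
              if (x$separation) "; separation warning" else ""))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.lans_classifier <- function(object, ...) object$coefficients

#' @export
predict.lans_classifier <- function(object, newdata, type = "response", ...) {
  stats::predict(object$model, newdata = newdata, type = type, ...)
}

#' Out-of-sample prediction and confusion metrics
#'
#' Applies a fitted classifier to a feature table (typically an external
#' cohort), calls LATE-NC present when the predicted probability exceeds
#' the threshold, and tabulates the confusion against the labels. Rows with
#' incomplete predictors or missing labels are dropped (complete-case
#' evaluation).
#'
#' @param fit a \code{lans_classifier}.
#' @param features feature table containing the predictor columns.
#' @param labels logical labels; defaults to \code{features$late_present}.
#' @param threshold probability cut for calling LATE-NC (default 0.5).
#' @return A \code{lans_confusion} object (see
#'   \code{\link{confusion_metrics}}).
#' @export
predict_out_of_sample <- function(fit, features,
                                  labels = features$late_present,
                                  threshold = 0.5) {
  stopifnot(inherits(fit, "lans_classifier"))
  missing_cols <- setdiff(CLASSIFIER_PREDICTORS, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- features[, CLASSIFIER_PREDICTORS, drop = FALSE]
  dat$late <- as.logical(labels)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (!nrow(dat)) stop("no complete cases to evaluate", call. = FALSE)
  p <- predict(fit, dat)
  called <- p > threshold
  confusion_metrics(tp = sum(called & dat$late),
                    fp = sum(called & !dat$late),
                    tn = sum(!called & !dat$late),
                    fn = sum(!called & dat$late))
}

#' Confusion metrics from counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), balanced
#' accuracy = their unweighted mean. Percentages print to one decimal.
#'
#' @param tp,fp,tn,fn non-negative integer counts; both classes must be
#'   represented (TP + FN > 0 and TN + FP > 0).
#' @return Object of class \code{lans_confusion} with the counts and
#'   \code{sensitivity}, \code{specificity}, \code{balanced_accuracy}
#'   (proportions in [0, 1]).
#' @examples
#' m <- confusion_metrics(tp = 786, fn = 214, tn = 706, fp = 294)
#' round(100 * m$balanced_accuracy, 1)  # 74.6
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("both classes must be represented (tp+fn > 0 and tn+fp > 0)",
         call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2),
            class = "lans_confusion")
}

#' @export
print.lans_confusion <- function(x, ...) {
  cat(sprintf("Confusion: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, balanced accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$balanced_accuracy))
  invisible(x)
}

#' Distribution of likelihoods across pathology groups
#'
#' Builds the contingency table of LANS likelihood categories (highest and
#' high collapsed into one bin) against autopsy groups, with row and column
#' percentages, an omnibus chi-square test, and pairwise two-proportion
#' post hoc comparisons (within each likelihood bin, between each pair of
#' groups) run only when the omnibus test is significant.
#'
#' @param likelihoods a \code{lans_likelihood_table} or factor of
#'   categories.
#' @param groups pathology group per patient; defaults to the table's
#'   \code{pathology_group}.
#' @param alpha omnibus significance level gating the post hoc tests
#'   (default 0.05).
#' @param p_adjust multiplicity correction for the post hoc p-values
#'   (\code{"none"}, the default, reports raw pairwise p-values;
#'   \code{"holm"} etc. as in \code{\link[stats]{p.adjust}}).
#' @return Object of class \code{lans_distribution}: \code{counts},
#'   \code{row_pct} (within group), \code{col_pct} (within likelihood bin),
#'   \code{omnibus} (htest), \code{posthoc} (data frame or NULL).
#' @export
likelihood_distribution <- function(likelihoods,
                                    groups = likelihoods$pathology_group,
                                    alpha = 0.05, p_adjust = "none") {
  cat_raw <- if (is.data.frame(likelihoods)) likelihoods$likelihood
             else likelihoods
  cat_chr <- as.character(cat_raw)
  keep <- cat_chr != "NOT_LANS" & !is.na(cat_chr) & !is.na(groups)
  if (sum(!keep & !is.na(cat_chr)) > 0 && any(cat_chr == "NOT_LANS",
                                              na.rm = TRUE)) {
    message("dropping ", sum(cat_chr == "NOT_LANS", na.rm = TRUE),
            " patient(s) not meeting core features")
  }
  cat_chr <- cat_chr[keep]
  grp <- as.character(groups)[keep]
  bin <- factor(ifelse(cat_chr %in% c("HIGH", "HIGHEST"), "HIGH_HIGHEST",
                       cat_chr),
                levels = c("LOW", "MODERATE", "HIGH_HIGHEST"))
  grp <- factor(grp)
  if (nlevels(grp) < 2L || length(unique(bin)) < 1L) {
    stop("need >= 2 pathology groups with classified patients",
         call. = FALSE)
  }
  counts <- table(group = grp, likelihood = bin)
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]  # drop empty bins
  if (any(rowSums(counts) == 0L) || ncol(counts) < 2L) {
    stop("degenerate contingency table", call. = FALSE)
  }
  omnibus <- suppressWarnings(stats::chisq.test(counts))
  posthoc <- NULL
  if (is.finite(omnibus$p.value) && omnibus$p.value < alpha) {
    pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
    rows <- list()
    for (lev in colnames(counts)) {
      for (pr in pairs) {
        x <- counts[pr, lev]
        n <- rowSums(counts)[pr]
        pt <- suppressWarnings(stats::prop.test(x, n))
        rows[[length(rows) + 1L]] <- data.frame(
          likelihood = lev, group1 = pr[1L], group2 = pr[2L],
          prop1 = unname(x[1L] / n[1L]), prop2 = unname(x[2L] / n[2L]),
          p_value = pt$p.value, stringsAsFactors = FALSE)
      }
    }
    posthoc <- do.call(rbind, rows)
    posthoc$p_value <- stats::p.adjust(posthoc$p_value, method = p_adjust)
  }
  structure(list(counts = counts,
                 row_pct = 100 * prop.table(counts, 1),
                 col_pct = 100 * prop.table(counts, 2),
                 omnibus = omnibus,
                 posthoc = posthoc),
            class = "lans_distribution")
}

#' @export
print.lans_distribution <- function(x, ...) {
  cat("Likelihood distribution by pathology group (counts)\n")
  print(x$counts)
  cat("Row percentages (within group):\n")
  print(round(x$row_pct, 1))
  cat(sprintf("Omnibus chi-square: X2 = %.3f, df = %s, p = %.4g\n",
              unname(x$omnibus$statistic), unname(x$omnibus$parameter),
              x$omnibus$p.value))
  if (!is.null(x$posthoc)) {
    cat("Post hoc pairwise two-proportion tests:\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

#' Mixed model of longitudinal CDR-SB by group
#'
#' Fits, by maximum likelihood, CDR-SB as outcome on fixed effects of
#' group, time from baseline (years) and their interaction, with a random
#' intercept (and by default a random slope on time) per subject. The
#' interaction terms are the group differences in annual CDR-SB slope
#' relative to the reference group.
#'
#' @param records a \code{lans_cohort}.
#' @param grouping named character vector mapping patient_id to group (e.g.
#'   likelihood bins or pathology labels); patients absent from it are
#'   dropped.
#' @param reference reference group level (default: first alphabetically).
#' @param random_slope include a per-subject random slope on time
#'   (default TRUE).
#' @return Object of class \code{lans_trajectory_model}: \code{model}
#'   (lmerMod), \code{fixed} (coefficient table), \code{interactions}
#'   (slope-difference contrasts vs reference), \code{n_subjects},
#'   \code{n_observations}, \code{converged}.
#' @export
fit_trajectory_model <- function(records, grouping, reference = NULL,
                                 random_slope = TRUE) {
  rows <- lapply(records, function(r) {
    if (!r$patient_id %in% names(grouping)) return(NULL)
    v <- r$visits[!is.na(r$visits$cdr_sb), , drop = FALSE]
    if (!nrow(v)) return(NULL)
    data.frame(patient_id = r$patient_id,
               group = grouping[[r$patient_id]],
               time = v$time_from_baseline, cdr_sb = v$cdr_sb,
               stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, rows)
  if (is.null(dat) || length(unique(dat$group)) < 2L) {
    stop("need longitudinal CDR-SB in >= 2 groups", call. = FALSE)
  }
  dat$group <- factor(dat$group)
  if (!is.null(reference)) dat$group <- stats::relevel(dat$group, reference)
  form <- if (random_slope) {
    cdr_sb ~ group * time + (1 + time | patient_id)
  } else {
    cdr_sb ~ group * time + (1 | patient_id)
  }
  fit <- lme4::lmer(form, data = dat, REML = FALSE)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  if (!conv) {
    warning("trajectory model convergence issue: ",
            paste(fit@optinfo$conv$lme4$messages, collapse = "; "),
            call. = FALSE)
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tab <- data.frame(term = names(fe), estimate = unname(fe),
                    se = unname(se), z = unname(fe / se),
                    stringsAsFactors = FALSE)
  inter <- tab[grepl(":time$", tab$term), , drop = FALSE]
  structure(list(model = fit, fixed = tab, interactions = inter,
                 reference = levels(dat$group)[1L],
                 n_subjects = length(unique(dat$patient_id)),
                 n_observations = nrow(dat), converged = conv),
            class = "lans_trajectory_model")
}

#' @export
print.lans_trajectory_model <- function(x, ...) {
  cat(sprintf("CDR-SB trajectory mixed model: %d subjects, %d observations%s\n",
              x$n_subjects, x$n_observations,
              if (x$converged) "" else " (NOT converged)"))
  cat("Fixed effects:\n")
  print(x$fixed, digits = 4, row.names = FALSE)
  cat(sprintf("Slope contrasts are vs reference group '%s'\n", x$reference))
  invisible(x)
}
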