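#' Longitudinal mixed model of hippocampal volume on clinical severity
#'
#' Fits, by maximum likelihood, a linear mixed model with ICV/sex-adjusted
#' hippocampal volume as outcome, CDR-SB as the fixed predictor and a random
#' intercept per subject to account for intra-individual change. The fixed
#' effects define the volume expected at a given severity; patients whose
#' hippocampus is smaller than that expectation show disproportionate
#' atrophy (see \code{\link{score_disproportion}}).
#'
#' @param records a \code{lans_cohort} or list of \code{lans_patient}; every
#'   visit with both CDR-SB and adjusted hippocampal volume contributes.
#' @param random_slope also include a per-subject random slope on CDR-SB
#'   (default FALSE: many subjects contribute few visits).
#' @param min_subjects minimum distinct subjects required (default 20).
#' @return Object of class \code{lans_volume_model} wrapping the
#'   \code{lme4} fit, with elements \code{fixed_intercept},
#'   \code{fixed_slope}, \code{fixed_se} (named), \code{random_intercept_sd},
#'   \code{random_slope_sd} (NA unless requested), \code{residual_sd},
#'   \code{n_subjects}, \code{n_observations}, \code{converged}.
#' @export
fit_volume_cdr_model <- function(records, random_slope = FALSE,
                                 min_subjects = 20L) {
  dat <- volume_cdr_long(records)
  n_subj <- length(unique(dat$patient_id))
  if (n_subj < max(2L, min_subjects)) {
    stop("need >= ", max(2L, min_subjects),
         " subjects with paired CDR-SB and adjusted hippocampal volume, got ",
         n_subj, call. = FALSE)
  }
  form <- if (random_slope) {
    hippocampal_volume_adj ~ cdr_sb + (1 + cdr_sb | patient_id)
  } else {
    hippocampal_volume_adj ~ cdr_sb + (1 | patient_id)
  }
  fit <- lme4::lmer(form, data = dat, REML = FALSE)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  if (!conv) {
    warning("mixed model convergence issue: ",
            paste(fit@optinfo$conv$lme4$messages, collapse = "; "),
            call. = FALSE)
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "patient_id" & vc$var1 == "(Intercept)" &
                      is.na(vc$var2)][1L]
  rs_sd <- if (random_slope) {
    vc$sdcor[vc$grp == "patient_id" & vc$var1 == "cdr_sb" &
               is.na(vc$var2)][1L]
  } else NA_real_
  structure(list(
    model = fit,
    fixed_intercept = unname(fe[["(Intercept)"]]),
    fixed_slope = unname(fe[["cdr_sb"]]),
    fixed_se = se,
    random_intercept_sd = ri_sd,
    random_slope_sd = rs_sd,
    residual_sd = stats::sigma(fit),
    n_subjects = n_subj,
    n_observations = nrow(dat),
    converged = conv
  ), class = "lans_volume_model")
}

volume_cdr_long <- function(records) {
  rows <- lapply(records, function(r) {
    v <- r$visits
    keep <- !is.na(v$cdr_sb) & !is.na(v$hippocampal_volume_adj)
    if (!any(keep)) return(NULL)
    cbind(data.frame(patient_id = r$patient_id, stringsAsFactors = FALSE),
          v[keep, , drop = FALSE])
  })
  dat <- do.call(rbind, rows)
  if (is.null(dat) || !nrow(dat)) {
    stop("no visits with paired CDR-SB and adjusted hippocampal volume",
         call. = FALSE)
  }
  rownames(dat) <- NULL
  dat
}

#' @export
print.lans_volume_model <- function(x, ...) {
  cat("Mixed model: adjusted hippocampal volume ~ CDR-SB + (1 | patient)\n")
  cat(sprintf("  %d subjects, %d observations (ML fit%s)\n", x$n_subjects,
              x$n_observations, if (x$converged) "" else "; NOT converged"))
  cat(sprintf("  fixed: intercept %.4g (SE %.3g), CDR-SB slope %.4g (SE %.3g)\n",
              x$fixed_intercept, x$fixed_se[1L], x$fixed_slope, x$fixed_se[2L]))
  cat(sprintf("  random intercept sd %.3g; residual sd %.3g\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' @export
coef.lans_volume_model <- function(object, ...) {
  c("(Intercept)" = object$fixed_intercept, cdr_sb = object$fixed_slope)
}

#' Population-level volume prediction at a given CDR-SB
#'
#' Uses the fixed effects only, so a model fit in one cohort transfers to
#' another without that cohort's random effects.
#'
#' @param object a \code{lans_volume_model}.
#' @param cdr_sb numeric vector of CDR-SB scores.
#' @param ... unused.
#' @return Predicted adjusted hippocampal volume.
#' @export
predict.lans_volume_model <- function(object, cdr_sb, ...) {
  object$fixed_intercept + object$fixed_slope * cdr_sb
}

#' Score disproportionate hippocampal atrophy
#'
#' For each patient, takes the last visit with an adjusted hippocampal
#' volume (the last MRI), computes the residual from the population-level
#' (fixed-effects-only) prediction at that visit's CDR-SB, scales by the
#' model residual SD, then Z-scores the scaled residuals across the scored
#' cohort. More-negative Z means hippocampal volume smaller than the
#' severity-expected value, i.e. disproportionate atrophy.
#'
#' Fixed-effects-only prediction allows the model fit in one cohort to score
#' patients of another; patients missing a usable visit are omitted with a
#' warning, never zero-filled.
#'
#' @param fit a \code{lans_volume_model}.
#' @param records cohort to score.
#' @return Data frame of class \code{lans_disproportion}: \code{patient_id},
#'   \code{raw_residual}, \code{scaled_residual}, \code{z_score},
#'   \code{source_visit_time}.
#' @export
score_disproportion <- function(fit, records) {
  stopifnot(inherits(fit, "lans_volume_model"))
  rows <- lapply(records, function(r) {
    v <- r$visits
    ok <- !is.na(v$cdr_sb) & !is.na(v$hippocampal_volume_adj)
    if (!any(ok)) return(NULL)
    i <- max(which(ok))  # last MRI with paired CDR-SB
    data.frame(patient_id = r$patient_id,
               raw_residual = v$hippocampal_volume_adj[i] -
                 predict(fit, v$cdr_sb[i]),
               source_visit_time = v$time_from_baseline[i],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " patient(s) lacked a visit with paired CDR-SB and ",
            "volume and were omitted from disproportion scoring",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    stop("no patients scoreable for disproportionate atrophy", call. = FALSE)
  }
  out$scaled_residual <- out$raw_residual / fit$residual_sd
  out$z_score <- as.numeric(scale(out$scaled_residual))
  rownames(out) <- NULL
  class(out) <- c("lans_disproportion", "data.frame")
  out
}

#' ROC-derived cut-point for disproportionate atrophy
#'
#' Runs \code{\link{roc_optimal_threshold}} on the Z-scored residuals with
#' lower-is-positive orientation (more-negative residual = more atrophy =
#' LATE-like). The returned threshold is installed in a configuration as
#' \code{hippo_z_abnormal_max}.
#'
#' @param scores a \code{lans_disproportion} table or numeric Z vector.
#' @param late_labels logical: LATE-NC present at autopsy.
#' @return \code{lans_roc} object.
#' @export
derive_atrophy_cutoff <- function(scores, late_labels) {
  z <- if (is.data.frame(scores)) scores$z_score else scores
  roc_optimal_threshold(z, late_labels, direction = "LOWER_IS_POSITIVE")
}
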