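#' Inferior-to-medial temporal (IMT) FDG-PET ratio
#'
#' Divides the inferior temporal SUVR by the size-weighted mean SUVR of the
#' medial temporal regions (amygdala and hippocampus), where the weights are
#' template region volumes. Higher values indicate hypometabolism that is
#' disproportionately medial-temporal, the LATE-like pattern; the canonical
#' Alzheimer pattern (lateral worse than medial) drives the ratio down.
#'
#' @param inferior_temporal_suvr inferior temporal FDG SUVR (pons-normalized).
#' @param medial_suvr numeric vector of medial-region SUVRs (>= 1 region).
#' @param medial_volume template volumes weighting each medial region
#'   (same length as \code{medial_suvr}).
#' @return The dimensionless ratio
#'   \eqn{SUVR_{IT} / (\sum_i v_i s_i / \sum_i v_i)}.
#' @examples
#' compute_imt_ratio(1.5, c(1.0, 1.0), c(2, 8))  # 1.5
#' compute_imt_ratio(1.2, c(1.0, 0.8), c(3, 7))  # 1.2 / 0.86
#' @export
compute_imt_ratio <- function(inferior_temporal_suvr, medial_suvr,
                              medial_volume) {
  if (length(medial_suvr) < 1L || length(medial_suvr) != length(medial_volume)) {
    stop("need >= 1 medial region with matching suvr and volume vectors",
         call. = FALSE)
  }
  vals <- c(inferior_temporal_suvr, medial_suvr, medial_volume)
  if (anyNA(vals) || any(vals <= 0)) {
    stop("all SUVRs and volumes must be positive and non-missing",
         call. = FALSE)
  }
  inferior_temporal_suvr /
    (sum(medial_volume * medial_suvr) / sum(medial_volume))
}

#' Fit sex-specific normative regressions of hippocampal volume on ICV
#'
#' Ordinary least squares of raw hippocampal volume (hemispheres combined)
#' on total intracranial volume, fit separately per sex in a control sample.
#' The fit supplies the expected volume from which patient residuals are
#' taken by \code{\link{adjust_hippocampal_volume}}.
#'
#' @param raw_volume,icv,sex parallel vectors over control subjects; sex in
#'   \{"F","M"\}. At least 3 controls per sex stratum.
#' @return Object of class \code{lans_normvol}: per-sex \code{intercept},
#'   \code{slope} and residual standard deviation.
#' @export
fit_normative_volume <- function(raw_volume, icv, sex) {
  stopifnot(length(raw_volume) == length(icv),
            length(raw_volume) == length(sex))
  check_enum(sex, SEXES, "sex")
  keep <- !is.na(raw_volume) & !is.na(icv)
  fits <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    idx <- keep & sex == s
    if (sum(idx) < 3L) {
      stop("need >= 3 controls with volume and ICV in sex stratum '", s, "'",
           call. = FALSE)
    }
    m <- stats::lm(raw_volume[idx] ~ icv[idx])
    list(intercept = unname(stats::coef(m)[1L]),
         slope = unname(stats::coef(m)[2L]),
         residual_sd = stats::sigma(m),
         n = sum(idx))
  })
  structure(fits, class = "lans_normvol")
}

#' @export
print.lans_normvol <- function(x, ...) {
  cat("Normative hippocampal volume ~ ICV fit (per sex)\n")
  for (s in names(x)) {
    cat(sprintf("  %s: volume = %.4g + %.4g * ICV (resid sd %.3g, n = %d)\n",
                s, x[[s]]$intercept, x[[s]]$slope, x[[s]]$residual_sd,
                x[[s]]$n))
  }
  invisible(x)
}

#' ICV- and sex-adjusted hippocampal volume
#'
#' Residual of the observed volume from its sex-specific normative
#' regression on intracranial volume; negative values mean the hippocampus
#' is smaller than expected for head size.
#'
#' @param raw_volume observed hippocampal volume (hemispheres combined).
#' @param icv total intracranial volume.
#' @param sex "F" or "M" (vectors recycled against \code{raw_volume}).
#' @param fit a \code{lans_normvol} from \code{\link{fit_normative_volume}}.
#' @return Residual volume(s), same length as \code{raw_volume}.
#' @export
adjust_hippocampal_volume <- function(raw_volume, icv, sex, fit) {
  stopifnot(inherits(fit, "lans_normvol"))
  check_enum(sex, SEXES, "sex")
  if (!all(sex %in% names(fit))) {
    stop("fit lacks sex stratum: ",
         paste(setdiff(unique(sex), names(fit)), collapse = ", "),
         call. = FALSE)
  }
  sex <- rep_len(sex, length(raw_volume))
  icv <- rep_len(icv, length(raw_volume))
  pred <- vapply(seq_along(raw_volume), function(i) {
    f <- fit[[sex[i]]]
    f$intercept + f$slope * icv[i]
  }, numeric(1))
  raw_volume - pred
}

#' ROC analysis with Youden-optimal threshold
#'
#' Computes the area under the ROC curve by all-pairs concordance (ties
#' count one half) and selects the operating threshold maximizing Youden's
#' J = sensitivity + specificity - 1. Candidate thresholds are midpoints
#' between adjacent unique scores, making the choice invariant to monotone
#' jitter below the data resolution; ties in J are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @param scores numeric scores, no missing values.
#' @param labels logical (or 0/1) disease labels; both classes required.
#' @param direction "HIGHER_IS_POSITIVE" (score above threshold calls
#'   disease) or "LOWER_IS_POSITIVE".
#' @return Object of class \code{lans_roc} with fields \code{auc},
#'   \code{optimal_threshold}, \code{sensitivity_at_threshold},
#'   \code{specificity_at_threshold}, \code{youden_j}, \code{direction},
#'   \code{n_positive}, \code{n_negative}.
#' @examples
#' roc_optimal_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
#'                       "HIGHER_IS_POSITIVE")
#' @export
roc_optimal_threshold <- function(scores, labels,
                                  direction = c("HIGHER_IS_POSITIVE",
                                                "LOWER_IS_POSITIVE")) {
  direction <- match.arg(direction)
  if (anyNA(scores)) stop("scores must not contain missing values",
                          call. = FALSE)
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must not contain missing values",
                          call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  oriented <- if (direction == "HIGHER_IS_POSITIVE") scores else -scores
  # Mann-Whitney concordance; midranks give ties weight 1/2
  r <- rank(oriented, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  u <- sort(unique(scores))
  cand <- if (length(u) >= 2L) (u[-1L] + u[-length(u)]) / 2 else u
  best <- NULL
  for (th in cand) {
    called <- if (direction == "HIGHER_IS_POSITIVE") scores > th
              else scores < th
    sens <- sum(called & labels) / n_pos
    spec <- sum(!called & !labels) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(th = th, sens = sens, spec = spec, j = j)
    }
  }
  structure(list(auc = auc,
                 optimal_threshold = best$th,
                 sensitivity_at_threshold = best$sens,
                 specificity_at_threshold = best$spec,
                 youden_j = best$j,
                 direction = direction,
                 n_positive = n_pos,
                 n_negative = n_neg),
            class = "lans_roc")
}

#' @export
print.lans_roc <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC %.3f over %d+/%d-\n", x$direction, x$auc,
              x$n_positive, x$n_negative))
  cat(sprintf("  Youden-optimal threshold %.4g (sens %.3f, spec %.3f, J %.3f)\n",
              x$optimal_threshold, x$sensitivity_at_threshold,
              x$specificity_at_threshold, x$youden_j))
  invisible(x)
}
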