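# Box-style LANS likelihood engine: core feature gate, tri-state standard
# and advanced supportive features, tiered tau-biomarker cascade, and the
# ordered likelihood assignment. Feature states are "MET" / "NOT_MET" /
# "UNAVAILABLE"; unavailable features never count toward a likelihood (they
# cap the reachable category rather than disqualifying the patient).

#' Evaluate the core LANS feature
#'
#' Core: a slow, predominant amnestic neurodegenerative syndrome with
#' insidious onset and gradual progression over two or more years. A
#' clinical diagnosis of amnestic MCI or amnestic dementia satisfies the
#' syndrome requirement; a recorded symptom duration under 2 years fails
#' the progression requirement. Unknown duration does not disqualify.
#'
#' @param record a \code{lans_patient}.
#' @return TRUE/FALSE.
#' @export
evaluate_core <- function(record) {
  if (!record$clinical_dx %in% c("AMNESTIC_MCI", "AMNESTIC_DEMENTIA")) {
    return(FALSE)
  }
  if (!is.na(record$symptom_duration) && record$symptom_duration < 2) {
    return(FALSE)
  }
  TRUE
}

#' Evaluate the standard supportive features
#'
#' Standard features: (1) older age at evaluation (age at first visit at or
#' above the configured cut-off, default 75); (2) mild clinical syndrome
#' (MCI diagnosis, or dementia with first-visit CDR-SB at or below the mild
#' maximum, default 4); (3) disproportionate hippocampal atrophy (passed in
#' as a tri-state, typically derived from \code{\link{score_disproportion}}
#' and the ROC cut); (4) impaired semantic memory, copied from the clinical
#' flag but excluded from likelihood counts unless
#' \code{cfg$include_semantic_feature} is TRUE.
#'
#' @param record a \code{lans_patient}.
#' @param cfg a \code{lans_config}.
#' @param atrophy_flag tri-state ("MET"/"NOT_MET"/"UNAVAILABLE").
#' @return Named list of tri-states: \code{age_ge_cutoff},
#'   \code{mild_syndrome}, \code{disproportionate_atrophy},
#'   \code{semantic_impairment}.
#' @export
evaluate_standard <- function(record, cfg, atrophy_flag = "UNAVAILABLE") {
  tristate(atrophy_flag)
  age <- as_tristate(record$age_first_visit >= cfg$age_cutoff)
  baseline_cdr <- if (nrow(record$visits)) record$visits$cdr_sb[1L] else NA
  mild <- if (record$clinical_dx == "AMNESTIC_MCI") {
    "MET"
  } else if (!is.na(baseline_cdr)) {
    as_tristate(baseline_cdr <= cfg$cdr_sb_mild_max)
  } else {
    "UNAVAILABLE"
  }
  semantic <- as_tristate(record$semantic_memory_impaired)
  list(age_ge_cutoff = age,
       mild_syndrome = mild,
       disproportionate_atrophy = atrophy_flag,
       semantic_impairment = semantic)
}

#' Evaluate low likelihood of neocortical tau via the biomarker cascade
#'
#' Scenarios are tried in priority order: (i) amyloid-PET available and
#' negative establishes low neocortical tau (amyloid negativity is a
#' surrogate for absent neocortical tau); (ii) amyloid-PET positive with
#' tau-PET available: negative tau-PET meets the feature, positive does not.
#' Amyloid-positive with no tau-PET cannot establish low tau likelihood:
#' the feature is not met and further workup is indicated (fluid markers
#' only substitute when PET is unavailable). (iii) With no PET, CSF meets
#' the feature only if every present CSF measure is Alzheimer-negative
#' (Abeta42 above its cut, P-tau below, P-tau/Abeta42 ratio below); any
#' positive measure fails it. (iv) With no PET or CSF, plasma pTau181 meets
#' the feature iff below its cut. (v) Nothing available: unavailable.
#'
#' @param imaging imaging panel list (or NULL).
#' @param fluids fluid panel list (or NULL).
#' @param cfg a \code{lans_config}.
#' @return List with \code{status} (tri-state) and \code{scenario}
#'   ("AMYLOID_PET", "TAU_PET", "CSF", "PLASMA" or "NONE").
#' @export
evaluate_tau_cascade <- function(imaging, fluids, cfg) {
  amyloid <- scalar_or_na(imaging$amyloid_pet_suvr)
  if (!is.na(amyloid)) {
    cut <- amyloid_cut_for(imaging$amyloid_tracer, cfg)
    positive <- apply_threshold(amyloid, cut, "ge")
    if (!positive) {
      return(list(status = "MET", scenario = "AMYLOID_PET"))
    }
    tau <- scalar_or_na(imaging$tau_pet_suvr)
    if (!is.na(tau)) {
      met <- !apply_threshold(tau, cfg$tau_pet_abnormal_min, "ge")
      return(list(status = as_tristate(met), scenario = "TAU_PET"))
    }
    # amyloid-positive, tau-PET missing: low neocortical-tau likelihood
    # cannot be established; fluids are fallbacks only when PET is absent
    return(list(status = "NOT_MET", scenario = "AMYLOID_PET"))
  }
  csf <- c(abeta42 = scalar_or_na(fluids$csf_abeta42),
           ptau = scalar_or_na(fluids$csf_ptau181),
           ratio = scalar_or_na(fluids$csf_ptau_abeta_ratio))
  if (is.na(csf["ratio"]) && !is.na(csf["abeta42"]) && !is.na(csf["ptau"])) {
    csf["ratio"] <- csf[["ptau"]] / csf[["abeta42"]]
  }
  if (any(!is.na(csf))) {
    positive <- c(
      abeta42 = apply_threshold(csf[["abeta42"]],
                                cfg$csf_abeta42_abnormal_max, "le"),
      ptau = apply_threshold(csf[["ptau"]], cfg$csf_ptau_abnormal_min, "ge"),
      ratio = apply_threshold(csf[["ratio"]], cfg$csf_ratio_abnormal_min,
                              "ge"))
    met <- all(!positive, na.rm = TRUE)  # conjunction over present measures
    return(list(status = as_tristate(met), scenario = "CSF"))
  }
  plasma <- scalar_or_na(fluids$plasma_ptau181)
  if (!is.na(plasma)) {
    met <- apply_threshold(plasma, cfg$plasma_ptau_abnormal_min, "lt")
    return(list(status = as_tristate(met), scenario = "PLASMA"))
  }
  list(status = "UNAVAILABLE", scenario = "NONE")
}

amyloid_cut_for <- function(tracer, cfg) {
  cuts <- cfg$amyloid_abnormal_min
  if (is.null(tracer) || is.na(tracer)) {
    return(cuts[[1L]])  # dialect's default tracer
  }
  if (!tracer %in% names(cuts)) {
    stop("no amyloid cut configured for tracer ", tracer, call. = FALSE)
  }
  cuts[[tracer]]
}

#' Evaluate the advanced supportive features
#'
#' Advanced features: (1) limbic hypometabolism, met when the FDG-PET IMT
#' ratio is at or above its cut (medial temporal metabolism
#' disproportionately reduced); (2) absence of a neocortical degenerative
#' pattern, met when the FDG-PET Alzheimer meta-ROI SUVR is strictly above
#' the abnormality cut (neocortical metabolism preserved); (3) low
#' likelihood of neocortical tau, passed through from
#' \code{\link{evaluate_tau_cascade}}.
#'
#' @param imaging imaging panel (or NULL).
#' @param cfg a \code{lans_config}.
#' @param tau_status tri-state from the tau cascade.
#' @return Named list of tri-states: \code{limbic_hypometabolism},
#'   \code{no_neocortical_pattern}, \code{low_neocortical_tau}, plus
#'   \code{imt_ratio} (numeric, NA when not computable).
#' @export
evaluate_advanced <- function(imaging, cfg, tau_status = "UNAVAILABLE") {
  tristate(tau_status)
  imt <- imt_from_panel(imaging, cfg)
  limbic <- if (is.na(imt) || is.na(cfg$imt_abnormal_min)) {
    "UNAVAILABLE"
  } else {
    as_tristate(apply_threshold(imt, cfg$imt_abnormal_min, "ge"))
  }
  meta <- scalar_or_na(imaging$fdg_meta_roi_suvr)
  no_neo <- if (is.na(meta)) {
    "UNAVAILABLE"
  } else {
    # SUVR <= cut is the hypometabolic (Alzheimer-pattern) side; preserved
    # metabolism strictly above the cut meets the feature
    as_tristate(!apply_threshold(meta, cfg$fdg_meta_roi_abnormal_max, "le"))
  }
  list(limbic_hypometabolism = limbic,
       no_neocortical_pattern = no_neo,
       low_neocortical_tau = tau_status,
       imt_ratio = imt)
}

imt_from_panel <- function(imaging, cfg) {
  it <- scalar_or_na(imaging$inferior_temporal_suvr)
  am <- scalar_or_na(imaging$amygdala_suvr)
  hc <- scalar_or_na(imaging$hippocampus_suvr)
  if (is.na(it) || is.na(am) || is.na(hc)) return(NA_real_)
  vols <- c(scalar_or_na(imaging$amygdala_volume),
            scalar_or_na(imaging$hippocampus_volume))
  if (anyNA(vols)) {
    vols <- cfg$imt_template_volumes[c("amygdala", "hippocampus")]
  }
  compute_imt_ratio(it, c(am, hc), vols)
}

#' Assign the LANS likelihood category
#'
#' Converts a feature profile into the ordered certainty category. With S =
#' number of standard features met (of \code{S_max}: 3 operationalized, 4
#' when the semantic feature is configured in) and A = number of advanced
#' features met (of 3):
#' \itemize{
#'   \item \code{NOT_LANS} when the core feature is unmet;
#'   \item \code{HIGHEST} when all operationalized standard and all advanced
#'     features are met (S = S_max, A = 3);
#'   \item \code{HIGH} when S >= 3 and A >= 1, or S >= 2 and A >= 2;
#'   \item \code{MODERATE} when S >= 3, or S >= 2 and A >= 1;
#'   \item \code{LOW} otherwise.
#' }
#' Rules are evaluated from highest down and the first satisfied wins.
#' Unavailable features count as not met: missing data never raises a
#' category, it only caps the reachable one.
#'
#' @param profile list with \code{core_met} (logical) and tri-state fields
#'   \code{age_ge_cutoff}, \code{mild_syndrome},
#'   \code{disproportionate_atrophy}, \code{semantic_impairment},
#'   \code{limbic_hypometabolism}, \code{no_neocortical_pattern},
#'   \code{low_neocortical_tau}.
#' @param cfg a \code{lans_config} (controls the semantic feature).
#' @return List with \code{category} (ordered factor), \code{n_standard_met},
#'   \code{n_advanced_met}.
#' @export
assign_likelihood <- function(profile, cfg) {
  standard <- c(profile$age_ge_cutoff, profile$mild_syndrome,
                profile$disproportionate_atrophy)
  s_max <- 3L
  if (isTRUE(cfg$include_semantic_feature)) {
    standard <- c(standard, profile$semantic_impairment)
    s_max <- 4L
  }
  advanced <- c(profile$limbic_hypometabolism, profile$no_neocortical_pattern,
                profile$low_neocortical_tau)
  s <- sum(is_met(standard))
  a <- sum(is_met(advanced))
  category <- if (!isTRUE(profile$core_met)) {
    "NOT_LANS"
  } else if (s == s_max && a == 3L) {
    "HIGHEST"
  } else if ((s >= 3L && a >= 1L) || (s >= 2L && a >= 2L)) {
    "HIGH"
  } else if (s >= 3L || (s >= 2L && a >= 1L)) {
    "MODERATE"
  } else {
    "LOW"
  }
  list(category = likelihood_factor(category),
       n_standard_met = s,
       n_advanced_met = a)
}

#' Evaluate LANS features and likelihoods for a cohort
#'
#' Runs the full criteria engine per patient: core gate, standard features
#' (with disproportionate-atrophy flags thresholded from supplied Z-scores),
#' tau cascade, advanced features and likelihood assignment. Patients with
#' missing features are still classified; missing counts as not met.
#'
#' @param records a \code{lans_cohort}.
#' @param cfg a \code{lans_config}; \code{cfg$hippo_z_abnormal_max} and
#'   \code{cfg$imt_abnormal_min} should be installed (e.g. from
#'   \code{\link{derive_atrophy_cutoff}} / \code{\link{roc_optimal_threshold}})
#'   for the atrophy and limbic features to resolve.
#' @param atrophy_scores optional \code{lans_disproportion} table; patients
#'   absent from it get an unavailable atrophy feature.
#' @return Data frame of class \code{lans_likelihood_table}: one row per
#'   patient with all tri-state flags, the tau scenario, \code{n_standard_met}
#'   (S), \code{n_advanced_met} (A) and \code{likelihood}.
#' @export
classify_cohort <- function(records, cfg, atrophy_scores = NULL) {
  if (!length(records)) stop("empty cohort", call. = FALSE)
  z <- if (is.null(atrophy_scores)) {
    stats::setNames(numeric(), character())
  } else {
    stats::setNames(atrophy_scores$z_score, atrophy_scores$patient_id)
  }
  rows <- lapply(records, function(r) {
    zi <- if (r$patient_id %in% names(z)) z[[r$patient_id]] else NA_real_
    atrophy <- if (is.na(zi) || is.na(cfg$hippo_z_abnormal_max)) {
      "UNAVAILABLE"
    } else {
      as_tristate(apply_threshold(zi, cfg$hippo_z_abnormal_max, "le"))
    }
    core <- evaluate_core(r)
    std <- evaluate_standard(r, cfg, atrophy)
    tau <- evaluate_tau_cascade(r$imaging, r$fluids, cfg)
    adv <- evaluate_advanced(r$imaging, cfg, tau$status)
    profile <- c(list(core_met = core), std,
                 adv[c("limbic_hypometabolism", "no_neocortical_pattern",
                       "low_neocortical_tau")])
    lk <- assign_likelihood(profile, cfg)
    data.frame(patient_id = r$patient_id,
               pathology_group = r$pathology_group,
               core_met = core,
               age_ge_cutoff = std$age_ge_cutoff,
               mild_syndrome = std$mild_syndrome,
               disproportionate_atrophy = std$disproportionate_atrophy,
               semantic_impairment = std$semantic_impairment,
               limbic_hypometabolism = adv$limbic_hypometabolism,
               no_neocortical_pattern = adv$no_neocortical_pattern,
               low_neocortical_tau = adv$low_neocortical_tau,
               tau_scenario = tau$scenario,
               imt_ratio = adv$imt_ratio,
               atrophy_z = zi,
               n_standard_met = lk$n_standard_met,
               n_advanced_met = lk$n_advanced_met,
               likelihood = as.character(lk$category),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$likelihood <- likelihood_factor(out$likelihood)
  class(out) <- c("lans_likelihood_table", "data.frame")
  out
}

#' @export
print.lans_likelihood_table <- function(x, ...) {
  cat("LANS likelihoods for", nrow(x), "patients\n")
  print(table(likelihood = x$likelihood))
  invisible(x)
}
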