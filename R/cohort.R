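#' Construct a patient record
#'
#' A \code{lans_patient} holds one subject's demographics, clinical
#' diagnosis, longitudinal visits, imaging and fluid biomarker panels and the
#' autopsy group label. Visits are stored as a data frame sorted by time from
#' baseline; missing measurements are \code{NA}, never sentinel values.
#'
#' @param patient_id character scalar identifier.
#' @param age_first_visit age in years at first visit (> 0).
#' @param sex "F" or "M".
#' @param clinical_dx "AMNESTIC_MCI", "AMNESTIC_DEMENTIA" or "OTHER".
#' @param cohort "MAYO", "ADNI" or "SYNTHETIC".
#' @param symptom_duration years of symptoms before evaluation (optional).
#' @param visits data frame with columns \code{time_from_baseline},
#'   \code{cdr_sb} (0-18) and optionally \code{hippocampal_volume_adj}.
#' @param imaging named list of imaging measurements (see Details) or NULL.
#' @param fluids named list of fluid measurements or NULL.
#' @param pathology_group autopsy label: "ADNC", "LATE", "ADNC_LATE",
#'   "OTHER" or "UNKNOWN" (prospective use).
#' @param semantic_memory_impaired logical or NA (optional clinical flag,
#'   excluded from likelihood counts unless configured).
#'
#' @details Recognized \code{imaging} fields: \code{inferior_temporal_suvr},
#' \code{amygdala_suvr}, \code{hippocampus_suvr}, \code{amygdala_volume},
#' \code{hippocampus_volume}, \code{fdg_meta_roi_suvr},
#' \code{amyloid_pet_suvr}, \code{amyloid_tracer}, \code{tau_pet_suvr},
#' \code{raw_hippocampal_volume}, \code{icv}. Recognized \code{fluids}
#' fields: \code{csf_abeta42}, \code{csf_ptau181}, \code{csf_ptau_abeta_ratio},
#' \code{plasma_ptau181}. SUVRs are pons-normalized for FDG and
#' cerebellar-crus-normalized for tau PET.
#'
#' @return An object of class \code{lans_patient}.
#' @export
lans_patient <- function(patient_id, age_first_visit, sex, clinical_dx,
                         cohort = "SYNTHETIC", symptom_duration = NA_real_,
                         visits = NULL, imaging = NULL, fluids = NULL,
                         pathology_group = "UNKNOWN",
                         semantic_memory_impaired = NA) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!is.numeric(age_first_visit) || is.na(age_first_visit) ||
      age_first_visit <= 0) {
    stop("age_first_visit must be a positive number", call. = FALSE)
  }
  check_enum(sex, SEXES, "sex")
  check_enum(clinical_dx, CLINICAL_DX, "clinical_dx")
  check_enum(cohort, COHORTS, "cohort")
  check_enum(pathology_group, PATHOLOGY_GROUPS, "pathology_group")
  if (is.null(visits)) {
    visits <- data.frame(time_from_baseline = numeric(), cdr_sb = numeric(),
                         hippocampal_volume_adj = numeric())
  }
  visits <- as.data.frame(visits)
  if (!"hippocampal_volume_adj" %in% names(visits)) {
    visits$hippocampal_volume_adj <- NA_real_
  }
  visits <- visits[order(visits$time_from_baseline),
                   c("time_from_baseline", "cdr_sb", "hippocampal_volume_adj"),
                   drop = FALSE]
  rownames(visits) <- NULL
  if (nrow(visits)) {
    if (any(visits$time_from_baseline < 0)) {
      stop("visit times must be >= 0", call. = FALSE)
    }
    bad_cdr <- !is.na(visits$cdr_sb) &
      (visits$cdr_sb < 0 | visits$cdr_sb > 18)
    if (any(bad_cdr)) stop("cdr_sb must lie in [0, 18]", call. = FALSE)
  }
  if (!is.null(imaging)) {
    imaging <- validate_imaging(imaging)
    if (all(is.na(unlist(imaging)))) imaging <- NULL
  }
  if (!is.null(fluids)) {
    fluids <- validate_fluids(fluids)
    if (all(is.na(unlist(fluids)))) fluids <- NULL
  }
  structure(list(
    patient_id = unname(patient_id),
    cohort = unname(cohort),
    age_first_visit = unname(as.numeric(age_first_visit)),
    sex = unname(sex),
    clinical_dx = unname(clinical_dx),
    symptom_duration = scalar_or_na(symptom_duration),
    visits = visits,
    imaging = imaging,
    fluids = fluids,
    pathology_group = pathology_group,
    semantic_memory_impaired =
      if (is.na(semantic_memory_impaired)) NA else
        as.logical(semantic_memory_impaired)
  ), class = "lans_patient")
}

validate_imaging <- function(imaging) {
  out <- lapply(stats::setNames(IMAGING_FIELDS, IMAGING_FIELDS),
                function(f) scalar_or_na(imaging[[f]]))
  for (f in IMAGING_FIELDS) {
    v <- out[[f]]
    if (!is.na(v) && v <= 0) {
      stop("imaging field '", f, "' must be positive, got ", v, call. = FALSE)
    }
  }
  tracer <- imaging[["amyloid_tracer"]]
  if (is.null(tracer) || length(tracer) == 0L || is.na(tracer[1L]) ||
      !nzchar(tracer[1L])) {
    tracer <- NA_character_
  } else {
    tracer <- check_enum(as.character(tracer[1L]), AMYLOID_TRACERS,
                         "amyloid_tracer")
  }
  out$amyloid_tracer <- tracer
  out
}

validate_fluids <- function(fluids) {
  out <- lapply(stats::setNames(FLUID_FIELDS, FLUID_FIELDS),
                function(f) scalar_or_na(fluids[[f]]))
  for (f in FLUID_FIELDS) {
    v <- out[[f]]
    if (!is.na(v) && v <= 0) {
      stop("fluid field '", f, "' must be positive, got ", v, call. = FALSE)
    }
  }
  out
}

#' @export
print.lans_patient <- function(x, ...) {
  cat(sprintf("<lans_patient %s> %s, %s, age %.1f, dx %s, pathology %s\n",
              x$patient_id, x$cohort, x$sex, x$age_first_visit,
              x$clinical_dx, x$pathology_group))
  cat(sprintf("  %d visit(s); imaging %s; fluids %s\n", nrow(x$visits),
              if (is.null(x$imaging)) "absent" else "present",
              if (is.null(x$fluids)) "absent" else "present"))
  invisible(x)
}

new_lans_cohort <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "lans_patient")))
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(records, ids), class = "lans_cohort")
}

#' @export
print.lans_cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, character(1), "pathology_group"))
  cat(sprintf("<lans_cohort> %d patients (%s)\n", length(x),
              paste(sprintf("%s: %d", names(groups), groups),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.lans_cohort <- function(object, ...) {
  df <- data.frame(
    patient_id = vapply(object, `[[`, character(1), "patient_id"),
    pathology_group = vapply(object, `[[`, character(1), "pathology_group"),
    age = vapply(object, `[[`, numeric(1), "age_first_visit"),
    n_visits = vapply(object, function(r) nrow(r$visits), integer(1)),
    row.names = NULL
  )
  cat("Cohort of", nrow(df), "patients\n")
  print(stats::aggregate(cbind(age, n_visits) ~ pathology_group, df,
                         function(v) round(stats::median(v), 1)))
  invisible(df)
}

#' @export
`[.lans_cohort` <- function(x, i) {
  new_lans_cohort(unclass(x)[i])
}
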