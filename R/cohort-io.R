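# Three-table CSV schema: the paper-style data mix per-patient quantities
# (demographics, last-scan biomarkers) with per-visit quantities (CDR-SB,
# hippocampal volume), so the cohort is serialized as patients / visits /
# biomarkers tables joined on patient_id.

PATIENTS_COLS <- c("patient_id", "cohort", "age_first_visit", "sex",
                   "clinical_dx", "symptom_duration", "pathology_group",
                   "semantic_memory_impaired")
VISITS_COLS <- c("patient_id", "time_from_baseline", "cdr_sb",
                 "hippocampal_volume_adj")
BIOMARKERS_COLS <- c("patient_id", IMAGING_FIELDS, "amyloid_tracer",
                     FLUID_FIELDS)

#' Read a cohort from its three CSV tables
#'
#' Joins per-patient, per-visit and biomarker tables on \code{patient_id}.
#' Visits are attached sorted by time; patients absent from the biomarkers
#' table get no imaging/fluid panels (downstream features become
#' unavailable, never zero). Empty cells are missing values; sentinel codes
#' are not interpreted.
#'
#' @param patients_csv,visits_csv,biomarkers_csv file paths. The visits and
#'   biomarkers tables may be omitted (\code{NULL}).
#' @return A \code{lans_cohort}: a named list of \code{\link{lans_patient}}
#'   records.
#' @seealso \code{\link{write_cohort}} for the inverse operation.
#' @export
read_cohort <- function(patients_csv, visits_csv = NULL,
                        biomarkers_csv = NULL) {
  pat <- read_checked_csv(patients_csv, PATIENTS_COLS,
                          numeric_cols = c("age_first_visit",
                                           "symptom_duration"))
  if (anyDuplicated(pat$patient_id)) {
    stop("duplicate patient_id rows in ", patients_csv, call. = FALSE)
  }
  vis <- if (is.null(visits_csv)) NULL else {
    read_checked_csv(visits_csv, VISITS_COLS,
                     numeric_cols = setdiff(VISITS_COLS, "patient_id"))
  }
  if (!is.null(vis) && nrow(vis)) {
    key <- paste(vis$patient_id, vis$time_from_baseline)
    if (anyDuplicated(key)) {
      rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      stop("duplicate (patient_id, time) visit rows: ",
           paste(rows, collapse = ", "), call. = FALSE)
    }
  }
  bio <- if (is.null(biomarkers_csv)) NULL else {
    read_checked_csv(biomarkers_csv, BIOMARKERS_COLS,
                     numeric_cols = setdiff(BIOMARKERS_COLS,
                                            c("patient_id", "amyloid_tracer")))
  }
  if (!is.null(bio) && anyDuplicated(bio$patient_id)) {
    stop("duplicate patient_id rows in ", biomarkers_csv, call. = FALSE)
  }

  records <- lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    pv <- if (is.null(vis)) NULL else vis[vis$patient_id == p$patient_id, ]
    imaging <- fluids <- NULL
    if (!is.null(bio)) {
      b <- bio[bio$patient_id == p$patient_id, ]
      if (nrow(b) == 1L) {
        img <- as.list(b[, c(IMAGING_FIELDS, "amyloid_tracer")])
        if (any(!is.na(unlist(img[IMAGING_FIELDS])))) imaging <- img
        fl <- as.list(b[, FLUID_FIELDS])
        if (any(!is.na(unlist(fl)))) fluids <- fl
      }
    }
    lans_patient(
      patient_id = as.character(p$patient_id),
      cohort = p$cohort,
      age_first_visit = p$age_first_visit,
      sex = p$sex,
      clinical_dx = p$clinical_dx,
      symptom_duration = p$symptom_duration,
      visits = if (is.null(pv) || !nrow(pv)) NULL else
        pv[, setdiff(VISITS_COLS, "patient_id")],
      imaging = imaging,
      fluids = fluids,
      pathology_group = p$pathology_group,
      semantic_memory_impaired = parse_tristate_logical(
        p$semantic_memory_impaired)
    )
  })
  new_lans_cohort(records)
}

read_checked_csv <- function(path, expected_cols, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, expected_cols, drop = FALSE]
  for (col in numeric_cols) {
    raw <- df[[col]]
    blank <- is.na(raw) | raw == ""
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- !blank & is.na(parsed)
    if (any(bad)) {
      stop(sprintf("non-numeric value in %s column '%s' (rows %s)", path,
                   col, paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    parsed[blank] <- NA_real_
    df[[col]] <- parsed
  }
  for (col in setdiff(expected_cols, numeric_cols)) {
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  df
}

parse_tristate_logical <- function(x) {
  if (is.na(x)) return(NA)
  v <- toupper(as.character(x))
  if (v %in% c("TRUE", "1")) return(TRUE)
  if (v %in% c("FALSE", "0")) return(FALSE)
  stop("invalid logical value: ", x, call. = FALSE)
}

#' Write a cohort to the three-table CSV schema
#'
#' Inverse of \code{\link{read_cohort}}: \code{read_cohort} on the written
#' files reconstructs the cohort field-for-field, including missingness.
#' Missing values are written as empty cells.
#'
#' @param cohort a \code{lans_cohort}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lans_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, cohort = r$cohort,
               age_first_visit = r$age_first_visit, sex = r$sex,
               clinical_dx = r$clinical_dx,
               symptom_duration = r$symptom_duration,
               pathology_group = r$pathology_group,
               semantic_memory_impaired = r$semantic_memory_impaired,
               stringsAsFactors = FALSE)
  }))
  vis <- do.call(rbind, lapply(cohort, function(r) {
    if (!nrow(r$visits)) return(NULL)
    cbind(data.frame(patient_id = r$patient_id, stringsAsFactors = FALSE),
          r$visits)
  }))
  if (is.null(vis)) {
    vis <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(VISITS_COLS))), VISITS_COLS)
  }
  bio <- do.call(rbind, lapply(cohort, function(r) {
    if (is.null(r$imaging) && is.null(r$fluids)) return(NULL)
    img <- r$imaging %||%
      c(lapply(stats::setNames(IMAGING_FIELDS, IMAGING_FIELDS),
               function(f) NA_real_), list(amyloid_tracer = NA_character_))
    fl <- r$fluids %||%
      lapply(stats::setNames(FLUID_FIELDS, FLUID_FIELDS),
             function(f) NA_real_)
    cbind(data.frame(patient_id = r$patient_id, stringsAsFactors = FALSE),
          as.data.frame(img[c(IMAGING_FIELDS, "amyloid_tracer")]),
          as.data.frame(fl[FLUID_FIELDS]))
  }))
  if (is.null(bio)) {
    bio <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(BIOMARKERS_COLS))),
      BIOMARKERS_COLS)
  }
  paths <- c(patients = file.path(dir, "patients.csv"),
             visits = file.path(dir, "visits.csv"),
             biomarkers = file.path(dir, "biomarkers.csv"))
  utils::write.csv(pat, paths["patients"], row.names = FALSE, na = "")
  utils::write.csv(vis, paths["visits"], row.names = FALSE, na = "")
  utils::write.csv(bio, paths["biomarkers"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Write feature/likelihood tables and a metrics file
#'
#' Writes one CSV per table plus a JSON metrics file with deterministic
#' column and key order, so re-running on identical inputs is byte-identical.
#'
#' @param features data frame of per-patient feature flags (may be NULL).
#' @param likelihoods data frame of per-patient likelihood assignments.
#' @param metrics named list (scalars or nested lists) of summary metrics.
#' @param out_dir output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(features = NULL, likelihoods = NULL, metrics = NULL,
                         out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(features)) {
    stopifnot(nrow(features) > 0)
    p <- file.path(out_dir, "features.csv")
    utils::write.csv(features[, sort_stable_first(names(features)),
                              drop = FALSE], p, row.names = FALSE, na = "")
    paths["features"] <- p
  }
  if (!is.null(likelihoods)) {
    stopifnot(nrow(likelihoods) > 0)
    p <- file.path(out_dir, "likelihoods.csv")
    utils::write.csv(likelihoods[, sort_stable_first(names(likelihoods)),
                                 drop = FALSE], p, row.names = FALSE, na = "")
    paths["likelihoods"] <- p
  }
  if (!is.null(metrics)) {
    p <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics[order(names(metrics))], p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["metrics"] <- p
  }
  invisible(paths)
}

# keep patient_id first, remaining columns in original order
sort_stable_first <- function(cols) {
  c(intersect("patient_id", cols), setdiff(cols, "patient_id"))
}
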