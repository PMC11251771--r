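#' Abnormality threshold configuration
#'
#' Builds the full set of biomarker abnormality cut-points used to
#' operationalize the LANS features, in one of two cohort "dialects" that
#' differ by PET processing pipeline and tracer:
#'
#' \itemize{
#'   \item \code{MAYO}: FDG-PET meta-ROI abnormal at SUVR <= 1.47, amyloid-PET
#'     (PiB) positive at >= 1.48, tau-PET (flortaucipir) positive at >= 1.29,
#'     plasma pTau181 negative below 2.56 pg/ml.
#'   \item \code{ADNI}: FDG-PET meta-ROI abnormal at <= 1.21, amyloid-PET
#'     positive at >= 1.11 (florbetapir) or >= 1.0818 (florbetaben), tau-PET
#'     positive at >= 1.29, plasma pTau181 negative below 17.7 pg/ml.
#' }
#'
#' CSF cut-points are shared across dialects (Elecsys assays): Abeta42
#' abnormal at <= 1026 pg/ml, P-tau181 abnormal at >= 22 pg/ml, P-tau/Abeta42
#' ratio abnormal at >= 0.023.
#'
#' The IMT-ratio cut (\code{imt_abnormal_min}) and the disproportionate-
#' atrophy Z cut (\code{hippo_z_abnormal_max}) are data-derived (see
#' \code{\link{derive_atrophy_cutoff}} and \code{\link{roc_optimal_threshold}})
#' and default to \code{NA} until installed; features depending on them are
#' reported unavailable while unset.
#'
#' @param dialect "MAYO" or "ADNI".
#' @param ... named overrides of any config field.
#' @return An object of class \code{lans_config}: a named list with fields
#'   \code{age_cutoff}, \code{cdr_sb_mild_max}, \code{fdg_meta_roi_abnormal_max},
#'   \code{amyloid_abnormal_min} (named numeric, one entry per tracer),
#'   \code{tau_pet_abnormal_min}, \code{csf_abeta42_abnormal_max},
#'   \code{csf_ptau_abnormal_min}, \code{csf_ratio_abnormal_min},
#'   \code{plasma_ptau_abnormal_min}, \code{imt_abnormal_min},
#'   \code{hippo_z_abnormal_max}, \code{include_semantic_feature},
#'   \code{imt_template_volumes} (amygdala/hippocampus weights for the IMT
#'   denominator), and \code{dialect}.
#' @examples
#' cfg <- lans_thresholds("MAYO")
#' cfg$fdg_meta_roi_abnormal_max  # 1.47
#' lans_thresholds("ADNI", age_cutoff = 70)$age_cutoff
#' @export
lans_thresholds <- function(dialect = c("MAYO", "ADNI"), ...) {
  dialect <- match.arg(dialect)
  base <- list(
    age_cutoff = 75,
    cdr_sb_mild_max = 4,
    tau_pet_abnormal_min = 1.29,
    csf_abeta42_abnormal_max = 1026,
    csf_ptau_abnormal_min = 22,
    csf_ratio_abnormal_min = 0.023,
    imt_abnormal_min = NA_real_,
    hippo_z_abnormal_max = NA_real_,
    include_semantic_feature = FALSE,
    # template region volumes weighting the IMT denominator
    # (hippocampus:amygdala = 4:1)
    imt_template_volumes = c(amygdala = 1, hippocampus = 4),
    dialect = dialect
  )
  if (dialect == "MAYO") {
    base$fdg_meta_roi_abnormal_max <- 1.47
    base$amyloid_abnormal_min <- c(PIB = 1.48)
    base$plasma_ptau_abnormal_min <- 2.56
  } else {
    base$fdg_meta_roi_abnormal_max <- 1.21
    base$amyloid_abnormal_min <- c(FLORBETAPIR = 1.11, FLORBETABEN = 1.0818)
    base$plasma_ptau_abnormal_min <- 17.7
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown)) {
      stop("unknown threshold field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    base[names(overrides)] <- overrides
  }
  validate_config(structure(base, class = "lans_config"))
}

validate_config <- function(cfg) {
  numeric_fields <- c("age_cutoff", "cdr_sb_mild_max",
                      "fdg_meta_roi_abnormal_max", "tau_pet_abnormal_min",
                      "csf_abeta42_abnormal_max", "csf_ptau_abnormal_min",
                      "csf_ratio_abnormal_min", "plasma_ptau_abnormal_min")
  for (f in numeric_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("threshold field '", f, "' must be a finite number", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$amyloid_abnormal_min) ||
      is.null(names(cfg$amyloid_abnormal_min)) ||
      !all(names(cfg$amyloid_abnormal_min) %in% AMYLOID_TRACERS)) {
    stop("amyloid_abnormal_min must be a named numeric with tracer names",
         call. = FALSE)
  }
  if (!is.logical(cfg$include_semantic_feature)) {
    stop("include_semantic_feature must be logical", call. = FALSE)
  }
  cfg
}

#' Load a threshold configuration from a YAML or JSON file
#'
#' Reads partial threshold overrides from a structured-text file and fills
#' every unspecified field from the dialect defaults of
#' \code{\link{lans_thresholds}}. An empty or missing-keys file therefore
#' returns the full printed dialect table.
#'
#' @param config_file path to a YAML (.yml/.yaml) or JSON (.json) file, or
#'   \code{NULL} for pure defaults.
#' @param dialect "MAYO" or "ADNI".
#' @return A \code{lans_config} object.
#' @examples
#' load_threshold_config(NULL, "MAYO")$fdg_meta_roi_abnormal_max  # 1.47
#' @export
load_threshold_config <- function(config_file = NULL,
                                  dialect = c("MAYO", "ADNI")) {
  dialect <- match.arg(dialect)
  overrides <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config_file))
    raw <- if (ext == "json") {
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config_file)
    }
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
    if (anyDuplicated(names(raw))) {
      dup <- unique(names(raw)[duplicated(names(raw))])
      stop("duplicate config key(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    overrides <- raw
    # amyloid map may arrive as a list from YAML/JSON
    if (!is.null(overrides$amyloid_abnormal_min)) {
      overrides$amyloid_abnormal_min <- unlist(overrides$amyloid_abnormal_min)
    }
    if (!is.null(overrides$imt_template_volumes)) {
      overrides$imt_template_volumes <- unlist(overrides$imt_template_volumes)
    }
  }
  do.call(lans_thresholds, c(list(dialect = dialect), overrides))
}

#' @export
print.lans_config <- function(x, ...) {
  cat("LANS threshold configuration (", x$dialect, " dialect)\n", sep = "")
  cat(sprintf("  age >= %g y; mild syndrome: CDR-SB <= %g\n",
              x$age_cutoff, x$cdr_sb_mild_max))
  cat(sprintf("  FDG meta-ROI abnormal <= %g\n", x$fdg_meta_roi_abnormal_max))
  cat("  amyloid-PET positive >=:",
      paste(sprintf("%s %g", names(x$amyloid_abnormal_min),
                    x$amyloid_abnormal_min), collapse = ", "), "\n")
  cat(sprintf("  tau-PET positive >= %g\n", x$tau_pet_abnormal_min))
  cat(sprintf("  CSF: Abeta42 <= %g, P-tau >= %g, P-tau/Abeta42 >= %g\n",
              x$csf_abeta42_abnormal_max, x$csf_ptau_abnormal_min,
              x$csf_ratio_abnormal_min))
  cat(sprintf("  plasma pTau181 negative < %g pg/ml\n",
              x$plasma_ptau_abnormal_min))
  cat(sprintf("  IMT ratio abnormal >= %s; atrophy Z abnormal <= %s\n",
              format(x$imt_abnormal_min), format(x$hippo_z_abnormal_max)))
  invisible(x)
}

#' Apply a one-sided abnormality threshold
#'
#' Boundary inclusion follows the printed threshold tables: \code{"le"} and
#' \code{"ge"} include the boundary on the abnormal side (e.g. FDG meta-ROI
#' SUVR 1.47 with the Mayo cut "<= 1.47" is abnormal), \code{"lt"}/\code{"gt"}
#' exclude it (plasma pTau181 is negative strictly below its cut).
#'
#' @param value numeric vector of measurements (NA allowed).
#' @param cutoff scalar cut-point.
#' @param op one of "le", "ge", "lt", "gt": the comparison marking positivity.
#' @return logical vector, NA where value is NA.
#' @examples
#' apply_threshold(1.47, 1.47, "le")  # TRUE: hypometabolic at the boundary
#' apply_threshold(1.48, 1.48, "ge")  # TRUE: amyloid positive
#' @export
apply_threshold <- function(value, cutoff, op = c("le", "ge", "lt", "gt")) {
  op <- match.arg(op)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  if (is.na(cutoff)) return(rep(NA, length(value)))
  switch(op,
         le = value <= cutoff,
         ge = value >= cutoff,
         lt = value < cutoff,
         gt = value > cutoff)
}
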