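# internal helpers shared across modules

TRISTATE <- c("MET", "NOT_MET", "UNAVAILABLE")
LIKELIHOOD_LEVELS <- c("NOT_LANS", "LOW", "MODERATE", "HIGH", "HIGHEST")
PATHOLOGY_GROUPS <- c("ADNC", "LATE", "ADNC_LATE", "OTHER", "UNKNOWN")
CLINICAL_DX <- c("AMNESTIC_MCI", "AMNESTIC_DEMENTIA", "OTHER")
COHORTS <- c("MAYO", "ADNI", "SYNTHETIC")
SEXES <- c("F", "M")
AMYLOID_TRACERS <- c("PIB", "FLORBETAPIR", "FLORBETABEN")

IMAGING_FIELDS <- c("inferior_temporal_suvr", "amygdala_suvr",
                    "hippocampus_suvr", "amygdala_volume",
                    "hippocampus_volume", "fdg_meta_roi_suvr",
                    "amyloid_pet_suvr", "tau_pet_suvr",
                    "raw_hippocampal_volume", "icv")

FLUID_FIELDS <- c("csf_abeta42", "csf_ptau181", "csf_ptau_abeta_ratio",
                  "plasma_ptau181")

tristate <- function(x) {
  stopifnot(all(x %in% TRISTATE))
  x
}

# logical (possibly NA) -> tri-state
as_tristate <- function(flag) {
  ifelse(is.na(flag), "UNAVAILABLE", ifelse(flag, "MET", "NOT_MET"))
}

is_met <- function(x) !is.na(x) & x == "MET"

likelihood_factor <- function(x) {
  factor(x, levels = LIKELIHOOD_LEVELS, ordered = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar field access tolerating NULL and NA
scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[1L])) NA_real_ else as.numeric(x[1L])
}

check_enum <- function(x, allowed, what, allow_na = FALSE) {
  bad <- !(x %in% allowed)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}
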