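# Synthetic clinicopathological cohort generator.
#
# Features are generated through latent continuous severities (limbic L,
# neocortical N) so that threshold/ROC machinery and the logistic classifier
# face correlated inputs: each feature draws a standard-normal latent
# u = rho * driver + sqrt(1 - rho^2) * noise and the continuous biomarker is
# placed on its measurement scale as an affine function of u anchored at the
# abnormality cut, so marginal threshold positivity equals the configured
# rate exactly in expectation. Setting rho = 0 gives the independence mode
# used for analytic checks.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the published clinicopathological cohort structure:
#' autopsy group sizes 75 (ADNC) / 81 (ADNC + LATE-NC) / 9 (LATE-NC);
#' per-group age spread matched to the printed interquartile ranges with the
#' location calibrated so that P(age >= 75) equals the printed age-feature
#' rate; per-group feature positivity and availability taken from the
#' printed feature-frequency table (numerators / denominators); MCI vs
#' dementia mix from the printed diagnosis counts; and group-dependent
#' annual CDR-SB slopes encoding the reported ordering (LATE-NC slowest,
#' ADNC fastest, comorbid intermediate — magnitudes are free parameters, not
#' published).
#'
#' @param group_sizes named integer vector over \{ADNC, ADNC_LATE, LATE,
#'   OTHER\}.
#' @param latent_rho correlation of feature latents with their driving
#'   severity (0 = independent features).
#' @param seed integer seed; all randomness flows from it.
#' @param thresholds a \code{lans_config} anchoring biomarker scales
#'   (default Mayo dialect).
#' @param ... overrides for any other config element (see the returned
#'   object for names).
#' @return A list of class \code{lans_sim_config}.
#' @export
sim_config <- function(group_sizes = c(ADNC = 75, ADNC_LATE = 81, LATE = 9,
                                       OTHER = 0),
                       latent_rho = 0.6, seed = 0L,
                       thresholds = lans_thresholds("MAYO"), ...) {
  groups <- c("ADNC", "ADNC_LATE", "LATE", "OTHER")
  stopifnot(all(names(group_sizes) %in% groups), all(group_sizes >= 0))
  gs <- stats::setNames(rep(0L, length(groups)), groups)
  gs[names(group_sizes)] <- as.integer(group_sizes)

  feature_rates <- list(
    ADNC      = c(age = 36 / 75, mild = 58 / 75, atrophy = 25 / 63,
                  limbic = 9 / 53, no_neocortical = 5 / 53,
                  low_tau = 7 / 60),
    ADNC_LATE = c(age = 53 / 81, mild = 66 / 81, atrophy = 38 / 54,
                  limbic = 15 / 33, no_neocortical = 7 / 33,
                  low_tau = 1 / 49),
    LATE      = c(age = 8 / 9, mild = 8 / 9, atrophy = 3 / 4,
                  limbic = 3 / 4, no_neocortical = 1 / 4, low_tau = 5 / 7)
  )
  feature_rates$OTHER <- feature_rates$ADNC
  availability <- list(
    ADNC      = c(mri = 63 / 75, fdg = 53 / 75, tau = 60 / 75),
    ADNC_LATE = c(mri = 54 / 81, fdg = 33 / 81, tau = 49 / 81),
    LATE      = c(mri = 4 / 9, fdg = 4 / 9, tau = 7 / 9)
  )
  availability$OTHER <- availability$ADNC
  # IQR-derived scales; locations calibrated so P(age >= cutoff) matches
  # the configured age-feature rate
  age_scale <- c(ADNC = (80.5 - 63.7), ADNC_LATE = (83.9 - 72.2),
                 LATE = (93.3 - 83.6), OTHER = (80.5 - 63.7)) /
    (2 * stats::qnorm(0.75))
  mci_prob <- c(ADNC = 48 / 75, ADNC_LATE = 51 / 81, LATE = 8 / 9,
                OTHER = 48 / 75)

  cfg <- list(
    group_sizes = gs,
    feature_rates = feature_rates,
    availability = availability,
    age_scale = age_scale,
    mci_prob = mci_prob,
    latent_rho = latent_rho,
    thresholds = thresholds,
    # generative IMT scale: cut anchoring positivity plus dispersion
    imt_generative_cut = 1.20,
    imt_dispersion = 0.10,
    fdg_meta_dispersion = 0.12,
    # tau-cascade route mix among tau-workup-available patients
    tau_route_probs = c(PET = 0.8, CSF = 0.1, PLASMA = 0.1),
    amyloid_negative_share = 0.7,  # of tau-feature-met PET-route patients
    # trajectory model: CDR-SB = baseline + slope * t + noise, clipped [0,18]
    slope_mean = c(ADNC = 1.4, ADNC_LATE = 1.0, LATE = 0.45, OTHER = 1.0),
    slope_sd = 0.35,
    visit_noise_sd = 0.5,
    visit_interval = 1,
    visits_range = c(2L, 7L),
    # adjusted hippocampal volume model (volume-residual units):
    # vol = b0 + b_cdr * cdr + subject intercept + atrophy shift + noise
    vol_intercept = 0,
    vol_cdr_slope = -0.05,
    vol_subject_sd = 0.5,
    vol_noise_sd = 0.2,
    atrophy_shift = -1.2,
    seed = as.integer(seed)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "lans_sim_config")
}

#' @export
print.lans_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  group sizes:", paste(sprintf("%s %d", names(x$group_sizes),
                                      x$group_sizes), collapse = ", "), "\n")
  cat(sprintf("  latent coupling rho = %.2f; seed = %d; dialect = %s\n",
              x$latent_rho, x$seed, x$thresholds$dialect))
  invisible(x)
}

clamp_rate <- function(p, what) {
  lo <- 5e-4
  if (any(p <= 0 | p >= 1)) {
    warning("rate for ", what, " outside (0,1); clamped", call. = FALSE)
    p <- pmin(pmax(p, lo), 1 - lo)
  }
  p
}

# latent feature draw: returns list(u, met) with P(met) = rate and
# cor(u, driver) = rho
draw_feature <- function(n, rate, driver, rho) {
  rate <- clamp_rate(rate, "feature")
  u <- rho * driver + sqrt(1 - rho^2) * stats::rnorm(n)
  list(u = u, met = u > stats::qnorm(1 - rate), q = stats::qnorm(1 - rate))
}

#' Generate a synthetic clinicopathological cohort
#'
#' Draws per-patient group labels, ages, diagnoses, latent limbic and
#' neocortical severities, continuous biomarkers calibrated so that
#' thresholding at the configured cuts reproduces the configured per-group
#' positivity rates, availability masking, and (by default) longitudinal
#' CDR-SB / hippocampal-volume visits via
#' \code{\link{generate_trajectories}}. Fully reproducible from
#' \code{cfg$seed}.
#'
#' The latent ground truth (pre-masking feature states, severities, routes)
#' is attached to the returned cohort and retrievable with
#' \code{\link{truth_table}}.
#'
#' @param cfg a \code{lans_sim_config}.
#' @param trajectories also generate longitudinal visits (default TRUE).
#' @return A \code{lans_cohort} with a \code{"truth"} attribute.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 1))
#' length(cohort)  # 165
#' @export
generate_cohort <- function(cfg = sim_config(), trajectories = TRUE) {
  stopifnot(inherits(cfg, "lans_sim_config"))
  set.seed(cfg$seed)
  groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
  n <- length(groups)
  if (n == 0L) stop("all group sizes are zero", call. = FALSE)
  th <- cfg$thresholds
  rho <- cfg$latent_rho

  # standard-normal severities within group; group differences in feature
  # prevalence enter through the per-group rates, which set the latent
  # cut-point for each feature
  latent_limbic <- stats::rnorm(n)
  latent_neocortical <- stats::rnorm(n)

  rate_of <- function(feature) {
    vapply(groups, function(g) cfg$feature_rates[[g]][[feature]], numeric(1))
  }
  avail_of <- function(kind) {
    vapply(groups, function(g) cfg$availability[[g]][[kind]], numeric(1))
  }

  # ages: spread from the printed IQRs, location calibrated to the age rate
  p_age <- clamp_rate(rate_of("age"), "age")
  sd_age <- cfg$age_scale[groups]
  mu_age <- th$age_cutoff - sd_age * stats::qnorm(1 - p_age)
  age <- stats::rnorm(n, mu_age, sd_age)
  age <- pmax(age, 55)
  age_met <- age >= th$age_cutoff

  # mild syndrome and diagnosis mix
  mild <- draw_feature(n, rate_of("mild"), -latent_neocortical, rho * 0.5)
  p_mci <- cfg$mci_prob[groups]
  p_mild <- clamp_rate(rate_of("mild"), "mild")
  dx_mci <- mild$met & stats::runif(n) < pmin(1, p_mci / p_mild)
  clinical_dx <- ifelse(dx_mci, "AMNESTIC_MCI", "AMNESTIC_DEMENTIA")
  baseline_cdr <- draw_baseline_cdr(dx_mci, mild$met)

  atrophy <- draw_feature(n, rate_of("atrophy"), latent_limbic, rho)
  limbic <- draw_feature(n, rate_of("limbic"), latent_limbic, rho)
  noneo <- draw_feature(n, rate_of("no_neocortical"), -latent_neocortical,
                        rho)
  lowtau <- draw_feature(n, rate_of("low_tau"), -latent_neocortical, rho)

  # FDG biomarkers on measurement scale, anchored at the dialect cuts
  imt_value <- cfg$imt_generative_cut +
    cfg$imt_dispersion * (limbic$u - limbic$q)
  hippocampus_suvr <- pmax(stats::rnorm(n, 0.95, 0.05), 0.6)
  amygdala_suvr <- pmax(stats::rnorm(n, 1.0, 0.05), 0.6)
  tv <- th$imt_template_volumes
  medial_mean <- (tv[["amygdala"]] * amygdala_suvr +
                    tv[["hippocampus"]] * hippocampus_suvr) / sum(tv)
  inferior_temporal_suvr <- imt_value * medial_mean
  fdg_meta <- th$fdg_meta_roi_abnormal_max +
    cfg$fdg_meta_dispersion * (noneo$u - noneo$q)
  fdg_meta <- pmax(fdg_meta, 0.5)

  tau_bio <- draw_tau_biomarkers(n, lowtau$met, cfg)

  mri_avail <- stats::runif(n) < avail_of("mri")
  fdg_avail <- stats::runif(n) < avail_of("fdg")
  tau_avail <- stats::runif(n) < avail_of("tau")

  sex <- sample(SEXES, n, replace = TRUE)
  icv <- stats::rnorm(n, ifelse(sex == "M", 1600, 1450), 110)

  ids <- sprintf("SYN%04d", seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    imaging <- list(
      inferior_temporal_suvr = if (fdg_avail[i])
        inferior_temporal_suvr[i] else NA,
      amygdala_suvr = if (fdg_avail[i]) amygdala_suvr[i] else NA,
      hippocampus_suvr = if (fdg_avail[i]) hippocampus_suvr[i] else NA,
      amygdala_volume = tv[["amygdala"]],
      hippocampus_volume = tv[["hippocampus"]],
      fdg_meta_roi_suvr = if (fdg_avail[i]) fdg_meta[i] else NA,
      amyloid_pet_suvr = if (tau_avail[i]) tau_bio$amyloid[i] else NA,
      amyloid_tracer = if (tau_avail[i] && !is.na(tau_bio$amyloid[i]))
        names(th$amyloid_abnormal_min)[1L] else NA,
      tau_pet_suvr = if (tau_avail[i]) tau_bio$tau_pet[i] else NA,
      raw_hippocampal_volume = NA,
      icv = if (mri_avail[i]) icv[i] else NA
    )
    fluids <- if (tau_avail[i]) {
      list(csf_abeta42 = tau_bio$csf_abeta42[i],
           csf_ptau181 = tau_bio$csf_ptau181[i],
           csf_ptau_abeta_ratio = NA,
           plasma_ptau181 = tau_bio$plasma[i])
    } else NULL
    records[[i]] <- lans_patient(
      patient_id = ids[i],
      cohort = "SYNTHETIC",
      age_first_visit = age[i],
      sex = sex[i],
      clinical_dx = clinical_dx[i],
      visits = data.frame(time_from_baseline = 0,
                          cdr_sb = baseline_cdr[i],
                          hippocampal_volume_adj = NA_real_),
      imaging = imaging,
      fluids = fluids,
      pathology_group = groups[i]
    )
  }
  cohort <- new_lans_cohort(records)

  truth <- data.frame(
    patient_id = ids, pathology_group = groups,
    latent_limbic = latent_limbic, latent_neocortical = latent_neocortical,
    age_met = age_met, mild_met = mild$met, atrophy_met = atrophy$met,
    limbic_met = limbic$met, no_neocortical_met = noneo$met,
    low_tau_met = lowtau$met, tau_route = tau_bio$route,
    imt_value = imt_value, fdg_meta = fdg_meta,
    mri_available = mri_avail, fdg_available = fdg_avail,
    tau_available = tau_avail, baseline_cdr = baseline_cdr,
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- truth
  if (trajectories) cohort <- generate_trajectories(cohort, cfg)
  cohort
}

# baseline CDR-SB in half-point steps: MCI mild, dementia mild (<= 4) or
# more severe (> 4) depending on the mild-syndrome flag
draw_baseline_cdr <- function(dx_mci, mild_met) {
  n <- length(dx_mci)
  cdr <- numeric(n)
  cdr[dx_mci] <- pmin(pmax(stats::rnorm(sum(dx_mci), 1.5, 1.0), 0.5), 4)
  dem_mild <- !dx_mci & mild_met
  cdr[dem_mild] <- pmin(pmax(stats::rnorm(sum(dem_mild), 3.2, 0.7), 0.5), 4)
  dem_sev <- !dx_mci & !mild_met
  cdr[dem_sev] <- pmin(pmax(stats::rnorm(sum(dem_sev), 6.5, 1.5), 4.5), 18)
  round(cdr * 2) / 2
}

# biomarker values realizing the tau-cascade feature through one of three
# measurement routes (PET / CSF / plasma)
draw_tau_biomarkers <- function(n, met, cfg) {
  th <- cfg$thresholds
  amyloid_cut <- th$amyloid_abnormal_min[[1L]]
  tau_cut <- th$tau_pet_abnormal_min
  plasma_cut <- th$plasma_ptau_abnormal_min
  route <- sample(names(cfg$tau_route_probs), n, replace = TRUE,
                  prob = cfg$tau_route_probs)
  amyloid <- tau_pet <- csf_abeta42 <- csf_ptau181 <- plasma <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (route[i] == "PET") {
      if (met[i] && stats::runif(1) < cfg$amyloid_negative_share) {
        amyloid[i] <- amyloid_cut - stats::runif(1, 0.02, 0.30)
      } else if (met[i]) {
        amyloid[i] <- amyloid_cut + stats::runif(1, 0.02, 1.0)
        tau_pet[i] <- tau_cut - stats::runif(1, 0.01, 0.15)
      } else {
        amyloid[i] <- amyloid_cut + stats::runif(1, 0.02, 1.0)
        if (stats::runif(1) < 0.9) {
          tau_pet[i] <- tau_cut + stats::runif(1, 0.01, 0.9)
        }  # else tau-PET missing: amyloid-positive, cannot establish low tau
      }
    } else if (route[i] == "CSF") {
      if (met[i]) {
        csf_abeta42[i] <- stats::runif(1, 1050, 1800)
        csf_ptau181[i] <- stats::runif(1, 8, 20)
      } else {
        csf_abeta42[i] <- stats::runif(1, 400, 1000)
        csf_ptau181[i] <- stats::runif(1, 23, 60)
      }
    } else {
      plasma[i] <- if (met[i]) stats::runif(1, 0.4, 0.95) * plasma_cut
                   else stats::runif(1, 1.05, 2.5) * plasma_cut
    }
  }
  list(route = route, amyloid = amyloid, tau_pet = tau_pet,
       csf_abeta42 = csf_abeta42, csf_ptau181 = csf_ptau181, plasma = plasma)
}

#' Generate longitudinal CDR-SB and volume trajectories
#'
#' Expands each record's visits at the configured interval: CDR-SB follows
#' baseline + per-subject slope x time + noise, clipped to [0, 18], with
#' group-dependent mean slopes; adjusted hippocampal volume follows a linear
#' model in concurrent CDR-SB with a per-subject intercept and a negative
#' shift for patients whose ground truth carries disproportionate atrophy.
#' Volume visits are masked for patients without MRI availability.
#'
#' Reproducible: uses \code{cfg$seed + 1} so it composes deterministically
#' with \code{\link{generate_cohort}}.
#'
#' @param cohort a \code{lans_cohort} (normally synthetic, carrying a truth
#'   attribute; records without truth get no atrophy shift).
#' @param cfg a \code{lans_sim_config}.
#' @return The cohort with visits filled in.
#' @export
generate_trajectories <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "lans_sim_config"))
  set.seed(cfg$seed + 1L)
  truth <- attr(cohort, "truth")
  out <- lapply(cohort, function(r) {
    g <- r$pathology_group
    slope_mu <- if (g %in% names(cfg$slope_mean)) cfg$slope_mean[[g]]
                else mean(cfg$slope_mean)
    slope <- stats::rnorm(1, slope_mu, cfg$slope_sd)
    nv_choices <- seq(cfg$visits_range[1L], cfg$visits_range[2L])
    n_vis <- if (length(nv_choices) == 1L) nv_choices
             else sample(nv_choices, 1L)
    times <- seq(0, by = cfg$visit_interval, length.out = n_vis)
    baseline <- if (nrow(r$visits)) r$visits$cdr_sb[1L] else 1
    cdr <- baseline + slope * times +
      stats::rnorm(n_vis, 0, cfg$visit_noise_sd)
    cdr[1L] <- baseline  # baseline visit anchors the drawn score
    cdr <- pmin(pmax(cdr, 0), 18)
    atrophy_true <- FALSE
    mri <- TRUE
    if (!is.null(truth) && r$patient_id %in% truth$patient_id) {
      row <- truth[truth$patient_id == r$patient_id, ]
      atrophy_true <- row$atrophy_met
      mri <- row$mri_available
    }
    vol <- if (mri) {
      cfg$vol_intercept + cfg$vol_cdr_slope * cdr +
        stats::rnorm(1, 0, cfg$vol_subject_sd) +
        cfg$atrophy_shift * atrophy_true +
        stats::rnorm(n_vis, 0, cfg$vol_noise_sd)
    } else rep(NA_real_, n_vis)
    r$visits <- data.frame(time_from_baseline = times, cdr_sb = cdr,
                           hippocampal_volume_adj = vol)
    r
  })
  res <- new_lans_cohort(out)
  attr(res, "truth") <- truth
  res
}

#' Ground-truth table of a synthetic cohort
#'
#' Returns the pre-masking latent severities, true feature states,
#' tau-measurement routes and availability indicators recorded at
#' generation time — the oracle against which downstream feature recovery
#' is tested. Masking hides measurements from the records but never alters
#' this table.
#'
#' @param cohort a synthetic \code{lans_cohort} from
#'   \code{\link{generate_cohort}}.
#' @return Data frame, one row per patient.
#' @export
truth_table <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    stop("cohort carries no ground truth; truth_table() applies to ",
         "synthetic cohorts from generate_cohort()", call. = FALSE)
  }
  truth
}
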