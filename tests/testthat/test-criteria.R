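cfg <- lans_thresholds("MAYO", imt_abnormal_min = 1.2,
                       hippo_z_abnormal_max = -0.5)

test_that("core feature requires an amnestic syndrome of >= 2 years", {
  expect_true(evaluate_core(make_patient(dx = "AMNESTIC_MCI")))
  expect_false(evaluate_core(make_patient(dx = "OTHER")))
  expect_false(evaluate_core(make_patient(dx = "AMNESTIC_DEMENTIA",
                                          duration = 1.0)))
  expect_true(evaluate_core(make_patient(dx = "AMNESTIC_DEMENTIA",
                                         duration = 2.0)))
  # unknown duration does not disqualify
  expect_true(evaluate_core(make_patient(dx = "AMNESTIC_DEMENTIA")))
})

test_that("standard features follow the printed operationalization", {
  # an older MCI patient with atrophy carries all three standard features
  p <- make_patient(age = 86.2, dx = "AMNESTIC_MCI", cdr = 0.5)
  std <- evaluate_standard(p, cfg, atrophy_flag = "MET")
  expect_identical(std$age_ge_cutoff, "MET")
  expect_identical(std$mild_syndrome, "MET")
  expect_identical(std$disproportionate_atrophy, "MET")

  # the age cut is strict at 75
  expect_identical(
    evaluate_standard(make_patient(age = 74.9), cfg)$age_ge_cutoff,
    "NOT_MET")
  expect_identical(
    evaluate_standard(make_patient(age = 75), cfg)$age_ge_cutoff, "MET")

  # dementia with CDR-SB exactly 4 is still a mild syndrome
  pd <- make_patient(dx = "AMNESTIC_DEMENTIA", cdr = 4.0)
  expect_identical(evaluate_standard(pd, cfg)$mild_syndrome, "MET")
  pd5 <- make_patient(dx = "AMNESTIC_DEMENTIA", cdr = 4.5)
  expect_identical(evaluate_standard(pd5, cfg)$mild_syndrome, "NOT_MET")
  # dementia without a baseline CDR-SB cannot be graded
  pna <- make_patient(dx = "AMNESTIC_DEMENTIA", cdr = NA, visits = NULL)
  expect_identical(evaluate_standard(pna, cfg)$mild_syndrome, "UNAVAILABLE")
})

test_that("tau cascade follows the PET > CSF > plasma priority", {
  # (i) negative amyloid-PET suffices (the low-centiloid LATE-NC pattern)
  neg_amyloid <- list(amyloid_pet_suvr = 1.30, amyloid_tracer = "PIB")
  r <- evaluate_tau_cascade(neg_amyloid, NULL, cfg)
  expect_identical(r$status, "MET")
  expect_identical(r$scenario, "AMYLOID_PET")

  # (ii) amyloid-positive, tau-PET 1.26 < 1.29 is tau-negative
  amy_tau <- list(amyloid_pet_suvr = 2.0, amyloid_tracer = "PIB",
                  tau_pet_suvr = 1.26)
  r <- evaluate_tau_cascade(amy_tau, NULL, cfg)
  expect_identical(r$status, "MET")
  expect_identical(r$scenario, "TAU_PET")
  # tau-positive fails the feature
  amy_tau$tau_pet_suvr <- 1.29
  expect_identical(evaluate_tau_cascade(amy_tau, NULL, cfg)$status,
                   "NOT_MET")

  # amyloid-positive with no tau-PET cannot establish low neocortical tau,
  # even with negative fluids on file
  amy_only <- list(amyloid_pet_suvr = 2.0, amyloid_tracer = "PIB")
  clean_fluids <- list(csf_abeta42 = 1500, csf_ptau181 = 15)
  r <- evaluate_tau_cascade(amy_only, clean_fluids, cfg)
  expect_identical(r$status, "NOT_MET")

  # (iii) CSF negativity requires every present measure negative
  r <- evaluate_tau_cascade(NULL, clean_fluids, cfg)
  expect_identical(r$status, "MET")
  expect_identical(r$scenario, "CSF")
  expect_identical(
    evaluate_tau_cascade(NULL, list(csf_abeta42 = 1500, csf_ptau181 = 25),
                         cfg)$status, "NOT_MET")
  expect_identical(
    evaluate_tau_cascade(NULL, list(csf_abeta42 = 1000), cfg)$status,
    "NOT_MET")
  # ratio computed from components when absent: 25/800 > 0.023 -> positive
  expect_identical(
    evaluate_tau_cascade(NULL, list(csf_abeta42 = 800, csf_ptau181 = 25),
                         cfg)$status, "NOT_MET")

  # (iv) plasma fallback at the Mayo cut
  r <- evaluate_tau_cascade(NULL, list(plasma_ptau181 = 2.0), cfg)
  expect_identical(r$status, "MET")
  expect_identical(r$scenario, "PLASMA")
  expect_identical(
    evaluate_tau_cascade(NULL, list(plasma_ptau181 = 2.56), cfg)$status,
    "NOT_MET")

  # (v) nothing available
  r <- evaluate_tau_cascade(NULL, NULL, cfg)
  expect_identical(r$status, "UNAVAILABLE")
  expect_identical(r$scenario, "NONE")
})

test_that("advanced features resolve FDG measures against their cuts", {
  img <- list(inferior_temporal_suvr = 1.3, amygdala_suvr = 1.0,
              hippocampus_suvr = 1.0, amygdala_volume = 1,
              hippocampus_volume = 4, fdg_meta_roi_suvr = 1.60)
  adv <- evaluate_advanced(img, cfg, "MET")
  expect_identical(adv$limbic_hypometabolism, "MET")    # IMT 1.3 >= 1.2
  expect_identical(adv$no_neocortical_pattern, "MET")   # 1.60 > 1.47
  expect_identical(adv$low_neocortical_tau, "MET")

  img$fdg_meta_roi_suvr <- 1.40  # neocortical hypometabolism present
  expect_identical(evaluate_advanced(img, cfg, "MET")$no_neocortical_pattern,
                   "NOT_MET")
  img$fdg_meta_roi_suvr <- 1.47  # boundary is abnormal
  expect_identical(evaluate_advanced(img, cfg, "MET")$no_neocortical_pattern,
                   "NOT_MET")

  # missing IMT inputs leave limbic hypometabolism unavailable
  expect_identical(
    evaluate_advanced(list(fdg_meta_roi_suvr = 1.6), cfg,
                      "UNAVAILABLE")$limbic_hypometabolism, "UNAVAILABLE")
  # an unset IMT cut also leaves it unavailable
  cfg_nocut <- lans_thresholds("MAYO")
  expect_identical(
    evaluate_advanced(img, cfg_nocut, "MET")$limbic_hypometabolism,
    "UNAVAILABLE")
})

test_that("likelihood assignment agrees with the exhaustive rule oracle", {
  for (semantic in c(FALSE, TRUE)) {
    cfg_s <- lans_thresholds("MAYO", include_semantic_feature = semantic)
    s_max <- if (semantic) 4L else 3L
    for (core in c(TRUE, FALSE)) {
      for (s in 0:s_max) {
        for (a in 0:3) {
          got <- assign_likelihood(profile_from_counts(core, s, a, s_max),
                                   cfg_s)
          expect_identical(
            as.character(got$category),
            oracle_likelihood(core, s, a, s_max),
            label = sprintf("core=%s s=%d a=%d smax=%d", core, s, a, s_max))
          expect_equal(got$n_standard_met, if (semantic) s else min(s, 3L))
          expect_equal(got$n_advanced_met, a)
        }
      }
    }
  }
})

test_that("unavailable features count as not met and semantic is excluded", {
  # semantic MET is ignored unless configured in
  p_sem <- make_profile(TRUE, std = c("MET", "MET", "NOT_MET", "MET"))
  expect_identical(as.character(assign_likelihood(p_sem, cfg)$category),
                   "LOW")  # S = 2, A = 0
  cfg_sem <- lans_thresholds("MAYO", include_semantic_feature = TRUE)
  expect_identical(as.character(assign_likelihood(p_sem, cfg_sem)$category),
                   "MODERATE")  # S = 3 of 4

  # UNAVAILABLE never counts
  p_un <- make_profile(TRUE, std = c("MET", "MET", "UNAVAILABLE"),
                       adv = c("UNAVAILABLE", "UNAVAILABLE", "UNAVAILABLE"))
  got <- assign_likelihood(p_un, cfg)
  expect_equal(got$n_standard_met, 2L)
  expect_equal(got$n_advanced_met, 0L)
  expect_identical(as.character(got$category), "LOW")
})

test_that("single-feature promotion is monotone over all profiles", {
  features <- c("age_ge_cutoff", "mild_syndrome", "disproportionate_atrophy",
                "limbic_hypometabolism", "no_neocortical_pattern",
                "low_neocortical_tau")
  states <- expand.grid(rep(list(c("MET", "NOT_MET")), 6),
                        stringsAsFactors = FALSE)
  names(states) <- features
  for (i in seq_len(nrow(states))) {
    base <- c(list(core_met = TRUE, semantic_impairment = "NOT_MET"),
              as.list(states[i, ]))
    cat0 <- assign_likelihood(base, cfg)$category
    for (f in features) {
      if (base[[f]] == "MET") next
      up <- base
      up[[f]] <- "MET"
      expect_gte(as.integer(assign_likelihood(up, cfg)$category),
                 as.integer(cat0))
    }
  }
})

test_that("highest likelihood is reachable only with every feature met", {
  states <- expand.grid(rep(list(c("MET", "NOT_MET")), 6),
                        stringsAsFactors = FALSE)
  names(states) <- c("age_ge_cutoff", "mild_syndrome",
                     "disproportionate_atrophy", "limbic_hypometabolism",
                     "no_neocortical_pattern", "low_neocortical_tau")
  for (i in seq_len(nrow(states))) {
    prof <- c(list(core_met = TRUE, semantic_impairment = "NOT_MET"),
              as.list(states[i, ]))
    cat_i <- as.character(assign_likelihood(prof, cfg)$category)
    if (cat_i == "HIGHEST") {
      expect_true(all(unlist(states[i, ]) == "MET"))
    }
  }
})

test_that("cohort classification spans the category range and is monotone", {
  img_full <- list(inferior_temporal_suvr = 1.4, amygdala_suvr = 1.0,
                   hippocampus_suvr = 1.0, amygdala_volume = 1,
                   hippocampus_volume = 4, fdg_meta_roi_suvr = 1.6,
                   amyloid_pet_suvr = 1.3, amyloid_tracer = "PIB")
  low <- make_patient("LOW1", age = 68, dx = "AMNESTIC_DEMENTIA", cdr = 6)
  mod <- make_patient("MOD1", age = 80, dx = "AMNESTIC_MCI", cdr = 1)
  top <- make_patient("TOP1", age = 80, dx = "AMNESTIC_MCI", cdr = 1,
                      imaging = img_full)
  scores <- data.frame(patient_id = c("MOD1", "TOP1"), z_score = c(-2, -2))
  lk <- classify_cohort(list(low, mod, top), cfg, scores)
  got <- setNames(as.character(lk$likelihood), lk$patient_id)
  expect_identical(got[["LOW1"]], "LOW")       # S = 0, A = 0
  expect_identical(got[["MOD1"]], "MODERATE")  # S = 3, A = 0
  expect_identical(got[["TOP1"]], "HIGHEST")   # S = 3, A = 3

  # with no biomarkers at all, A is forced to 0: moderate is the ceiling
  bare <- lapply(1:6, function(i) {
    make_patient(sprintf("B%d", i), age = 70 + 2 * i, dx = "AMNESTIC_MCI",
                 cdr = 1)
  })
  lk_bare <- classify_cohort(bare, cfg)
  expect_true(all(lk_bare$likelihood <= "MODERATE"))
  expect_true(all(lk_bare$n_advanced_met == 0L))

  # granting an advanced feature never lowers the category
  mod_plus <- make_patient("MOD1", age = 80, dx = "AMNESTIC_MCI", cdr = 1,
                           imaging = list(amyloid_pet_suvr = 1.3,
                                          amyloid_tracer = "PIB"))
  lk2 <- classify_cohort(list(mod_plus), cfg, scores)
  expect_true(lk2$likelihood[1] >= "MODERATE")

  expect_error(classify_cohort(list(), cfg), "empty")
})
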