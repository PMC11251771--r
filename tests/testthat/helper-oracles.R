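# Independent oracles and fixture builders used across the suite.

# O(n^2) all-pairs concordance AUC (ties count one half)
oracle_auc <- function(scores, labels, direction = "HIGHER_IS_POSITIVE") {
  s <- if (direction == "HIGHER_IS_POSITIVE") scores else -scores
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan over midpoint candidates (independent re-derivation)
oracle_youden <- function(scores, labels, direction = "HIGHER_IS_POSITIVE") {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  res <- data.frame(th = cand, sens = NA_real_, spec = NA_real_)
  for (i in seq_along(cand)) {
    called <- if (direction == "HIGHER_IS_POSITIVE") scores > cand[i]
              else scores < cand[i]
    res$sens[i] <- sum(called & labels) / sum(labels)
    res$spec[i] <- sum(!called & !labels) / sum(!labels)
  }
  res$j <- res$sens + res$spec - 1
  jmax <- max(res$j)
  best <- res[res$j > jmax - 1e-12, , drop = FALSE]
  best <- best[best$sens > max(best$sens) - 1e-12, , drop = FALSE]
  best[which.min(best$th), ]
}

# logistic regression by hand-rolled iteratively reweighted least squares
oracle_irls_logistic <- function(X, y, tol = 1e-13, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# hand-enumerated rule table for the likelihood categories: rows are
# (S, A) -> category, written out literally from the certainty definitions
oracle_rule_table <- function(s_max) {
  if (s_max == 3) {
    rules <- rbind(
      c(3, 3, "HIGHEST"), c(3, 2, "HIGH"), c(3, 1, "HIGH"),
      c(3, 0, "MODERATE"),
      c(2, 3, "HIGH"), c(2, 2, "HIGH"), c(2, 1, "MODERATE"), c(2, 0, "LOW"),
      c(1, 3, "LOW"), c(1, 2, "LOW"), c(1, 1, "LOW"), c(1, 0, "LOW"),
      c(0, 3, "LOW"), c(0, 2, "LOW"), c(0, 1, "LOW"), c(0, 0, "LOW"))
  } else {
    rules <- rbind(
      c(4, 3, "HIGHEST"), c(4, 2, "HIGH"), c(4, 1, "HIGH"),
      c(4, 0, "MODERATE"),
      c(3, 3, "HIGH"), c(3, 2, "HIGH"), c(3, 1, "HIGH"), c(3, 0, "MODERATE"),
      c(2, 3, "HIGH"), c(2, 2, "HIGH"), c(2, 1, "MODERATE"), c(2, 0, "LOW"),
      c(1, 3, "LOW"), c(1, 2, "LOW"), c(1, 1, "LOW"), c(1, 0, "LOW"),
      c(0, 3, "LOW"), c(0, 2, "LOW"), c(0, 1, "LOW"), c(0, 0, "LOW"))
  }
  data.frame(s = as.integer(rules[, 1]), a = as.integer(rules[, 2]),
             category = rules[, 3], stringsAsFactors = FALSE)
}

oracle_likelihood <- function(core, s, a, s_max = 3) {
  if (!core) return("NOT_LANS")
  tab <- oracle_rule_table(s_max)
  tab$category[tab$s == s & tab$a == a]
}

# direct Pearson chi-square formula, no continuity correction
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

likelihood_factor_vec <- function(x) {
  factor(x, levels = c("NOT_LANS", "LOW", "MODERATE", "HIGH", "HIGHEST"),
         ordered = TRUE)
}

# longitudinal CDR-SB records with a known group slope
sim_traj_group <- function(prefix, n, slope, baseline = 1.5, n_vis = 5,
                           noise = 0.5, slope_sd = 0.2) {
  lapply(seq_len(n), function(i) {
    t <- seq(0, by = 1, length.out = n_vis)
    b_i <- slope + stats::rnorm(1, 0, slope_sd)
    cdr <- pmin(pmax(baseline + b_i * t + stats::rnorm(n_vis, 0, noise), 0),
                18)
    make_patient(sprintf("%s%03d", prefix, i),
                 visits = data.frame(time_from_baseline = t, cdr_sb = cdr,
                                     hippocampal_volume_adj = NA_real_))
  })
}

# strip class for exact cohort comparison
serialize_cohort <- function(cohort) {
  list(records = unclass(cohort), truth = attr(cohort, "truth"))
}

# minimal patient builder
make_patient <- function(id = "P1", age = 80, dx = "AMNESTIC_MCI",
                         sex = "F", cdr = 1.5, duration = NA,
                         imaging = NULL, fluids = NULL,
                         pathology = "UNKNOWN", visits = NULL,
                         semantic = NA) {
  if (is.null(visits) && !is.na(cdr)) {
    visits <- data.frame(time_from_baseline = 0, cdr_sb = cdr,
                         hippocampal_volume_adj = NA_real_)
  }
  lans_patient(patient_id = id, age_first_visit = age, sex = sex,
               clinical_dx = dx, symptom_duration = duration,
               visits = visits, imaging = imaging, fluids = fluids,
               pathology_group = pathology,
               semantic_memory_impaired = semantic)
}

# build a full feature profile for assign_likelihood from MET counts
make_profile <- function(core = TRUE, std = character(), adv = character()) {
  flag <- function(i, set) if (i <= length(set)) set[i] else "NOT_MET"
  list(core_met = core,
       age_ge_cutoff = flag(1, std), mild_syndrome = flag(2, std),
       disproportionate_atrophy = flag(3, std),
       semantic_impairment = flag(4, std),
       limbic_hypometabolism = flag(1, adv),
       no_neocortical_pattern = flag(2, adv),
       low_neocortical_tau = flag(3, adv))
}

profile_from_counts <- function(core, s, a, s_max = 3) {
  make_profile(core,
               std = rep(c("MET", "NOT_MET"), c(s, s_max - s)),
               adv = rep(c("MET", "NOT_MET"), c(a, 3 - a)))
}

# longitudinal cohort with known volume ~ CDR-SB fixed effects, for
# mixed-model recovery tests (independent of the package generator)
sim_volume_cohort <- function(n_subj = 85, intercept = 0.2, slope = -0.05,
                              ri_sd = 0.5, resid_sd = 0.2,
                              visits_range = 4:6) {
  lapply(seq_len(n_subj), function(i) {
    nv <- sample(visits_range, 1)
    t <- seq(0, by = 1, length.out = nv)
    cdr <- pmin(pmax(1 + 1.2 * t + stats::rnorm(nv, 0, 0.5), 0), 18)
    u <- stats::rnorm(1, 0, ri_sd)
    vol <- intercept + slope * cdr + u + stats::rnorm(nv, 0, resid_sd)
    make_patient(sprintf("SIM%03d", i),
                 visits = data.frame(time_from_baseline = t, cdr_sb = cdr,
                                     hippocampal_volume_adj = vol))
  })
}

# synthetic classifier feature tables with a controllable class signal,
# independent of the cohort generator
sim_feature_table <- function(n, shift = 1.5) {
  late <- rep(c(TRUE, FALSE), length.out = n)
  data.frame(
    patient_id = sprintf("F%03d", seq_len(n)),
    age = rnorm(n, 78 + 3 * late * shift / 1.5, 6),
    cdr_sb = pmax(rnorm(n, 2.5 - 0.5 * late * shift / 1.5, 1.5), 0),
    hippocampal_volume_adj = rnorm(n, -0.4 - 0.5 * late * shift, 0.6),
    imt_ratio = rnorm(n, 1.1 + 0.08 * late * shift, 0.08),
    fdg_meta_roi_suvr = rnorm(n, 1.45 + 0.05 * late * shift, 0.1),
    tau_positive = as.numeric(runif(n) < ifelse(late, 0.3, 0.8)),
    late_present = late)
}
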