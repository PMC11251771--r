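Package: lans
Title: Operationalized Clinical Criteria for a Limbic-Predominant Amnestic
    Neurodegenerative Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computational operationalization of clinical criteria
    for a limbic-predominant amnestic neurodegenerative syndrome (LANS): a
    rule-based likelihood engine over core, standard and advanced features
    derived from clinical visits, FDG-PET regional ratios, structural MRI and
    amyloid/tau biomarkers. Provides the inferior-to-medial temporal (IMT)
    FDG-PET ratio, intracranial-volume-adjusted hippocampal volume with a
    longitudinal mixed model of volume on clinical severity to score
    disproportionate hippocampal atrophy, ROC-derived abnormality cut-points,
    a tiered tau-biomarker positivity cascade, a calibrated synthetic
    clinicopathological cohort generator, and validation analyses: likelihood
    distributions by autopsy group, a logistic classifier of
    limbic-predominant age-related TDP-43 encephalopathy neuropathological
    change (LATE-NC), and mixed models of longitudinal Clinical Dementia
    Rating Sum of Boxes trajectories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
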