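# Shared cohort configurations for tests. Small four-profile cohorts for
# plumbing tests; two-arm null / planted-atrophy designs for the calibration
# and recovery studies.

tiny_cohort_config <- function(seed = 1L, q = 12, scans = 3) {
  cohort_config(
    n_patients = c(CIS = 3, RR = 4, PP = 3, SP = 3),
    n_scans = NULL,
    mean_scans_per_patient = c(CIS = scans, RR = scans, PP = scans, SP = scans),
    q = q, seed = seed
  )
}

# two-arm cohort with no group difference at all (RR and PP labels only)
null_two_arm_config <- function(seed, n_per_arm = 30, q = 68, scans = 3) {
  cohort_config(
    n_patients = c(RR = n_per_arm, PP = n_per_arm),
    n_scans = NULL,
    mean_scans_per_patient = c(RR = scans, PP = scans),
    q = q,
    atrophy_frac = c(RR = 0, PP = 0),
    atrophy_depth = c(RR = 0, PP = 0),
    longitudinal_rate = c(RR = 0, PP = 0),
    age_mean = c(RR = 33.6, PP = 40.4),
    age_sd = c(RR = 7.1, PP = 6.3),
    sex_frac_female = c(RR = 0.82, PP = 0.66),
    seed = seed
  )
}

# two-arm cohort with a planted atrophy contrast: the PP arm is thinned by
# `depth` mm on 30% of ROIs, the RR arm is untouched
planted_two_arm_config <- function(depth, seed, n_per_arm = 30, q = 68,
                                   scans = 3) {
  cfg <- null_two_arm_config(seed, n_per_arm = n_per_arm, q = q, scans = scans)
  cfg$atrophy_frac <- c(RR = 0.30, PP = 0.30)
  cfg$atrophy_depth <- c(RR = 0, PP = depth)
  validate_cohort_config <- getFromNamespace("validate_cohort_config", "gmconnect")
  validate_cohort_config(cfg)
  cfg
}

# shorthand: simulate, build connectomes
built_cohort <- function(cfg) cohort_connectomes(simulate_cohort(cfg))
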