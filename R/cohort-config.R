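#' Configuration for the synthetic longitudinal cohort simulator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: four multiple
#' sclerosis clinical profiles (CIS, RR, PP, SP) with per-profile patient and
#' scan counts, a longitudinal scan schedule (6-monthly visits for the first
#' three years, then yearly), an atlas parcellation of `q` regions of interest
#' (ROIs), and profile-dependent cortical thinning. Defaults reproduce the
#' structure of the reference cohort: 90 patients (12 CIS, 30 RR, 20 PP, 28
#' SP) contributing 652 scans (64, 233, 140, 215).
#'
#' The generative model for the thickness of ROI `i` of patient `p` at time
#' `t` (years since baseline) is
#' \deqn{x_{pit} = \mu_i - a(g_p, i) - \rho(g_p)\,t + b_p + \epsilon_{pit}}
#' where `mu_i` is the baseline thickness, `a(g, i)` the atrophy depth (mm) if
#' ROI `i` belongs to profile `g`'s affected set and 0 otherwise, `rho(g)` the
#' longitudinal thinning rate (mm/year), `b_p ~ N(0, subject_sd^2)` a patient
#' random intercept and `epsilon ~ N(0, noise_sd^2)` measurement noise.
#' Values are clipped at 0.5 mm to stay physiologic. Affected-ROI sets are
#' nested across profiles (a seeded ROI permutation is shared, each profile
#' takes its leading fraction), so atrophy burden is ordered CIS < RR < SP/PP.
#'
#' @param n_patients Named vector, patients per profile.
#' @param n_scans Named vector, total scans per profile, or `NULL` to draw
#'   per-patient scan counts from a truncated Poisson with mean
#'   `mean_scans_per_patient`.
#' @param mean_scans_per_patient Named vector of per-profile mean scan counts;
#'   ignored when `n_scans` is given (counts are then drawn and adjusted to
#'   match the totals exactly).
#' @param q Number of ROIs (68 for the FSAverage atlas, 360 for Glasser 2016).
#' @param n_features Morphometric features per ROI; 1 (mean thickness, mm) by
#'   default.
#' @param baseline_thickness Length-`q` vector of ROI mean thicknesses (mm),
#'   each within 1.0--5.0 mm; the default profile takes the normal quantiles
#'   `qnorm(ppoints(q), 2.6, 0.4)` (about 1.6--3.6 mm at q = 68), emulating
#'   the bell-shaped spread of parcel mean thickness across a real cortex.
#'   A distribution with tails matters: thresholded dissimilarity graphs of
#'   1-D features can only contain triangles when the value spread exceeds
#'   twice the cutoff, so a too-narrow (e.g. uniform ramp) profile makes
#'   transitivity degenerate at high thresholds.
#' @param atrophy_frac Named vector, fraction of ROIs affected per profile.
#' @param atrophy_depth Named vector, thinning depth (mm) in affected ROIs.
#' @param longitudinal_rate Named vector, thinning rate (mm/year) per profile.
#' @param subject_sd Between-patient random-intercept sd (mm).
#' @param noise_sd Within-scan measurement sd (mm).
#' @param age_mean,age_sd Named vectors, baseline age distribution per profile.
#' @param sex_frac_female Named vector, fraction of female patients.
#' @param schedule Visit times in years since baseline.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#'
#' @return A list of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = c(CIS = 12, RR = 30, PP = 20, SP = 28),
                          n_scans = c(CIS = 64, RR = 233, PP = 140, SP = 215),
                          mean_scans_per_patient = NULL,
                          q = 68,
                          n_features = 1,
                          baseline_thickness = NULL,
                          atrophy_frac = c(CIS = 0.05, RR = 0.15, PP = 0.30, SP = 0.30),
                          atrophy_depth = c(CIS = 0.05, RR = 0.12, PP = 0.30, SP = 0.25),
                          longitudinal_rate = c(CIS = 0.005, RR = 0.010, PP = 0.020, SP = 0.020),
                          subject_sd = 0.10,
                          noise_sd = 0.05,
                          age_mean = c(CIS = 32.4, RR = 33.6, PP = 40.4, SP = 40.8),
                          age_sd = c(CIS = 6.4, RR = 7.1, PP = 6.3, SP = 4.8),
                          sex_frac_female = c(CIS = 0.47, RR = 0.82, PP = 0.66, SP = 0.40),
                          schedule = c(seq(0, 3, by = 0.5), 4:7),
                          seed = 1L) {
  profiles <- names(n_patients)
  assert_profile(profiles)
  if (is.null(baseline_thickness)) {
    baseline_thickness <- stats::qnorm(stats::ppoints(q), mean = 2.6, sd = 0.4)
  }
  cfg <- list(
    profiles = profiles,
    n_patients = n_patients,
    n_scans = n_scans,
    mean_scans_per_patient = mean_scans_per_patient,
    q = as.integer(q),
    n_features = as.integer(n_features),
    baseline_thickness = baseline_thickness,
    atrophy_frac = atrophy_frac,
    atrophy_depth = atrophy_depth,
    longitudinal_rate = longitudinal_rate,
    subject_sd = subject_sd,
    noise_sd = noise_sd,
    age_mean = age_mean,
    age_sd = age_sd,
    sex_frac_female = sex_frac_female,
    schedule = sort(unique(schedule)),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  p <- cfg$profiles
  need <- c("n_patients", "atrophy_frac", "atrophy_depth", "longitudinal_rate",
            "age_mean", "age_sd", "sex_frac_female")
  for (field in need) {
    if (!all(p %in% names(cfg[[field]]))) {
      abort(paste0("cohort_config: `", field, "` must be named for every profile"))
    }
  }
  if (any(cfg$n_patients < 1)) abort("cohort_config: all patient counts must be >= 1")
  if (!is.null(cfg$n_scans) && any(cfg$n_scans < cfg$n_patients[names(cfg$n_scans)])) {
    abort("cohort_config: per-profile scan totals must be >= patient counts")
  }
  if (cfg$q < 2) abort("cohort_config: q must be >= 2")
  if (cfg$n_features < 1) abort("cohort_config: n_features must be >= 1")
  if (length(cfg$baseline_thickness) != cfg$q) {
    abort("cohort_config: baseline_thickness must have length q")
  }
  if (any(cfg$baseline_thickness < 1.0 | cfg$baseline_thickness > 5.0)) {
    abort("cohort_config: baseline thickness must lie in the physiologic band [1, 5] mm")
  }
  if (cfg$subject_sd < 0 || cfg$noise_sd < 0 || any(cfg$age_sd < 0)) {
    abort("cohort_config: standard deviations must be >= 0")
  }
  if (any(cfg$atrophy_frac < 0 | cfg$atrophy_frac > 1)) {
    abort("cohort_config: affected-ROI fractions must lie in [0, 1]")
  }
  if (any(cfg$sex_frac_female < 0 | cfg$sex_frac_female > 1)) {
    abort("cohort_config: sex fractions must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  profiles:", paste(x$profiles, collapse = ", "), "\n")
  cat("  patients:", paste(x$n_patients, collapse = "/"),
      if (!is.null(x$n_scans)) paste0(" scans: ", paste(x$n_scans, collapse = "/")), "\n")
  cat("  q =", x$q, "ROIs,", x$n_features, "feature(s), seed =", x$seed, "\n")
  invisible(x)
}
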