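#' Simulate a synthetic longitudinal cortical-thickness cohort
#'
#' Generates a cohort of per-scan ROI thickness tables with the statistical
#' structure the downstream connectome analysis assumes: four clinical
#' profiles, profile-specific cortical atrophy, within-patient correlation
#' (random intercepts), longitudinal thinning and measurement noise. See
#' [cohort_config()] for the generative model.
#'
#' @param config A [cohort_config()] object.
#'
#' @return A tibble of class `"gm_cohort"` with one row per scan and columns
#'   `patient_id`, `profile`, `sex`, `age` (years at scan), `scan_time`
#'   (years since baseline), `scan_id`, and `features` (list-column of
#'   `q x n_features` matrices, ROI ids as row names). ROI ids and `q` are
#'   stored as attributes. Byte-identical for identical configs.
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_patients = c(CIS = 2, RR = 3, PP = 2, SP = 2),
#'   n_scans = NULL, mean_scans_per_patient = c(CIS = 3, RR = 3, PP = 3, SP = 3),
#'   q = 10, seed = 42))
#' nrow(cohort)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config object")
  }
  cfg <- config
  roi_ids <- sprintf("roi_%03d", seq_len(cfg$q))

  with_seed(cfg$seed, {
    # shared ROI permutation -> nested affected sets across profiles
    roi_perm <- sample.int(cfg$q)
    affected <- lapply(cfg$atrophy_frac[cfg$profiles], function(fr) {
      k <- round(fr * cfg$q)
      if (k == 0) integer(0) else roi_perm[seq_len(k)]
    })

    rows <- list()
    for (g in cfg$profiles) {
      np <- cfg$n_patients[[g]]
      counts <- draw_scan_counts(
        np,
        total = if (is.null(cfg$n_scans)) NULL else cfg$n_scans[[g]],
        mean_count = cfg$mean_scans_per_patient[[g]] %||% NA_real_,
        max_count = length(cfg$schedule)
      )
      atro <- numeric(cfg$q)
      atro[affected[[g]]] <- cfg$atrophy_depth[[g]]
      for (p in seq_len(np)) {
        pid <- sprintf("%s%03d", g, p)
        b_p <- rnorm(1, 0, cfg$subject_sd)
        age0 <- rnorm(1, cfg$age_mean[[g]], cfg$age_sd[[g]])
        sex <- if (runif(1) < cfg$sex_frac_female[[g]]) "F" else "M"
        times <- cfg$schedule[seq_len(counts[p])]
        for (s in seq_along(times)) {
          t <- times[s]
          mu <- cfg$baseline_thickness - atro - cfg$longitudinal_rate[[g]] * t + b_p
          x <- mu + matrix(rnorm(cfg$q * cfg$n_features, 0, cfg$noise_sd),
                           nrow = cfg$q, ncol = cfg$n_features)
          x <- pmax(x, 0.5)  # physiologic floor
          dimnames(x) <- list(roi_ids, sprintf("feature_%d", seq_len(cfg$n_features)))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patient_id = pid,
            profile = g,
            sex = sex,
            age = age0 + t,
            scan_time = t,
            scan_id = sprintf("%s_s%02d", pid, s),
            features = list(x)
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
  })

  out$profile <- factor(out$profile, levels = ms_profiles())
  out$sex <- factor(out$sex, levels = c("F", "M"))
  new_gm_cohort(out, q = cfg$q, roi_ids = roi_ids)
}

new_gm_cohort <- function(tbl, q, roi_ids) {
  structure(tbl, q = as.integer(q), roi_ids = roi_ids,
            class = c("gm_cohort", class(tibble::as_tibble(tbl))))
}

# Per-patient scan counts. With an explicit group total: truncated-Poisson
# draws (>= 1, <= max_count) adjusted to hit the total exactly, emulating the
# attrition visible in real longitudinal cohorts. Otherwise: truncated
# Poisson around `mean_count`.
draw_scan_counts <- function(n_patients, total = NULL, mean_count = NA_real_,
                             max_count = 11L) {
  if (is.null(total) && is.na(mean_count)) {
    abort("either per-profile scan totals or mean scan counts must be configured")
  }
  lambda <- if (!is.null(total)) total / n_patients else mean_count
  counts <- pmin(pmax(rpois(n_patients, lambda), 1L), max_count)
  if (!is.null(total)) {
    if (total < n_patients || total > n_patients * max_count) {
      abort("scan total incompatible with patient count and schedule length")
    }
    while (sum(counts) > total) {
      i <- sample(which(counts > 1L), 1L)
      counts[i] <- counts[i] - 1L
    }
    while (sum(counts) < total) {
      i <- sample(which(counts < max_count), 1L)
      counts[i] <- counts[i] + 1L
    }
  }
  counts
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat("<gm_cohort> ", nrow(x), " scans, ",
      length(unique(x$patient_id)), " patients, q = ", attr(x, "q"),
      " ROIs\n", sep = "")
  NextMethod()
}

#' Extract the per-scan feature matrix of a cohort
#'
#' Stacks each scan's first morphometric feature into a `scans x q` matrix
#' (rows named by `scan_id`), the shape used for pooled summaries.
#'
#' @param cohort A `gm_cohort` tibble.
#' @param feature Feature column index (default 1, mean thickness).
#' @return A numeric matrix.
#' @export
cohort_feature_matrix <- function(cohort, feature = 1L) {
  m <- t(vapply(cohort$features, function(f) f[, feature],
                numeric(attr(cohort, "q"))))
  rownames(m) <- cohort$scan_id
  m
}
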