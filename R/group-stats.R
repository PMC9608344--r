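#' Compare two clinical profiles on each global metric
#'
#' Fits, per metric, a binomial-family logistic model with the group
#' indicator as outcome and the metric value plus age and sex as covariates,
#' accounting for the longitudinal design in one of two ways:
#'
#' * `unit = "patient"` (default): scans are averaged within patient and an
#'   ordinary logistic GLM is fitted on patient-level observations. Because
#'   the outcome is constant within patient, the patient mean carries all
#'   the between-group information, and this reduction keeps the test
#'   calibrated.
#' * `unit = "scan"`: scan-level observations with a per-patient random
#'   intercept (mixed logistic, Laplace). With a patient-constant outcome
#'   the random-intercept variance is weakly identified and can run to the
#'   boundary, which makes the Wald test conservative; the option is kept
#'   for sensitivity analyses.
#'
#' The reported p-value is the Wald test on the metric coefficient, which
#' is z-scored before fitting (so `coef` is per SD of the metric). Under
#' (near-)complete separation the Wald statistic degenerates (Hauck-Donner);
#' the function then falls back to the likelihood-ratio test against the
#' covariate-only model and records the route in `method`.
#'
#' @param metrics Long metric table from [compute_metrics()] (one `tau`).
#' @param pair Character vector of two profiles, e.g. `c("RR", "PP")`; the
#'   second is coded as the positive outcome.
#' @param covariates Fixed covariates beyond the metric; any of `"age"`,
#'   `"sex"`, `"scan_time"`.
#' @param unit `"patient"` (aggregate scans, plain GLM) or `"scan"` (mixed
#'   model with patient random intercept).
#' @param adjust If `TRUE`, Bonferroni-adjust p-values across the six metrics
#'   (off by default; one model per metric is reported unadjusted).
#' @return A tibble `pair, metric, coef, p, stars, converged, method,
#'   n_scans, n_patients`; non-convergence or degenerate predictors give
#'   `converged = FALSE` with `NA` estimates, never a silent drop. `method`
#'   is `"wald"` or, on Wald-degenerate (separated) fits, `"lrt"`.
#' @export
compare_pair <- function(metrics, pair, covariates = c("age", "sex"),
                         unit = c("patient", "scan"), adjust = FALSE) {
  unit <- match.arg(unit)
  assert_profile(pair)
  if (length(pair) != 2) abort("compare_pair: `pair` must name two profiles")
  if (length(unique(metrics$tau)) > 1) {
    abort("compare_pair: fix one tau before comparing groups")
  }
  dat <- dplyr::filter(metrics, .data$profile %in% pair)
  dat <- dplyr::arrange(dat, .data$patient_id, .data$scan_id, .data$metric)
  if (length(unique(dat$patient_id[dat$profile == pair[1]])) < 2 ||
      length(unique(dat$patient_id[dat$profile == pair[2]])) < 2) {
    abort("compare_pair: need at least 2 patients per profile")
  }
  dat$y <- as.integer(as.character(dat$profile) == pair[2])
  covariates <- match.arg(covariates, c("age", "sex", "scan_time"),
                          several.ok = TRUE)
  rhs_fixed <- paste(c("value_s", covariates), collapse = " + ")
  fml <- if (unit == "scan") {
    stats::as.formula(paste("y ~", rhs_fixed, "+ (1 | patient_id)"))
  } else {
    stats::as.formula(paste("y ~", rhs_fixed))
  }

  out <- purrr::map_dfr(metric_names(), function(mt) {
    d <- dplyr::filter(dat, .data$metric == mt, !is.na(.data$value))
    res <- tibble::tibble(
      pair = paste(pair, collapse = "-"), metric = mt,
      coef = NA_real_, p = NA_real_, stars = "", converged = FALSE,
      method = NA_character_,
      n_scans = nrow(d), n_patients = length(unique(d$patient_id))
    )
    if (nrow(d) < 4 || sd(d$value) == 0) return(res)  # degenerate predictor
    if (unit == "patient") {
      d <- d |>
        dplyr::group_by(.data$patient_id, .data$y, .data$sex) |>
        dplyr::summarise(value = mean(.data$value), age = mean(.data$age),
                         scan_time = mean(.data$scan_time), .groups = "drop")
      if (sd(d$value) == 0) return(res)
    }
    d$value_s <- as.numeric(scale(d$value))
    fit <- fit_group_logit(fml, d, unit)
    if (is.null(fit)) return(res)
    co <- suppressWarnings(summary(fit$model))$coefficients
    if (!"value_s" %in% rownames(co)) return(res)
    res$coef <- co["value_s", "Estimate"]
    res$p <- co["value_s", ncol(co)]
    res$method <- "wald"
    # Under (near-)complete separation the Wald statistic degenerates: the
    # coefficient and its standard error both diverge and p -> 1 however
    # strong the effect (Hauck-Donner). Fall back to the likelihood-ratio
    # test against the covariate-only model.
    if (!is.finite(res$p) || co["value_s", "Std. Error"] > 100) {
      fml0 <- stats::update.formula(fml, . ~ . - value_s)
      fit0 <- fit_group_logit(fml0, d, unit, nAGQ = fit$nAGQ)
      if (!is.null(fit0)) {
        lrt <- suppressWarnings(if (unit == "scan") {
          stats::anova(fit0$model, fit$model)[2, "Pr(>Chisq)"]
        } else {
          stats::anova(fit0$model, fit$model, test = "Chisq")[2, "Pr(>Chi)"]
        })
        res$p <- lrt
        res$method <- "lrt"
      }
    }
    # converged = a usable test statistic came out of a successful fit;
    # the route (wald vs lrt fallback) is recorded in `method`
    res$converged <- is.finite(res$p)
    res
  })
  if (adjust) out$p <- pmin(out$p * nrow(out), 1)
  out$stars <- significance_stars(out$p)
  out
}

fit_group_logit <- function(fml, d, unit, nAGQ = 1L) {
  if (unit == "patient") {
    m <- tryCatch(
      suppressWarnings(stats::glm(fml, data = d, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(m)) return(NULL)
    return(list(model = m, nAGQ = NA_integer_))
  }
  fit_mixed_logit(fml, d, nAGQ = nAGQ)
}

# Laplace-approximation fit with an adaptive-quadrature-free retry: the
# default fit occasionally fails outright on quasi-separated data.
fit_mixed_logit <- function(fml, d, nAGQ = 1L) {
  warned <- FALSE
  m <- tryCatch(
    withCallingHandlers(
      suppressMessages(
        lme4::glmer(fml, data = d, family = stats::binomial(), nAGQ = nAGQ)),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  used_nagq <- nAGQ
  if (is.null(m) && nAGQ != 0L) {
    used_nagq <- 0L
    warned <- TRUE
    m <- tryCatch(
      suppressWarnings(lme4::glmer(fml, data = d,
                                   family = stats::binomial(), nAGQ = 0L)),
      error = function(e) NULL)
  }
  if (is.null(m)) return(NULL)
  conv_msgs <- m@optinfo$conv$lme4$messages %||% character(0)
  list(model = m, warned = warned || length(conv_msgs) > 0, nAGQ = used_nagq)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare every profile pair present in a metric table
#'
#' @inheritParams compare_pair
#' @return Row-bound [compare_pair()] results for all unordered pairs.
#' @export
compare_all_pairs <- function(metrics, covariates = c("age", "sex"),
                              unit = c("patient", "scan"), adjust = FALSE) {
  profs <- intersect(ms_profiles(), unique(as.character(metrics$profile)))
  pairs <- utils::combn(profs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, compare_pair, metrics = metrics,
                 covariates = covariates, unit = unit, adjust = adjust)
}

#' Per-group metric summaries (boxplot table)
#'
#' Group-wise mean and sample standard deviation of each global metric at a
#' fixed threshold — the numeric companion of the group boxplots.
#'
#' @inheritParams compare_pair
#' @return A tibble with one row per (profile, metric): `profile, metric,
#'   mean, sd, n_scans`. Groups with a single scan report `sd = 0` with a
#'   warning.
#' @export
group_summary <- function(metrics) {
  out <- metrics |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$profile, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n_scans = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_scans == 1)) {
    warn("group_summary: group(s) with a single scan; sd reported as 0")
    out$sd[out$n_scans == 1] <- 0
  }
  out
}
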