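#' Configuration of one classification experiment
#'
#' @param pair Group pair, e.g. `"RR:PP"` or `"CIS+RR:PP+SP"` (merged
#'   groups); see [parse_pair()].
#' @param taus Candidate binarization thresholds; treated as an extra
#'   hyperparameter tuned per learner on the training/validation split. The
#'   default grid covers the informative 0.6--0.8 working range; pass
#'   `seq(0.05, 0.95, 0.05)` for the full percentile range.
#' @param grids Named list of per-learner hyperparameter grids (`lr`, `rf`,
#'   `svm`, `adb`), as produced by `default_grids()`. Each grid must stay
#'   inside the tuning intervals: LR C in \[1, 100\]; RF trees in
#'   \[10, 500\], depth in \[1, 10\]; SVM C and gamma in \[1, 100\];
#'   AdaBoost trees in \[10, 500\], learning rate in \[0.1, 3\].
#' @param k Number of cross-validation folds.
#' @param val_frac Validation fraction of non-test patients.
#' @param minimal If `TRUE`, use one-point grids (no search) — handy for
#'   calibration studies.
#' @param seed Integer seed controlling folds and learner randomness.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(pair, taus = seq(0.6, 0.8, by = 0.05),
                              grids = NULL, k = 10, val_frac = 0.2,
                              minimal = FALSE, seed = 1L) {
  grids <- grids %||% if (minimal) minimal_grids() else default_grids()
  validate_grids(grids)
  if (any(taus <= 0 | taus >= 1)) abort("taus must lie strictly in (0, 1)")
  structure(list(pair = parse_pair(pair), taus = taus, grids = grids,
                 k = as.integer(k), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

validate_grids <- function(grids) {
  need <- c("lr", "rf", "svm", "adb")
  if (!all(need %in% names(grids))) {
    abort("grids must contain entries lr, rf, svm, adb")
  }
  ok <- all(
    grids$lr$C >= 1, grids$lr$C <= 100,
    grids$rf$trees >= 10, grids$rf$trees <= 500,
    grids$rf$depth >= 1, grids$rf$depth <= 10,
    grids$svm$C >= 1, grids$svm$C <= 100,
    grids$svm$gamma >= 1, grids$svm$gamma <= 100,
    grids$adb$trees >= 10, grids$adb$trees <= 500,
    grids$adb$lr >= 0.1, grids$adb$lr <= 3
  )
  if (!ok) abort("a hyperparameter grid exceeds its tuning interval")
  invisible(grids)
}

#' Run one classification experiment
#'
#' Classifies the scans of a profile pair from the six global graph metrics
#' via four base learners (logistic regression, random forest, RBF SVM,
#' AdaBoost) combined by majority voting, under patient-grouped stratified
#' `k`-fold cross-validation. Per fold and per learner, a grid search over
#' hyperparameters *and* the binarization threshold `tau` maximizes F1 on
#' the validation split; the pooled percentile cutoff `phi(tau)` is always
#' recomputed from the scans available to the learner (training scans during
#' the search, training+validation scans for the final refit), never from
#' test scans. Features are standardized, and undefined metric values
#' (assortativity/modularity on degenerate graphs) mean-imputed, using
#' training statistics only. Class weighting is inverse class frequency on
#' scan counts.
#'
#' @param cohort A `gm_cohort` tibble.
#' @param config An [experiment_config()].
#' @return A `gm_experiment` object: list with `folds` (per-fold ensemble
#'   scores, chosen `tau` and hyperparameters, ROC points), `learner_folds`
#'   (per-fold scores of each base learner), `aggregate` (mean and sd over
#'   folds), `config`. Bit-stable under a fixed seed.
#' @seealso [tidy.gm_experiment()], [glance.gm_experiment()],
#'   [compare_reports()]
#' @export
run_experiment <- function(cohort, config) {
  stopifnot(inherits(config, "experiment_config"))
  pr <- config$pair
  if (is.null(cohort$connectome)) cohort <- cohort_connectomes(cohort)
  dat <- tibble::as_tibble(cohort)
  dat$class <- dplyr::case_when(
    as.character(dat$profile) %in% pr$a ~ 0L,
    as.character(dat$profile) %in% pr$b ~ 1L,
    TRUE ~ NA_integer_
  )
  dat <- dplyr::filter(dat, !is.na(.data$class))
  folds <- make_folds(dat, pr, k = config$k, val_frac = config$val_frac,
                      seed = derive_seed(config$seed, "folds"))
  check_fold_leakage(folds)

  fold_rows <- list()
  learner_rows <- list()
  for (i in seq_len(nrow(folds))) {
    fr <- run_fold(dat, folds[i, ], config)
    fold_rows[[i]] <- fr$ensemble
    learner_rows[[i]] <- fr$learners
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  learner_tbl <- dplyr::bind_rows(learner_rows)

  score_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  aggregate <- fold_tbl |>
    dplyr::summarise(dplyr::across(dplyr::all_of(score_cols),
      list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))))
  structure(list(folds = fold_tbl, learner_folds = learner_tbl,
                 aggregate = aggregate, config = config),
            class = "gm_experiment")
}

run_fold <- function(dat, fold_row, config) {
  tr_ids <- fold_row$train[[1]]
  va_ids <- fold_row$validation[[1]]
  te_ids <- fold_row$test[[1]]
  fold_seed <- derive_seed(config$seed, paste0("fold", fold_row$fold))

  in_tr <- dat$patient_id %in% tr_ids
  in_va <- dat$patient_id %in% va_ids
  in_te <- dat$patient_id %in% te_ids

  # feature matrices at each candidate tau (cutoff from training scans
  # only), computed lazily: a forced one-point search never needs them
  feat_env <- new.env(parent = emptyenv())
  tuning_features <- function(ti) {
    key <- as.character(ti)
    if (is.null(feat_env[[key]])) {
      tau <- config$taus[ti]
      phi <- percentile_cutoff(pool_weights(dat$connectome[in_tr]), tau)
      feat_env[[key]] <- prepare_features(
        metric_features(dat$connectome, phi, tau), fit_rows = in_tr)
    }
    feat_env[[key]]
  }

  y <- dat$class
  learners <- c("lr", "rf", "svm", "adb")

  choices <- lapply(learners, function(ln) {
    grid <- config$grids[[ln]]
    best <- list(score = -Inf, tau = config$taus[1], params = grid[1, ])
    if (nrow(grid) == 1 && length(config$taus) == 1) {
      return(best)  # single candidate: the search is forced
    }
    for (ti in seq_along(config$taus)) {
      xs <- tuning_features(ti)
      w_tr <- class_weights(y[in_tr])
      for (gi in seq_len(nrow(grid))) {
        fit <- fit_learner(ln, xs[in_tr, , drop = FALSE], y[in_tr], w_tr,
                           as.list(grid[gi, ]), seed = fold_seed)
        p_va <- predict_prob(fit, xs[in_va, , drop = FALSE])
        f1 <- score_predictions(y[in_va], as.integer(p_va > 0.5), p_va)$f1
        f1 <- ifelse(is.na(f1), -1, f1)
        if (f1 > best$score) {  # first max wins: grids are ordered small-to-large
          best <- list(score = f1, tau = config$taus[ti], params = grid[gi, ])
        }
      }
    }
    best
  })
  names(choices) <- learners

  # final refit on train + validation at each learner's chosen tau
  in_fit <- in_tr | in_va
  w_fit <- class_weights(y[in_fit])
  test_probs <- matrix(NA_real_, sum(in_te), 4,
                       dimnames = list(NULL, learners))
  test_labels <- test_probs
  learner_scores <- list()
  refit_cache <- list()  # learners often agree on tau; share the feature pass
  for (ln in learners) {
    ch <- choices[[ln]]
    key <- as.character(ch$tau)
    if (is.null(refit_cache[[key]])) {
      phi <- percentile_cutoff(pool_weights(dat$connectome[in_fit]), ch$tau)
      refit_cache[[key]] <- prepare_features(
        metric_features(dat$connectome, phi, ch$tau), fit_rows = in_fit)
    }
    xs <- refit_cache[[key]]
    fit <- fit_learner(ln, xs[in_fit, , drop = FALSE], y[in_fit], w_fit,
                       as.list(ch$params), seed = fold_seed)
    p_te <- predict_prob(fit, xs[in_te, , drop = FALSE])
    test_probs[, ln] <- p_te
    test_labels[, ln] <- as.integer(p_te > 0.5)
    learner_scores[[ln]] <- dplyr::bind_cols(
      tibble::tibble(fold = fold_row$fold, learner = ln, tau = ch$tau,
                     params = list(as.list(ch$params))),
      score_predictions(y[in_te], test_labels[, ln], p_te)
    )
  }

  ens <- majority_vote(test_labels, test_probs)
  ensemble <- dplyr::bind_cols(
    tibble::tibble(fold = fold_row$fold,
                   tau_lr = choices$lr$tau, tau_rf = choices$rf$tau,
                   tau_svm = choices$svm$tau, tau_adb = choices$adb$tau),
    score_predictions(y[in_te], ens$label, ens$prob)
  )
  ensemble$roc <- list(roc_points(y[in_te], ens$prob))
  list(ensemble = ensemble, learners = dplyr::bind_rows(learner_scores))
}

# six-metric wide feature matrix (rows = scans) at a given cutoff
metric_features <- function(connectomes, phi, tau) {
  m <- t(vapply(connectomes, function(a) {
    fast_metrics(binarize(a, phi, tau = tau))
  }, numeric(6)))
  colnames(m) <- metric_names()
  m
}

# training-only standardization and mean-imputation of undefined metrics
prepare_features <- function(x, fit_rows) {
  mu <- apply(x[fit_rows, , drop = FALSE], 2, mean, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  sdv <- apply(x[fit_rows, , drop = FALSE], 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)
}

#' @export
print.gm_experiment <- function(x, ...) {
  cat("<gm_experiment> ", x$config$pair$label, ", ",
      nrow(x$folds), " folds\n", sep = "")
  agg <- x$aggregate
  cat(sprintf("  F1 %.3f (%.3f)  Precision %.3f (%.3f)  Accuracy %.3f (%.3f)  AUC %.3f (%.3f)\n",
              agg$f1_mean, agg$f1_sd, agg$precision_mean, agg$precision_sd,
              agg$accuracy_mean, agg$accuracy_sd, agg$auc_mean, agg$auc_sd))
  invisible(x)
}

#' Tidy per-fold scores of an experiment
#'
#' @param x A `gm_experiment`.
#' @param ... Unused.
#' @return Per-fold tibble of ensemble scores and chosen thresholds.
#' @exportS3Method generics::tidy
tidy.gm_experiment <- function(x, ...) {
  dplyr::select(x$folds, -dplyr::any_of("roc"))
}

#' One-row summary of an experiment
#'
#' @param x A `gm_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: pair label plus mean and sd of each score over
#'   folds, mirroring the usual mean (sd) report tables.
#' @exportS3Method generics::glance
glance.gm_experiment <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(pair = x$config$pair$label), x$aggregate)
}
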