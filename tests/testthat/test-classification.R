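test_that("pair specifications parse, including merged groups", {
  pr <- parse_pair("RR:PP")
  expect_equal(pr$a, "RR")
  expect_equal(pr$b, "PP")
  expect_equal(pr$label, "RR-PP")
  pr <- parse_pair("CIS+RR:PP+SP")
  expect_equal(pr$a, c("CIS", "RR"))
  expect_equal(pr$b, c("PP", "SP"))
  expect_error(parse_pair("RR:RR"), "disjoint")
  expect_error(parse_pair("RR:XX"), "profile")
})

test_that("folds are patient-disjoint, exhaustive and stratified", {
  cohort <- simulate_cohort(null_two_arm_config(5, n_per_arm = 10, q = 5,
                                                scans = 3))
  folds <- make_folds(cohort, "RR:PP", k = 10, seed = 3)
  expect_equal(nrow(folds), 10)
  # 20 patients, k = 10 -> exactly 2 test patients per fold, one per class
  expect_true(all(vapply(folds$test, length, integer(1)) == 2))
  all_test <- unlist(folds$test)
  expect_setequal(all_test, unique(cohort$patient_id))
  expect_equal(anyDuplicated(all_test), 0)
  # stratification: each fold's test set has one patient per arm
  prof <- substr(all_test, 1, 2)
  for (i in seq_len(10)) {
    expect_setequal(substr(folds$test[[i]], 1, 2), c("RR", "PP"))
  }
  # within-fold disjointness and full scan accounting
  for (i in seq_len(10)) {
    ids <- c(folds$train[[i]], folds$validation[[i]], folds$test[[i]])
    expect_equal(anyDuplicated(ids), 0)
    expect_setequal(ids, unique(cohort$patient_id))
  }
  expect_error(make_folds(cohort, "RR:PP", k = 30, seed = 1), "fewer patients")
})

test_that("every scan of a patient lands in exactly one split role per fold", {
  cohort <- simulate_cohort(null_two_arm_config(6, n_per_arm = 8, q = 5,
                                                scans = 6))
  folds <- make_folds(cohort, "RR:PP", k = 4, seed = 9)
  scans_by_patient <- split(cohort$scan_id, cohort$patient_id)
  for (i in seq_len(nrow(folds))) {
    for (pid in names(scans_by_patient)) {
      roles <- c(train = pid %in% folds$train[[i]],
                 validation = pid %in% folds$validation[[i]],
                 test = pid %in% folds$test[[i]])
      expect_equal(sum(roles), 1)
    }
  }
})

test_that("majority vote follows modal rule with probability tie-break", {
  labels <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 1), c(1, 1, 1, 1))
  probs <- rbind(c(0.9, 0.8, 0.7, 0.4),   # strict majority 1
                 c(0.9, 0.8, 0.2, 0.3),   # 2-2 tie, mean 0.55 -> 1
                 c(0.1, 0.2, 0.3, 0.6),   # strict majority 0
                 c(0.9, 0.9, 0.9, 0.9))   # unanimity
  v <- majority_vote(labels, probs)
  expect_equal(v$label, c(1L, 1L, 0L, 1L))
  expect_equal(v$prob, rowMeans(probs))
  # 2-2 tie with mean below one half goes to class 0
  v2 <- majority_vote(rbind(c(1, 1, 0, 0)), rbind(c(0.6, 0.55, 0.1, 0.15)))
  expect_equal(v2$label, 0L)
  expect_error(majority_vote(labels[, 1:3], probs[, 1:3]), "4")
})

test_that("scores follow the confusion-count formulas", {
  truth <- c(rep(1, 9), rep(0, 11))
  label <- c(rep(1, 6), rep(0, 3), rep(1, 2), rep(0, 9))
  s <- score_predictions(truth, label)
  expect_equal(s$tp, 6); expect_equal(s$fp, 2)
  expect_equal(s$fn, 3); expect_equal(s$tn, 9)
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 * 0.75 * (2 / 3) / (0.75 + 2 / 3), tolerance = 1e-12)
  expect_equal(s$accuracy, 0.75)

  perfect <- score_predictions(truth, truth, prob = truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  # truth-independent constant probabilities carry no ranking information
  s0 <- score_predictions(truth, label, prob = rep(0.4, 20))
  expect_equal(s0$auc, 0.5)
  # single-class truth: AUC undefined, flagged
  expect_true(is.na(score_predictions(rep(1, 5), rep(1, 5), runif(5))$auc))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:10) {
    truth <- rbinom(40, 1, 0.4)
    if (length(unique(truth)) < 2) next
    prob <- runif(40)
    ref <- as.numeric(suppressMessages(pROC::auc(truth, prob,
                                                 direction = "<")))
    expect_equal(rank_auc(truth, prob), ref, tolerance = 1e-12)
  }
})

test_that("report comparison uses the exact signed-rank null", {
  a <- tibble::tibble(f1 = seq(0.5, 0.95, length.out = 10))
  ident <- compare_reports(a, a)
  expect_equal(ident$p, 1)
  b <- dplyr::mutate(a, f1 = f1 - seq(0.01, 0.1, length.out = 10))
  cmp <- compare_reports(a, b)                 # uniformly worse on all folds
  expect_equal(cmp$p, 2 / 2^10, tolerance = 1e-6)  # exact n=10 signed-rank floor
  # two-sided p is symmetric in the argument order
  expect_equal(compare_reports(b, a)$p, cmp$p)
  expect_error(compare_reports(a, b[1:5, ]), "unequal fold")
})

test_that("single grid point and tau are returned unchanged and reruns are bit-stable", {
  cohort <- built_cohort(null_two_arm_config(7, n_per_arm = 8, q = 10,
                                             scans = 2))
  ec <- experiment_config("RR:PP", taus = 0.7, minimal = TRUE, k = 4, seed = 5)
  r1 <- run_experiment(cohort, ec)
  expect_true(all(r1$folds$tau_lr == 0.7))
  expect_true(all(r1$learner_folds$tau == 0.7))
  r2 <- run_experiment(cohort, ec)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$learner_folds$f1, r2$learner_folds$f1)
  # all scores bounded
  sc <- tidy(r1)
  expect_true(all(sc$accuracy >= 0 & sc$accuracy <= 1))
  expect_true(all(is.na(sc$auc) | (sc$auc >= 0 & sc$auc <= 1)))
})

test_that("merged-group experiments run under the identical interface", {
  cohort <- built_cohort(tiny_cohort_config(seed = 41, q = 10, scans = 2))
  ec <- experiment_config("CIS+RR:PP+SP", taus = 0.7, minimal = TRUE, k = 3,
                          seed = 2)
  rep <- run_experiment(cohort, ec)
  expect_s3_class(rep, "gm_experiment")
  expect_equal(rep$config$pair$label, "CIS+RR-PP+SP")
  expect_equal(nrow(tidy(rep)), 3)
})

test_that("hyperparameter grids outside the tuning intervals are rejected", {
  expect_error(
    experiment_config("RR:PP", grids = modifyList(
      gmconnect:::default_grids(), list(lr = tibble::tibble(C = 1000)))),
    "interval")
  expect_error(experiment_config("RR:PP", taus = c(0.5, 1)), "taus")
})

test_that("a signal planted only above tau = 0.6 drives the tuned tau there", {
  # Hand-built connectomes: a common random backbone, plus block edges whose
  # weights are 0.65 (class a) vs 0.95 (class b). Both values exceed every
  # cutoff phi(tau) for tau <= 0.6, so low-tau binarizations are
  # class-identical in distribution; only cutoffs in (0.65, 0.95) - reached
  # around tau ~ 0.7 - expose the class difference.
  set.seed(31)
  q <- 16
  block <- 1:6
  make_scan <- function(cls, id) {
    a <- matrix(0, q, q)
    w <- runif(q * (q - 1) / 2)           # shared-backbone distribution
    a[upper.tri(a)] <- w
    a <- a + t(a)
    lvl <- if (cls == "RR") 0.65 else 0.95
    for (i in block) for (j in block) if (i < j) a[i, j] <- a[j, i] <- lvl
    dimnames(a) <- list(sprintf("r%02d", 1:q), sprintf("r%02d", 1:q))
    attr(a, "scan_id") <- id
    a
  }
  n_per <- 14
  rows <- purrr::map_dfr(seq_len(2 * n_per), function(i) {
    cls <- if (i <= n_per) "RR" else "PP"
    tibble::tibble(
      patient_id = sprintf("%s%03d", cls, i),
      profile = factor(cls, levels = gmconnect:::ms_profiles()),
      sex = factor("F", levels = c("F", "M")),
      age = 35, scan_time = 0,
      scan_id = sprintf("scan%03d", i),
      connectome = list(make_scan(cls, sprintf("scan%03d", i)))
    )
  })
  ec <- experiment_config("RR:PP", taus = c(0.2, 0.4, 0.7, 0.75),
                          minimal = TRUE, k = 4, seed = 11)
  rep <- run_experiment(rows, ec)
  chosen <- c(rep$folds$tau_lr, rep$folds$tau_rf, rep$folds$tau_svm,
              rep$folds$tau_adb)
  expect_gt(mean(chosen >= 0.6), 0.5)
})
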