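#' Parse a group-pair specification
#'
#' Accepts `"RR:PP"`, `"CIS+RR:PP+SP"` or a list with elements `a` and `b`
#' (character vectors of profiles). Merged groups pool the listed profiles
#' into one class.
#'
#' @param pair Pair specification.
#' @return A list with `a`, `b` (profile vectors) and `label`.
#' @export
parse_pair <- function(pair) {
  if (is.list(pair)) {
    a <- pair$a
    b <- pair$b
  } else {
    parts <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort("pair must look like 'RR:PP' or 'CIS+RR:PP+SP'")
    a <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
    b <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  }
  assert_profile(c(a, b))
  if (length(intersect(a, b)) > 0) abort("pair sides must be disjoint")
  list(a = a, b = b,
       label = paste(paste(a, collapse = "+"), paste(b, collapse = "+"), sep = "-"))
}

#' Patient-grouped stratified cross-validation folds
#'
#' Partitions the patients of a two-class experiment into `k` patient-disjoint
#' test folds, stratified by profile so class proportions are preserved
#' within rounding. All longitudinal scans of a patient travel with the
#' patient — a patient assigned to the test set contributes every scan to
#' the test set, never to training, which prevents identity leakage. Within
#' each fold the non-test patients are further split (stratified, seeded)
#' into a training set and a validation set (`val_frac`, default 20%) used
#' for hyperparameter selection.
#'
#' @param cohort A `gm_cohort` tibble.
#' @param pair Pair specification (see [parse_pair()]).
#' @param k Number of folds (default 10).
#' @param val_frac Fraction of non-test patients held out for validation.
#' @param seed Integer seed; folds are deterministic given it.
#' @return A tibble with one row per fold: `fold`, list-columns `train`,
#'   `validation`, `test` of patient ids. Attributes `pair` and `seed`.
#' @export
make_folds <- function(cohort, pair, k = 10, val_frac = 0.2, seed = 1L) {
  pr <- parse_pair(pair)
  pts <- dplyr::distinct(tibble::as_tibble(cohort),
                         .data$patient_id, .data$profile)
  pts$class <- dplyr::case_when(
    as.character(pts$profile) %in% pr$a ~ "a",
    as.character(pts$profile) %in% pr$b ~ "b",
    TRUE ~ NA_character_
  )
  pts <- dplyr::filter(pts, !is.na(.data$class))
  n_by_class <- table(pts$class)
  if (length(n_by_class) < 2 || any(n_by_class < 2)) {
    abort("make_folds: each side of the pair needs at least 2 patients")
  }
  if (nrow(pts) < k) abort("make_folds: fewer patients than folds")

  with_seed(seed, {
    # stratified round-robin assignment of shuffled patients to folds,
    # stratum by stratum (profile level keeps proportions within rounding)
    assign_tbl <- pts |>
      dplyr::group_by(.data$profile) |>
      dplyr::group_modify(function(d, key) {
        d <- d[sample.int(nrow(d)), ]
        d$fold <- rep_len(seq_len(k), nrow(d))
        d
      }) |>
      dplyr::ungroup()

    folds <- purrr::map_dfr(seq_len(k), function(f) {
      test <- assign_tbl$patient_id[assign_tbl$fold == f]
      rest <- assign_tbl[assign_tbl$fold != f, ]
      val <- rest |>
        dplyr::group_by(.data$class) |>
        dplyr::group_modify(function(d, key) {
          n_val <- max(1L, round(val_frac * nrow(d)))
          d[sample.int(nrow(d), n_val), ]
        }) |>
        dplyr::ungroup()
      tibble::tibble(
        fold = f,
        train = list(setdiff(rest$patient_id, val$patient_id)),
        validation = list(val$patient_id),
        test = list(test)
      )
    })
  })
  attr(folds, "pair") <- pr
  attr(folds, "seed") <- as.integer(seed)
  check_fold_leakage(folds)
  folds
}

#' Assert that folds are leakage-free
#'
#' Verifies that within every fold the train / validation / test patient sets
#' are pairwise disjoint, and that test sets partition the patient pool
#' across folds. Called automatically by [make_folds()] and
#' [run_experiment()].
#'
#' @param folds A fold tibble from [make_folds()].
#' @return `folds`, invisibly; aborts on any violation.
#' @export
check_fold_leakage <- function(folds) {
  for (i in seq_len(nrow(folds))) {
    tr <- folds$train[[i]]; va <- folds$validation[[i]]; te <- folds$test[[i]]
    if (length(intersect(tr, va)) || length(intersect(tr, te)) ||
        length(intersect(va, te))) {
      abort(paste0("fold ", folds$fold[i],
                   ": patient appears in more than one of train/validation/test"))
    }
  }
  test_all <- unlist(folds$test)
  if (anyDuplicated(test_all)) {
    abort("a patient appears in the test set of more than one fold")
  }
  invisible(folds)
}
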