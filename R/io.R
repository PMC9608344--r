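#' Write a cohort to a directory of delimited-text files
#'
#' Emits one feature file per scan (`scans/<scan_id>.csv`, columns
#' `roi_id, feature_1[, feature_2, ...]`, ROIs in fixed atlas order) and a
#' manifest `manifest.csv` with header
#' `patient_id,profile,sex,age,scan_time,feature_file`. The pair round-trips
#' through [read_cohort()] without loss.
#'
#' @param cohort A `gm_cohort` tibble.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  scan_dir <- file.path(dir, "scans")
  dir.create(scan_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(scan_dir)) abort(paste0("cannot create directory: ", scan_dir))
  feature_file <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    f <- cohort$features[[i]]
    tbl <- tibble::as_tibble(f, rownames = "roi_id")
    feature_file[i] <- file.path("scans", paste0(cohort$scan_id[i], ".csv"))
    readr::write_csv(tbl, file.path(dir, feature_file[i]), progress = FALSE)
  }
  manifest <- tibble::tibble(
    patient_id = cohort$patient_id,
    profile = as.character(cohort$profile),
    sex = as.character(cohort$sex),
    age = cohort$age,
    scan_time = cohort$scan_time,
    feature_file = feature_file
  )
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the manifest header, that every patient maps to a single
#' profile and sex, and that scan times increase within patient.
#'
#' @param dir Directory containing `manifest.csv` and the per-scan feature
#'   files it references.
#' @return A `gm_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) abort(paste0("no manifest.csv under ", dir))
  manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "profile", "sex", "age", "scan_time", "feature_file")
  if (!identical(names(manifest)[seq_along(need)], need)) {
    abort(paste0("malformed manifest header; expected: ",
                 paste(need, collapse = ",")))
  }
  multi <- manifest |>
    dplyr::distinct(.data$patient_id, .data$profile) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("manifest: patient(s) listed under more than one profile: ",
                 paste(multi$patient_id, collapse = ", ")))
  }
  assert_profile(manifest$profile)

  features <- vector("list", nrow(manifest))
  roi_ids <- NULL
  for (i in seq_len(nrow(manifest))) {
    ftbl <- readr::read_csv(file.path(dir, manifest$feature_file[i]),
                            show_col_types = FALSE, progress = FALSE)
    if (names(ftbl)[1] != "roi_id") {
      abort(paste0("feature file ", manifest$feature_file[i],
                   ": first column must be roi_id"))
    }
    x <- as.matrix(ftbl[-1])
    rownames(x) <- ftbl$roi_id
    if (is.null(roi_ids)) roi_ids <- ftbl$roi_id
    if (!identical(ftbl$roi_id, roi_ids)) {
      abort(paste0("feature file ", manifest$feature_file[i],
                   ": ROI order differs from the first scan"))
    }
    features[[i]] <- x
  }
  out <- tibble::tibble(
    patient_id = manifest$patient_id,
    profile = factor(manifest$profile, levels = ms_profiles()),
    sex = factor(manifest$sex, levels = c("F", "M")),
    age = manifest$age,
    scan_time = manifest$scan_time,
    scan_id = sub("\\.csv$", "", basename(manifest$feature_file)),
    features = features
  )
  bad_time <- out |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = all(diff(.data$scan_time) > 0) || dplyr::n() == 1)
  if (!all(bad_time$ok)) {
    abort("manifest: scan_time must be strictly increasing within patient")
  }
  new_gm_cohort(out, q = length(roi_ids %||% character(0)), roi_ids = roi_ids)
}

#' Read/write a connectome matrix as delimited text
#'
#' Square matrix with an ROI-label header row and leading label column.
#'
#' @param connectome A connectome matrix.
#' @param path File path.
#' @return `write_connectome()` returns `path` invisibly; `read_connectome()`
#'   returns a `gm_connectome` matrix.
#' @export
write_connectome <- function(connectome, path) {
  tbl <- tibble::as_tibble(unclass(connectome), rownames = "roi_id")
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "roi_id") abort("connectome file: first column must be roi_id")
  a <- as.matrix(tbl[-1])
  rownames(a) <- tbl$roi_id
  if (nrow(a) != ncol(a) || !identical(rownames(a), colnames(a))) {
    abort("connectome file: matrix must be square with matching ROI labels")
  }
  if (any(!is.finite(a))) {
    bad <- which(!is.finite(a), arr.ind = TRUE)[1, ]
    abort(paste0("connectome file: non-numeric cell at row ", bad[1]))
  }
  structure(a, scan_id = sub("\\.csv$", "", basename(path)),
            class = c("gm_connectome", "matrix", "array"))
}

#' Read/write a binarized graph as an edge list
#'
#' Edge list `roi_a,roi_b` plus a YAML sidecar (`<path>.meta.yaml`)
#' recording `tau`, `phi`, `scan_id` and the full vertex set (so isolated
#' nodes survive the round trip). Self-loops are rejected on read.
#'
#' @param graph An igraph graph from [binarize()].
#' @param path Edge-list file path.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  tbl <- tibble::tibble(roi_a = el[, 1], roi_b = el[, 2])
  readr::write_csv(tbl, path, progress = FALSE)
  yaml::write_yaml(list(
    tau = igraph::graph_attr(graph, "tau"),
    phi = igraph::graph_attr(graph, "phi"),
    scan_id = igraph::graph_attr(graph, "scan_id"),
    vertices = igraph::V(graph)$name
  ), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(tbl)[1:2], c("roi_a", "roi_b"))) {
    abort("edge list: header must be roi_a,roi_b")
  }
  loops <- which(tbl$roi_a == tbl$roi_b)
  if (length(loops) > 0) {
    abort(paste0("edge list: self-loop at row ", loops[1]))
  }
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  verts <- meta$vertices %||% unique(c(tbl$roi_a, tbl$roi_b))
  g <- igraph::graph_from_data_frame(tbl, directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::graph_attr(g, "tau") <- meta$tau %||% NA_real_
  igraph::graph_attr(g, "phi") <- meta$phi %||% NA_real_
  igraph::graph_attr(g, "scan_id") <- meta$scan_id %||% NA_character_
  g
}

#' Read/write the long metric table
#'
#' The single exchange format feeding statistics and classification:
#' `scan_id, patient_id, profile, sex, age, scan_time, tau, phi, metric,
#' value`.
#'
#' @param metrics Long metric tibble from [compute_metrics()].
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("scan_id", "patient_id", "profile", "tau", "metric", "value")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("metric table: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl$profile <- factor(tbl$profile, levels = ms_profiles())
  if ("sex" %in% names(tbl)) tbl$sex <- factor(tbl$sex, levels = c("F", "M"))
  tbl
}
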