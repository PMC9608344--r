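#' Build a morphological connectome from one scan's ROI feature table
#'
#' The morphological grey-matter connectome of a scan is the `q x q` matrix of
#' Manhattan (city-block) dissimilarities between ROI feature vectors:
#' `A[i, j] = sum_k |x[i, k] - x[j, k]|`. With the default single feature
#' (mean cortical thickness) this is the absolute thickness difference
#' between two parcels. The matrix is symmetric, nonnegative, and has a zero
#' diagonal; it is the weighted-graph view `G = (V, E, omega)` with `|V| = q`.
#'
#' @param features A `q x f` numeric matrix (ROI ids as row names) or a data
#'   frame with an ROI id column (`roi_id`) and numeric feature columns.
#' @param scan_id Optional scan identifier stored as an attribute.
#' @param standardize If `TRUE`, z-score each feature column before computing
#'   distances (useful when `f > 1` and features have different units).
#' @return A `q x q` numeric matrix of class `"gm_connectome"` with ROI
#'   dimnames and a `scan_id` attribute.
#' @examples
#' build_connectome(matrix(c(2.0, 2.5), ncol = 1,
#'                         dimnames = list(c("roi_a", "roi_b"), "thickness")))
#' @export
build_connectome <- function(features, scan_id = NULL, standardize = FALSE) {
  x <- as_feature_matrix(features)
  if (nrow(x) < 2) abort("build_connectome: need at least 2 ROIs")
  bad <- !apply(is.finite(x), 1, all)
  if (any(bad)) {
    abort(paste0("build_connectome: non-finite feature value(s) in ROI(s): ",
                 paste(rownames(x)[bad], collapse = ", ")))
  }
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant feature carries no signal
  }
  a <- as.matrix(stats::dist(x, method = "manhattan"))
  dimnames(a) <- list(rownames(x), rownames(x))
  structure(a, scan_id = scan_id, class = c("gm_connectome", "matrix", "array"))
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    id_col <- intersect(c("roi_id", "roi"), names(features))[1]
    ids <- if (!is.na(id_col)) as.character(features[[id_col]]) else
      sprintf("roi_%03d", seq_len(nrow(features)))
    x <- as.matrix(features[setdiff(names(features), c("roi_id", "roi"))])
    rownames(x) <- ids
    x
  } else {
    x <- as.matrix(features)
    if (is.null(rownames(x))) rownames(x) <- sprintf("roi_%03d", seq_len(nrow(x)))
    x
  }
}

#' Build connectomes for every scan of a cohort
#'
#' @param cohort A `gm_cohort` tibble (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @inheritParams build_connectome
#' @return The cohort tibble with an added `connectome` list-column.
#' @export
cohort_connectomes <- function(cohort, standardize = FALSE) {
  cohort$connectome <- purrr::map2(
    cohort$features, cohort$scan_id,
    function(f, id) build_connectome(f, scan_id = id, standardize = standardize)
  )
  cohort
}

#' Pool edge weights over a set of scans
#'
#' Concatenates the strict upper-triangle entries (row-major order) of every
#' scan's connectome, in scan order. This pooled distribution over the whole
#' scan set is the reference against which proportional percentile thresholds
#' are taken, so that one absolute cutoff applies to every scan.
#'
#' @param connectomes A list of connectome matrices, or a cohort tibble with a
#'   `connectome` list-column.
#' @return A numeric vector of length `n_scans * q * (q - 1) / 2` with
#'   attribute `n_scans`.
#' @export
pool_weights <- function(connectomes) {
  if (is.data.frame(connectomes)) {
    if (is.null(connectomes$connectome)) {
      abort("pool_weights: cohort has no `connectome` column; run cohort_connectomes() first")
    }
    connectomes <- connectomes$connectome
  }
  qs <- vapply(connectomes, nrow, integer(1))
  if (length(unique(qs)) > 1) {
    abort("pool_weights: all connectomes must share the same node count q")
  }
  pooled <- unlist(lapply(connectomes, upper_triangle_rowmajor), use.names = FALSE)
  attr(pooled, "n_scans") <- length(connectomes)
  pooled
}

# strict upper triangle in row-major order: (1,2), (1,3), ..., (q-1,q)
upper_triangle_rowmajor <- function(a) {
  ta <- t(a)
  ta[lower.tri(ta)]
}

#' Percentile cutoff of a pooled weight distribution
#'
#' Maps the percentile threshold `tau` to the absolute cutoff `phi`: the
#' linearly interpolated empirical `tau`-quantile of the pooled edge weights
#' (order-statistic position `1 + tau * (n - 1)`, the common statistical
#' default). Fixing the quantile definition makes `phi` reproducible
#' bit-exactly.
#'
#' @param weights Pooled weight vector from [pool_weights()].
#' @param tau Percentile threshold, strictly between 0 and 1.
#' @return The absolute cutoff `phi` (feature units).
#' @examples
#' percentile_cutoff(1:10, 0.7)  # 7.3
#' @export
percentile_cutoff <- function(weights, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    abort("percentile_cutoff: tau must lie strictly in (0, 1)")
  }
  if (length(weights) == 0) abort("percentile_cutoff: empty weight distribution")
  unname(quantile(weights, probs = tau, type = 7, names = FALSE))
}

#' Binarize a connectome at an absolute cutoff
#'
#' Thresholds the weighted connectome into an unweighted undirected graph:
#' edge `(i, j)` is kept iff `A[i, j] >= phi` (ties at the cutoff are
#' retained), removing the weakest connections. Self-loops are never created.
#'
#' @param connectome A connectome matrix.
#' @param phi Absolute cutoff (>= 0), typically from [percentile_cutoff()].
#' @param tau Optional percentile recorded alongside `phi` on the graph.
#' @return An [igraph::graph] (undirected, simple) with `q` vertices named by
#'   ROI id and graph attributes `tau`, `phi` and `scan_id`.
#' @export
binarize <- function(connectome, phi, tau = NA_real_) {
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0) {
    abort("binarize: phi must be a single nonnegative number")
  }
  adj <- (connectome >= phi)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::graph_attr(g, "tau") <- tau
  igraph::graph_attr(g, "phi") <- phi
  igraph::graph_attr(g, "scan_id") <- attr(connectome, "scan_id") %||% NA_character_
  g
}
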