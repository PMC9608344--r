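#' Global graph metrics of a binarized connectome
#'
#' Six global metrics characterize each binarized scan graph:
#' \describe{
#'   \item{D (density)}{realized fraction of possible edges,
#'     `2m / (q (q - 1))`.}
#'   \item{r (assortativity)}{Pearson correlation between the degrees of the
#'     two endpoints of an edge; `NA` when endpoint degrees are constant
#'     (e.g. complete or empty graphs), never silently 0.}
#'   \item{T (transitivity)}{`3 * triangles / connected triples`; 0 when the
#'     graph has no connected triple.}
#'   \item{Eg (global efficiency)}{mean over node pairs of the inverse
#'     shortest-path length, with `1/Inf = 0` for disconnected pairs.}
#'   \item{BC (average betweenness)}{unnormalized betweenness centrality
#'     (each unordered pair counted once, endpoints excluded), averaged over
#'     nodes.}
#'   \item{Q (modularity)}{Newman modularity of the partition found by
#'     deterministic greedy agglomerative modularity maximization; `NA` on
#'     edgeless graphs.}
#' }
#'
#' @param g An [igraph::graph], typically from [binarize()].
#' @return A single numeric value (`NA_real_` where the metric is undefined).
#' @name graph-metrics
NULL

#' @rdname graph-metrics
#' @export
graph_density <- function(g) {
  q <- igraph::vcount(g)
  if (q < 2) return(0)
  2 * igraph::ecount(g) / (q * (q - 1))
}

#' @rdname graph-metrics
#' @export
graph_assortativity <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.nan(r)) NA_real_ else r
}

#' @rdname graph-metrics
#' @export
graph_transitivity <- function(g) {
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t)) 0 else t
}

#' @rdname graph-metrics
#' @export
global_efficiency <- function(g) {
  q <- igraph::vcount(g)
  if (q < 2) return(0)
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  inv <- ifelse(is.finite(du) & du > 0, 1 / du, 0)
  mean(inv)
}

#' @rdname graph-metrics
#' @export
avg_betweenness <- function(g) {
  if (igraph::vcount(g) < 3) return(0)
  mean(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
}

#' @rdname graph-metrics
#' @export
graph_modularity <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  comm <- igraph::cluster_fast_greedy(g)
  igraph::modularity(comm)
}

# numeric fast path: the six metrics as a named vector, no tibble overhead
fast_metrics <- function(g) {
  c(BC = avg_betweenness(g), r = graph_assortativity(g),
    T = graph_transitivity(g), Eg = global_efficiency(g),
    Q = graph_modularity(g), D = graph_density(g))
}

#' Compute the six-metric vector of one binarized graph
#'
#' @inheritParams graph-metrics
#' @return A one-row tibble with columns `scan_id`, `tau`, `BC`, `r`, `T`,
#'   `Eg`, `Q`, `D`. Undefined metrics are `NA`.
#' @export
metric_vector <- function(g) {
  m <- fast_metrics(g)
  dplyr::bind_cols(
    tibble::tibble(scan_id = igraph::graph_attr(g, "scan_id") %||% NA_character_,
                   tau = igraph::graph_attr(g, "tau") %||% NA_real_),
    tibble::as_tibble_row(m)
  )
}

#' Compute per-scan global metrics for a cohort at one threshold
#'
#' Binarizes every scan's connectome at the pooled percentile cutoff
#' `phi(tau)` (pooled over all scans in `cohort` unless `phi` is supplied,
#' e.g. a training-set cutoff inside cross-validation) and computes the six
#' global metrics.
#'
#' @param cohort A `gm_cohort` tibble; connectomes are built on the fly if the
#'   `connectome` column is absent.
#' @param tau Percentile threshold in (0, 1); default 0.7, the centre of the
#'   informative 0.6--0.8 working range.
#' @param phi Optional absolute cutoff overriding the pooled quantile.
#' @param long If `TRUE` (default) return the long exchange format
#'   `scan_id, patient_id, profile, sex, age, scan_time, tau, metric, value`;
#'   otherwise one wide row per scan.
#' @return A tibble.
#' @export
compute_metrics <- function(cohort, tau = 0.7, phi = NULL, long = TRUE) {
  if (is.null(cohort$connectome)) cohort <- cohort_connectomes(cohort)
  if (is.null(phi)) {
    phi <- percentile_cutoff(pool_weights(cohort), tau)
  }
  mm <- metric_features(cohort$connectome, phi, tau)
  wide <- dplyr::bind_cols(tibble::tibble(scan_id = cohort$scan_id, tau = tau),
                           tibble::as_tibble(mm))
  meta <- dplyr::select(tibble::as_tibble(cohort), dplyr::any_of(
    c("scan_id", "patient_id", "profile", "sex", "age", "scan_time")))
  wide <- dplyr::left_join(meta, wide, by = "scan_id")
  wide$phi <- phi
  if (!long) return(wide)
  tidyr::pivot_longer(wide, cols = dplyr::all_of(metric_names()),
                      names_to = "metric", values_to = "value")
}

#' Coefficient-of-variation sweep over the percentile-threshold grid
#'
#' For each threshold `tau` on the grid (5\%--95\% in steps of 5\% by
#' default), binarizes all scans at the pooled cutoff `phi(tau)`, computes
#' the six metrics, and summarizes their across-scan variability as
#' `CV\% = 100 * sd / |mean|` (sample sd). This sweep is how the informative
#' working range of `tau` is located: thresholds where CV\% blows up produce
#' unstable graph topology.
#'
#' @param cohort A `gm_cohort` tibble (needs >= 2 scans).
#' @param taus Threshold grid.
#' @return A tibble `tau, metric, cv, mean, sd, n, n_undefined` of class
#'   `"gm_cv_table"`; cells where every scan's metric is undefined carry
#'   `cv = NA` with `n = 0`.
#' @export
cv_sweep <- function(cohort, taus = seq(0.05, 0.95, by = 0.05)) {
  if (nrow(cohort) < 2) abort("cv_sweep: need at least 2 scans")
  if (is.null(cohort$connectome)) cohort <- cohort_connectomes(cohort)
  pooled <- pool_weights(cohort)
  out <- purrr::map_dfr(taus, function(tau) {
    m <- compute_metrics(cohort, tau = tau, phi = percentile_cutoff(pooled, tau))
    m |>
      dplyr::group_by(.data$tau, .data$metric) |>
      dplyr::summarise(
        n = sum(!is.na(.data$value)),
        n_undefined = sum(is.na(.data$value)),
        mean = mean(.data$value, na.rm = TRUE),
        sd = sd(.data$value, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        cv = dplyr::if_else(.data$n >= 2 & abs(.data$mean) > 0,
                            100 * .data$sd / abs(.data$mean), NA_real_)
      )
  })
  out <- dplyr::select(out, "tau", "metric", "cv", "mean", "sd", "n", "n_undefined")
  class(out) <- c("gm_cv_table", class(out))
  out
}
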