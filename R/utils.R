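#' @importFrom rlang abort warn inform %||%
#' @importFrom stats quantile sd rnorm rbinom runif rpois predict median
#' @importFrom utils head modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage sub-seed fan-out from one global seed; kept below
# 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(as.character(stage))) * 1009L
  as.integer((abs(seed) * 97 + offset) %% 2147483629)
}

ms_profiles <- function() c("CIS", "RR", "PP", "SP")

assert_profile <- function(x) {
  bad <- setdiff(unique(as.character(x)), ms_profiles())
  if (length(bad) > 0) {
    abort(paste0("unknown clinical profile(s): ", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

metric_names <- function() c("BC", "r", "T", "Eg", "Q", "D")
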