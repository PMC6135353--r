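#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov coef lm lowess pnorm quantile rbinom rnorm rpois
#'   runif sd var complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package route
# through this so callers' streams are never clobbered.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible stage seed from a master seed
#'
#' Splits one master seed into named per-stage substreams so pipeline stages
#' can be rerun in isolation with the same realisation. The derivation hashes
#' the stage name into an integer offset; it is deterministic across
#' platforms and keeps results below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

stop_if_not_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
}
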