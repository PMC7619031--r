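#' @importFrom stats rnorm rbinom plogis pchisq pnorm qnorm sd cor kmeans
#'   logLik AIC lm wilcox.test cor.test coef vcov setNames complete.cases
#' @importFrom utils head
NULL

# Classed conditions so callers can distinguish bad input from bad state.
stop_drm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "drm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are derived from one master seed by a fixed counter scheme:
#' `seed_k = (master * 2654435761 + k * 40503) mod (2^31 - 1)` (classic
#' Knuth multiplicative-hashing constants). Every pipeline stage draws its
#' seed this way, so any stage is independently replayable from
#' `(master_seed, stage counter)` and all derived seeds stay in integer
#' range.
#'
#' @param master_seed integer master seed.
#' @param k nonnegative integer stage counter.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, k) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 2654435761 + k * 40503) %% m)
}

# role labels for lure rows in a trial table
LURE_ROLES <- c("lure_close", "lure_far")

lure_rows <- function(table) {
  if ("role" %in% names(table)) table$role %in% LURE_ROLES else rep(TRUE, nrow(table))
}
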