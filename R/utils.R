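#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov var mad median pchisq phyper pnorm quantile
#'   rbinom rlnorm rnorm runif sd uniroot rexp setNames p.adjust
#' @importFrom utils combn head read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Condition constructors: every module raises a classed condition so the
## pipeline can name the failing stage.
coexmeta_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "coexmeta_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
stop_config        <- function(msg, ...) coexmeta_stop("coexmeta_config_error", msg, ...)
stop_format        <- function(msg, ...) coexmeta_stop("coexmeta_format_error", msg, ...)
stop_stats         <- function(msg, ...) coexmeta_stop("coexmeta_stats_error", msg, ...)
stop_network       <- function(msg, ...) coexmeta_stop("coexmeta_network_error", msg, ...)
stop_survival      <- function(msg, ...) coexmeta_stop("coexmeta_survival_error", msg, ...)
stop_consensus     <- function(msg, ...) coexmeta_stop("coexmeta_consensus_error", msg, ...)
stop_normalization <- function(msg, ...) coexmeta_stop("coexmeta_normalization_error", msg, ...)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generators are pure
#' functions of their seed argument and never perturb the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-study child seed from a root seed
#'
#' Fixed splitting rule: `(root * 48271 + index * 16807) mod (2^31 - 1)`,
#' so each study's seed depends only on the root seed and its index —
#' adding a study never changes the data of earlier studies.
#'
#' @param root_seed integer root seed.
#' @param index positive integer study index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, index) {
  m <- 2147483647
  s <- (as.numeric(root_seed) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% m + 1)
}

#' Canonical keys for undirected edges
#'
#' `"lo|hi"` with endpoints in lexicographic order, so two edge lists can
#' be compared as sets regardless of orientation.
#'
#' @param a,b character vectors of endpoints.
#' @return character vector of canonical keys.
#' @export
edge_keys <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "|")
}
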