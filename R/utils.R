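#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rbinom rnorm runif rgamma qnorm pnorm pt plogis
#'   cor sd median p.adjust fisher.test quantile setNames
#' @importFrom utils read.delim write.table combn head packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cellqtl <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop_cellqtl(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || is.na(seed)) stop_cellqtl("`seed` must be a single integer")
  as.integer(seed)
}

# Run generator code under a local RNG state so generators are pure
# functions of (config, seed) and never disturb the caller's stream.
with_rng <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a > b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}
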