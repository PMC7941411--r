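#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats lm rnorm runif sd t.test var quantile setNames
#' @importFrom utils head read.csv write.csv
#' @importFrom grDevices rgb2hsv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state so callers' streams are never
## disturbed and results are reproducible from `seed` alone.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Derive a per-item seed from a base seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %%
    .Machine$integer.max)
}

cqMessage <- function(...) message("[CobQuant] ", ...)

stopValidation <- function(...) {
  stop(structure(
    class = c("cq_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stopCoverage <- function(...) {
  stop(structure(
    class = c("cq_coverage_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

## Largest-remainder apportionment of n among fractions that sum to 1.
allocateCounts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
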