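#' @importFrom stats runif
#' @importFrom utils head tail modifyList
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Generators take explicit seeds; no global state.
with_local_seed <- function(seed, expr) {
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

# sample() without the length-1 surprise
sample_one <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

sample_k <- function(x, k) {
  if (k == 0L) return(x[0])
  x[sample.int(length(x), k)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bt_stop <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "bteval_error")))
}

harmonic_f1 <- function(recall, precision) {
  if (!is.finite(recall) || !is.finite(precision)) return(0)
  if (recall + precision <= 0) return(0)
  2 * recall * precision / (recall + precision)
}
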