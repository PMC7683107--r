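#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate coef cor median optim predict quantile rbinom
#'   rnorm runif sd var setNames
#' @importFrom utils capture.output head write.csv
NULL

# Derive a reproducible child seed from a parent seed and a stream index.
# Keeps results below .Machine$integer.max so set.seed() always accepts them.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483587) + 1L
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

msg <- function(..., verbose = getOption("strokesep.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
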