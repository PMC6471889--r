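#' @useDynLib growthseq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm optimize pbeta pf quantile rhyper rlnorm
#'   rmultinom rnorm runif sd var rbeta setNames
#' @importFrom utils read.delim write.table
"_PACKAGE"

## Run `code` under a fixed RNG seed without disturbing the caller's RNG
## stream. All exported functions that consume randomness route through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed derivation: one master seed fans out to labelled
## streams (simulation, rarefaction, splits, ...) so that stages never share
## or perturb each other's RNG streams. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483587 + 1)
}

## Coefficient of variation with the population (divide-by-n) SD convention.
cv_pop <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / abs(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
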