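#' @useDynLib ReVarNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats phyper pchisq ppois pnorm pt qnorm rbeta rbinom rlnorm
#'   rnorm runif p.adjust fisher.test wilcox.test setNames ks.test rpois
#' @importFrom utils head write.table read.table
NULL

## log(mean(exp(x))) without overflow
logMeanExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) stop("no finite values to average")
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Derive a per-stage RNG seed from the global seed so generators can be
## re-run independently and still be jointly reproducible. Kept below 2^31.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Combine independent p-values with Fisher's method
#'
#' \eqn{X = -2\sum_i \log p_i} is referred to a chi-squared distribution with
#' \eqn{2k} degrees of freedom, \eqn{k} the number of p-values combined.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
#' @examples
#' fisherMethod(c(0.05, 0.05))
fisherMethod <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1))
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

## one-sided (upper) Fisher exact p for 2x2 tables given as vectors:
## a successes among n1 (cases), c successes among n2 (controls).
## Identical to fisher.test(alternative = "greater") but vectorized.
fisherOneSided <- function(a, n1, c, n2) {
  phyper(a - 1, n1, n2, a + c, lower.tail = FALSE)
}

## largest-remainder apportionment of n into shares proportional to `prop`
largestRemainder <- function(n, prop) {
  stopifnot(abs(sum(prop) - 1) < 1e-8)
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## countOverlaps across objects from different sources: a missing seqlevel
## simply means zero overlaps, not a user error worth a warning
quietCountOverlaps <- function(query, subject, ...) {
  if (length(subject) == 0L || length(query) == 0L)
    return(integer(length(query)))
  suppressWarnings(GenomicRanges::countOverlaps(query, subject, ...))
}
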