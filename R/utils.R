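# Internal helpers shared across modules.

#' @importFrom stats pnorm qnorm pchisq qchisq median rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

Z975 <- 1.959964

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic child seed: keep within 32-bit signed range.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
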