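# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; independent stages
#' (schedule, responses, noise, permutations, ...) draw from substreams derived
#' by hashing the stream name, so stages stay reproducible independently of
#' each other.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return an integer seed (always < 2^31).
#' @export
substream_seed <- function(seed, name) {
  v <- as.numeric(utf8ToInt(name))
  h <- sum(v * seq_along(v) * 2654435) %% 2147483629
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# truncated normal on (0, Inf) by inverse-cdf sampling
rtruncnorm_pos <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}
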