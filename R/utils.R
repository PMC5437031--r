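#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage (fold assignment, model fits, fixture generation,
#' hyperparameter draws) draws its seed from one global seed through this
#' mixing function, so stages are independently reproducible and two stages
#' never share an RNG stream. The derived seed is always in [1, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param stage character tag naming the stage (e.g. "cv-repeat-3").
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; Lehmer-style mixing below it
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  s <- (abs(seed) %% m)
  as.integer((((s * 48271) %% m) + h) %% (m - 1L) + 1)
}

# evaluate expr with a local RNG state (does not disturb caller's stream)
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarChr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  invisible(x)
}
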