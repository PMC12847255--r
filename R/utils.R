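#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream. A `NULL` seed runs `code` on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stage sub-seed from a global seed
#'
#' Counter-based scheme: each pipeline stage gets a reproducible sub-seed
#' so stages can be rerun in isolation. Result is always in
#' \[1, 2^31 - 2\].
#'
#' @param seed global integer seed.
#' @param stage integer stage counter (>= 0).
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), is.numeric(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.numeric(seed)) %% m) + 1
  # two multiplicative hops per stage step keep successive sub-seeds decorrelated
  for (i in seq_len(stage + 1L)) s <- (s * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)
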