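#' Derive a substream seed from a global seed and a stream name
#'
#' All randomness in the pipeline flows from one global integer seed. Each
#' stage draws from its own named substream so that adding draws to one stage
#' never perturbs another. The derivation is a fixed integer hash of the
#' stream name mixed with the global seed (and an optional index, e.g. a
#' subject number); results stay below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stream character scalar naming the substream (e.g. "tractography").
#' @param index optional non-negative integer sub-index (default 0).
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.character(stream), length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 5381
  for (ch in utf8ToInt(stream)) h <- (h * 33 + ch) %% m
  val <- (h + (abs(seed) %% m) * 48271 + (abs(index) %% m) * 69621) %% m
  as.integer(val)
}

# Run code with a seeded RNG, restoring the caller's RNG state afterwards.
with_substream <- function(seed, stream, code, index = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream, index))
  force(code)
}
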