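#' Evaluate an expression under a named RNG substream
#'
#' All simulator randomness flows from one master seed through named
#' substreams, so each generation stage is independently reproducible and
#' adding draws to one stage does not perturb another. The caller's RNG
#' state is saved and restored.
#'
#' @param seed master integer seed.
#' @param name substream label.
#' @param expr expression to evaluate.
#' @return Value of `expr`.
#' @export
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# deterministic 31-bit sub-seed from (seed, label); simple string hash,
# kept below 2^31 - 1 so set.seed() always accepts it
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}
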