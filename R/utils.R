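# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed derived from a base seed and a tag, so each
# generated artefact draws from its own reproducible stream regardless of
# the order artefacts are produced in.
subSeed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a local RNG state with a fixed seed.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Uniform bin edges helper.
uniformEdges <- function(lo, hi, width) {
  n <- round((hi - lo) / width)
  if (n < 1 || abs(lo + n * width - hi) > 1e-9 * width)
    stop("range is not an integer number of bins")
  lo + width * (0:n)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
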