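#' @keywords internal
"_PACKAGE"

# Run code with a private RNG stream so generators never disturb (or depend
# on) the caller's global random state. Seeds are explicit everywhere.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + 7919L * as.double(k)) %% 2147483647)
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
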