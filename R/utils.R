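#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Canonical unordered-pair key on labels, for edge-set algebra.
edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")

is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x == 0L | x == 1L)
}

stop_morbnet <- function(...) stop(..., call. = FALSE)
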