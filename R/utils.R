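# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Locale-independent character sort (C collation), so ranked output is
# byte-identical across machines.
c_sort <- function(x) sort(x, method = "radix")

c_order <- function(...) order(..., method = "radix")

#' Round half away from zero
#'
#' Nearest-integer rounding with exact halves rounded away from zero
#' (so 0.5 -> 1, 2.5 -> 3, -0.5 -> -1), the convention used for all
#' reported percentages and aggregated medians in this package. A small
#' epsilon guards values that are exact halves in rational arithmetic but
#' sit just below .5 in floating point.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(0.5, 1.49, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

# Percentage of a over b, rounded per round_half_away.
pct_of <- function(a, b) round_half_away(100 * a / b)

# Evaluate `expr` with the global RNG stream saved and restored, running
# under `seed`. Keeps corpus generation from disturbing a caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit safe substream seed derived from a base seed and an index.
sub_seed <- function(base, i) {
  (as.double(base) * 48271 + as.double(i) * 16807) %% 2147483647
}

cocite_msg <- function(...) message("cocite: ", ...)
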