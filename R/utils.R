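# Internal helpers: platform-independent hashing, seed derivation, rounding.

# 32-bit FNV-1a hash of a character vector, returned as doubles in [0, 2^32).
# Arithmetic is done in doubles with an explicit 16-bit split so the 32-bit
# multiply never leaves the exactly-representable integer range.
fnv1a32 <- function(strings) {
  prime <- 16777619
  vapply(strings, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), bitwAnd(as.integer(b), 255L))
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Derive a child seed (< 2^31) from a master seed and a stage label, so every
# source of randomness flows from one integer without global state.
derive_seed <- function(seed, label) {
  as.integer(fnv1a32(paste0(label, "#", seed)) %% 2147483629)
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round values to a decimal precision step
#'
#' Rounds `x` to the nearest multiple of `precision` with ties going to the
#' even multiple (the convention of [round()]). The precision step is part of
#' the identity of duplicate keys, so the same function is used everywhere a
#' value enters a key.
#'
#' @param x Numeric vector.
#' @param precision Positive rounding step in the units of `x`
#'   (default `0.01` log units).
#' @return Numeric vector of rounded values.
#' @examples
#' round_to_precision(-2.344, 0.01) # -2.34
#' @export
round_to_precision <- function(x, precision = 0.01) {
  if (!is.numeric(precision) || length(precision) != 1L || precision <= 0)
    stop("`precision` must be a single positive number")
  digits <- max(0L, as.integer(ceiling(-log10(precision))) + 2L)
  round(round(x / precision) * precision, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable check that a data.frame has the required columns.
require_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
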