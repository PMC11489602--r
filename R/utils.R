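# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half-to-even; clinical tables are conventionally
#' formatted half-up (so 47.45 prints as 47.5, not 47.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Deterministic 31-bit hash of a character string (FNV-style, double
# arithmetic; 31 * 2^31 < 2^53 so no precision loss). Used to key per-pair
# RNG substreams by variable name so results are invariant to column order.
string_hash31 <- function(s) {
  h <- 2166136261 %% 2147483647
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Derive a substream seed (< 2^31) from a master seed and a label.
substream_seed <- function(master_seed, label) {
  as.integer((as.double(master_seed) %% 2147483647 + string_hash31(label)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(expr)
}
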