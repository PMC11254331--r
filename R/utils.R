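# Internal helpers shared across modules.

# Nearest-integer rounding, halves away from zero. base::round() rounds
# halves to even, which would turn 6/18 = 33.33 -> 33 but 12.5 -> 12; the
# explorer-style percents round 0.5 up.
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Fixed-precision number formatting for deterministic SVG output.
fmt_num <- function(x, digits = 2L) {
  formatC(x, format = "f", digits = digits)
}
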