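# Shared numerical helpers.

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

logistic <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# round() in R rounds half to even; kernel sizing and seconds->samples
# conversion use conventional half-away-from-zero rounding.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
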