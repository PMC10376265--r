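# Deterministic seed splitting. Every stochastic generator derives its own
# 32-bit seed from (master seed, stream, timepoint, replicate) so that any
# single output can be regenerated in isolation, bit-identically, regardless
# of call order.

STREAM_IMAGES <- 1L
STREAM_CALIB <- 2L
STREAM_FLOW <- 3L
STREAM_GROWTH <- 4L

split_seed <- function(seed, stream, time_h = 0, replicate = 0L,
                       treatment = "control") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tp_code <- round(time_h * 10)
  trt_code <- switch(treatment, control = 0L, hc = 1L, hu = 2L, 3L)
  # mix below 2^53 to stay exact in doubles, then reduce mod (2^31 - 1)
  x <- (abs(seed) %% 2147483647) * 69621
  x <- (x + stream * 754913 + tp_code * 60493 + replicate * 4099 +
          trt_code * 7919) %% 2147483647
  as.integer(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
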