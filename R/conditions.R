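# Structured conditions so callers (and tests) can distinguish bad data from
# bad files from training blow-ups.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wntlink_validation_error", "wntlink_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wntlink_format_error", "wntlink_error")))
}

stop_training <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("wntlink_training_error", "wntlink_error")))
}

warn_wntlink <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "wntlink_warning"))
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
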