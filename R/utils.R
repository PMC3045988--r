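## Internal helpers shared across the pipeline.

## Deterministic sub-seed derivation: one master integer seed fans out to
## per-stage / per-replicate seeds. Kept strictly below 2^31 - 1.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 1000003) %% 2147483647)
}

.assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}
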