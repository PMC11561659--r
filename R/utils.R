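# Internal helpers.

# Derive an independent, reproducible sub-seed from a master seed. Keeps the
# result inside the positive 32-bit integer range.
substream_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  v <- (as.double(seed) %% 2147483647) * 2654435 + 97 * stream
  as.integer(v %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

sandi_metric_names <- function() c("f_in", "f_is", "f_ec", "r_s", "D_in", "D_ec")
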