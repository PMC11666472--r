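#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a parent seed and integer tags; stays < 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) x <- (x * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(x)
}

## Population standard deviation (denominator n).
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

## sample() without the length-1 surprise
resample <- function(x) x[sample.int(length(x))]

abort <- function(msg, class) {
  stop(structure(class = c(class, "sentencode_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
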