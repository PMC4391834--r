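# Internal helpers shared across modules.

# x * log2(x) with the 0*log(0) = 0 convention used by the map equation.
plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a given seed without disturbing the caller's RNG stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_named_vector <- function(x) {
  is.atomic(x) && !is.null(names(x)) && all(nzchar(names(x)))
}

# Small deterministic fingerprint (polynomial rolling hash over the JSON
# serialization) used to stamp pipeline outputs so artifacts can be traced
# back to their configuration.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
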