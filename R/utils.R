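# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_flag <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_config(field, msg)
}

# Derive a deterministic child seed from a parent seed and a stream label.
# Keeps results independent across components while remaining reproducible
# from the single user-facing seed. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483629L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_binary <- function(x) all(x %in% c(0L, 1L))

as_binary <- function(x, what = "labels") {
  if (is.logical(x)) x <- as.integer(x)
  if (is.factor(x)) x <- as.integer(x) - 1L
  x <- as.integer(x)
  if (!is_binary(x[!is.na(x)])) {
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  }
  x
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}
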