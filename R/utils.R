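# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# normalize a free-text key: trim, squeeze internal whitespace, lower-case
norm_key <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

# numerically stable log(exp(x) + exp(y)), vectorized
logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  # when both are -Inf the max is -Inf; the sum is then -Inf as well
  out <- m + log1p(exp(pmin(x, y) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# percentage rounded to 2 decimals, the display convention of the output tables
pct2 <- function(n, total) round(100 * n / total, 2)

# run code with a private RNG stream, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
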