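# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so that a master seed fully determines every output.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative lognormal noise factor with mean 1 and coefficient of
# variation `cv` (cv = 0 returns exactly 1).
lnFactor <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}

geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values",
                        call. = FALSE)
  10^mean(log10(x))
}

# Nearest sample day to `day` within +/- tol; NA if none.
matchDay <- function(days, day, tol = 0.5) {
  d <- abs(days - day)
  i <- which.min(d)
  if (length(i) == 0L || d[i] > tol + 1e-9) return(NA_integer_)
  i
}

stopNamed <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
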