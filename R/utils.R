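#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state, so
#' generator calls are reproducible without clobbering the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a parent seed and an index; keeps every
# seed below .Machine$integer.max so set.seed() always accepts it.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1117) %% 2147483629)
}

# Shape parameters of a Beta distribution with the given mean and sd.
beta_shapes <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("swb_spread too large for a Beta distribution with mean ",
         mean, call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Two-sided p-values of the Pearson correlation between each column of `x`
# and `y`, computed from the t transform. Zero-variance columns give NA.
pearson_pvalues <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) return(rep(NA_real_, ncol(x)))
  sds <- apply(x, 2, stats::sd)
  r <- rep(NA_real_, ncol(x))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(x[, ok, drop = FALSE], y))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!ok] <- NA_real_
  p
}

# Rounds half to even at 4 decimals (the precision used when reporting
# normalized scale statistics).
round4 <- function(x) round(x, 4)

`%||%` <- function(a, b) if (is.null(a)) b else a
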