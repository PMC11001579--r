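#' @keywords internal
"_PACKAGE"

## numerically stable softplus: log(1 + exp(x))
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

## min-max rescale to [0, 1]; constant input maps to 0
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

## column z-score; constant columns become 0 rather than NaN
zscore_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd < .Machine$double.eps] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}

## derive a named child seed from a root seed, keeping it a valid 32-bit int
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## linear interpolation onto new time points, constant extrapolation
interp_trace <- function(t, x, t_out) {
  stats::approx(t, x, xout = t_out, rule = 2)$y
}
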