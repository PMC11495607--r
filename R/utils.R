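# Internal helpers: seeded RNG scoping, slice sampling, chain diagnostics.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls stay side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive `n` child seeds from a master seed, all below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2146000000L, n))
}

stop_mrpsup <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Univariate slice sampler with stepping out (Neal 2003), used for
# group-sd and categorical-logit coefficient updates.
slice1 <- function(x0, logf, w = 0.5, lower = -Inf, upper = Inf, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop_mrpsup("slice sampler started from a zero-density point")
  y <- f0 + log(runif(1))
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  steps <- floor(max_steps * runif(1))
  while (steps > 0 && L > lower && logf(max(L, lower)) > y) {
    L <- L - w
    steps <- steps - 1L
  }
  steps <- max_steps - steps
  while (steps > 0 && R < upper && logf(min(R, upper)) > y) {
    R <- R + w
    steps <- steps - 1L
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Split-R-hat (Gelman et al.): chains is a list of equal-length numeric
# vectors holding one parameter's draws per chain.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-12) return(if (B < 1e-12) 1 else Inf)
  sqrt((W * (n - 1) / n + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains after centering each.
ess_basic <- function(chains) {
  n <- length(chains[[1]])
  m <- length(chains)
  x <- unlist(lapply(chains, function(v) v - mean(v)))
  if (sd(x) < 1e-12) return(n * m)
  rho <- numeric(0)
  lag <- 1L
  denom <- sum(x^2)
  repeat {
    r <- 0
    for (c in seq_len(m)) {
      v <- chains[[c]] - mean(chains[[c]])
      if (lag < n) r <- r + sum(v[1:(n - lag)] * v[(lag + 1):n])
    }
    r <- r / denom
    if (lag > 1L && lag %% 2L == 1L && rho[lag - 1L] + r < 0) break
    rho[lag] <- r
    lag <- lag + 1L
    if (lag >= n) break
  }
  tau <- 1 + 2 * sum(rho)
  max(1, n * m / max(tau, 1e-3))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_count <- function(x, name) {
  if (!is_scalar_number(x) || x < 1 || x != round(x)) {
    stop_mrpsup(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}
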