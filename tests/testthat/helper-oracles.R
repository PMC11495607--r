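# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force counting for PSup, full
# enumeration for permutation tests, Monte-Carlo simulation for the
# closed-form population values.

# PSup by explicit pairwise counting.
oracle_psup <- function(a, b) {
  stopifnot(length(a) == length(b))
  num <- 0
  for (i in seq_along(a)) {
    if (a[i] > b[i]) num <- num + 1
    else if (a[i] == b[i]) num <- num + 0.5
  }
  num / length(a)
}

# Exact two-sided c-value by enumerating every pair-swap pattern.
oracle_exact_cvalue <- function(a, b) {
  n <- length(a)
  obs_dev <- abs(oracle_psup(a, b) - 0.5)
  extreme <- 0
  for (mask in 0:(2^n - 1)) {
    aa <- a; bb <- b
    for (i in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) {
        tmp <- aa[i]; aa[i] <- bb[i]; bb[i] <- tmp
      }
    }
    if (abs(oracle_psup(aa, bb) - 0.5) >= obs_dev - 1e-12) extreme <- extreme + 1
  }
  extreme / 2^n
}

# Small synthetic geography shared by the fitting tests: 4 states,
# modest population, single-party model to keep the cell count low.
small_spec <- function(total = 60000, parties = 1) {
  pm <- if (parties == 1) party_model(parties = "All") else NULL
  population_spec(levels = default_levels(4), total_population = total,
                  party_model = pm %||% default_party_model(default_levels(4)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced formula for small fits (no party when the table has one party).
small_formula <- function() {
  formula_spec(fixed = c("sex", "region", "state_hesitancy_z"),
               varying = c("age_band", "education", "income", "race", "state",
                           "sex:race", "education:age_band"))
}

# 99% two-sided binomial bounds on a proportion estimated from n draws.
binom_bounds99 <- function(p, n) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p)) / n
}
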