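#' ROPE and graded effect-size thresholds for PSup decisions
#'
#' The region of practical equivalence on the PSup scale defaults to
#' (.47, .53); graded thresholds mark increasingly large effects: .53
#' (non-negligible), .60 (supermajority preference), .67 (2:1 ratio),
#' .75 (3:1 ratio), mirrored below 0.5 as `1 - t` for inferiority.
#'
#' @param lower,upper ROPE bounds (within `[0, 1]`, `lower < upper`).
#' @param thresholds Sorted vector of graded thresholds above 0.5.
#' @return An object of class `rope_config`.
#' @export
rope_config <- function(lower = 0.47, upper = 0.53,
                        thresholds = c(0.53, 0.60, 0.67, 0.75)) {
  if (!(lower >= 0 && upper <= 1 && lower < upper)) {
    stop_mrpsup("rope_config: need 0 <= lower < upper <= 1")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_mrpsup("rope_config: thresholds must be strictly increasing")
  }
  structure(list(lower = lower, upper = upper, thresholds = thresholds),
            class = "rope_config")
}

#' Classify a posterior PSup against the ROPE and graded thresholds
#'
#' A "reliable difference" requires the whole 95% HDI outside the ROPE.
#' Each graded threshold `t` is flagged when the HDI lies entirely beyond
#' it in the effect's direction: above `t` for superiority (HDI above the
#' ROPE), below `1 - t` for inferiority.
#'
#' @param psup A `psup_result` with posterior draws (or explicit HDI).
#' @param cfg A [rope_config()].
#' @return One-row data frame: pair, mean, HDI, `reliable`, direction, and
#'   one logical column per threshold (`beyond_0.53`, ...).
#' @export
rope_classify <- function(psup, cfg = rope_config()) {
  lo <- psup$hdi_lower
  hi <- psup$hdi_upper
  if (!is.finite(lo) || !is.finite(hi)) {
    stop_mrpsup("rope_classify: psup result has no HDI (posterior draws needed)")
  }
  if (lo < 0 || hi > 1) stop_mrpsup("rope_classify: HDI outside [0, 1]")
  above <- lo > cfg$upper
  below <- hi < cfg$lower
  direction <- if (above) "superior" else if (below) "inferior" else "none"
  flags <- vapply(cfg$thresholds, function(t) {
    (above && lo > t) || (below && hi < 1 - t)
  }, logical(1))
  out <- data.frame(
    item_a = psup$pair[1], item_b = psup$pair[2],
    mean = psup$mean, hdi_lower = lo, hdi_upper = hi,
    reliable = above || below, direction = direction,
    row.names = NULL
  )
  for (i in seq_along(cfg$thresholds)) {
    out[[sprintf("beyond_%.2f", cfg$thresholds[i])]] <- flags[i]
  }
  out
}

#' Paired-permutation randomization test on PSup
#'
#' Permutations independently swap each respondent's (a, b) pair with
#' probability one half; the c-value is the fraction of permutations whose
#' PSup is as or more extreme (two-sided around 0.5) than the observed
#' PSup.
#'
#' @param a,b Paired rating vectors (n >= 2 complete pairs).
#' @param permutations Number of random pair swaps (default 1000).
#' @param seed Integer seed (exactly reproducible).
#' @param exact If `TRUE` (or n <= `exact_limit` when `exact = NA`),
#'   enumerate all 2^n swap patterns instead of sampling.
#' @param exact_limit Maximum n for enumeration.
#' @param pair Item labels.
#' @return An object of class `randomization_result`: observed PSup,
#'   c-value, permutation count.
#' @export
randomization_test <- function(a, b, permutations = 1000, seed = 1,
                               exact = FALSE, exact_limit = 14L,
                               pair = c("A", "B")) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop_mrpsup("randomization_test: need at least 2 complete pairs")
  # per-pair contribution to PSup, in half units of 1/(2n)
  contrib <- 2L * ((a > b) + 0.5 * (a == b)) # integers 0,1,2
  obs2n <- sum(contrib) # observed PSup * 2n
  dev_obs <- abs(obs2n - n)
  if (is.na(exact)) exact <- n <= exact_limit
  if (exact) {
    if (n > 25) stop_mrpsup("exact enumeration infeasible for n > 25")
    # enumerate all swap patterns; swapping pair i maps contrib -> 2 - contrib
    total <- 0
    extreme <- 0
    for (mask in 0:(2^n - 1)) {
      flips <- as.integer(intToBits(mask))[seq_len(n)]
      s <- sum(ifelse(flips == 1L, 2L - contrib, contrib))
      total <- total + 1
      if (abs(s - n) >= dev_obs) extreme <- extreme + 1
    }
    cval <- extreme / total
    perms <- total
  } else {
    permutations <- assert_scalar_count(permutations, "permutations")
    cval <- with_seed(seed, {
      Fm <- matrix(runif(permutations * n) < 0.5, permutations, n)
      s2n <- Fm %*% (2 - contrib) + (!Fm) %*% contrib
      mean(abs(s2n - n) >= dev_obs)
    })
    perms <- permutations
  }
  structure(
    list(pair = pair, observed = obs2n / (2 * n), c_value = cval,
         n = n, permutations = perms, exact = exact),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result: %s vs %s>\n", x$pair[1], x$pair[2]))
  cat(sprintf("  observed PSup %.3f, c = %.4f (%s%d permutations, n = %d)\n",
              x$observed, x$c_value, if (x$exact) "exact, " else "",
              x$permutations, x$n))
  invisible(x)
}

#' Select comparisons under a cumulative c-value budget
#'
#' Orders comparisons by ascending c-value (ties broken by label) and
#' selects from the top while the running sum of selected c-values stays
#' within the budget — the rule holding expected false positives per
#' comparison set near the budget.
#'
#' @param c_values Numeric vector of c-values in `[0, 1]`.
#' @param budget Cumulative budget (default 0.05).
#' @param labels Comparison labels (defaults to names, else indices).
#' @return Data frame sorted by ascending c-value with columns `label`,
#'   `c_value`, `cumulative`, `selected`.
#' @export
select_within_budget <- function(c_values, budget = 0.05, labels = NULL) {
  if (any(c_values < 0 | c_values > 1, na.rm = TRUE)) {
    stop_mrpsup("select_within_budget: c-values must be in [0, 1]")
  }
  labels <- labels %||% names(c_values) %||% as.character(seq_along(c_values))
  ord <- order(c_values, labels)
  cs <- cumsum(c_values[ord])
  data.frame(
    label = labels[ord],
    c_value = c_values[ord],
    cumulative = cs,
    selected = if (budget <= 0) rep(FALSE, length(cs)) else cs <= budget + 1e-12,
    row.names = NULL
  )
}
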