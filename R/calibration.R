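# Simulation-based calibration of the two decision rules: the ROPE
# false-positive rate under null paired ratings, and the expected
# false-positive percentage of the cumulative c-value budget per set of
# null pairwise comparisons.

#' Configuration for calibration simulations
#'
#' The null response model makes items exchangeable within respondent:
#' each respondent has a latent trait `theta ~ N(0, respondent_sd^2)` and
#' each item adds independent standard normal noise; cutpoints are the
#' marginal quantiles giving equal category probabilities, so items are
#' identically distributed and any apparent pairwise difference is a false
#' positive.
#'
#' @param replicates Number of simulated comparisons (ROPE) or comparison
#'   sets (budget rule).
#' @param n Respondents per replicate.
#' @param K Likert scale size (>= 3).
#' @param items Items per set (pairwise comparisons = `items` choose 2;
#'   2 for the ROPE assessment).
#' @param respondent_sd SD of the shared respondent trait (induces the
#'   within-subject correlation real paired ratings have).
#' @param rope A [rope_config()].
#' @param budget Cumulative c-value budget.
#' @param permutations Permutations per randomization test.
#' @param psup_draws Posterior draws for the fast PSup posterior.
#' @param level HDI mass.
#' @param seed Integer seed.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(replicates = 500, n = 1500, K = 7, items = 2,
                               respondent_sd = 1, rope = rope_config(),
                               budget = 0.05, permutations = 1000,
                               psup_draws = 4000, level = 0.95, seed = 1) {
  replicates <- assert_scalar_count(replicates, "replicates")
  n <- assert_scalar_count(n, "n")
  K <- assert_scalar_count(K, "K")
  items <- assert_scalar_count(items, "items")
  if (K < 3) stop_mrpsup("calibration_config: K must be >= 3")
  if (respondent_sd < 0) stop_mrpsup("calibration_config: respondent_sd must be >= 0")
  structure(
    list(replicates = replicates, n = n, K = K, items = items,
         respondent_sd = respondent_sd, rope = rope, budget = budget,
         permutations = permutations, psup_draws = psup_draws,
         level = level, seed = seed),
    class = "calibration_config"
  )
}

# n x items matrix of exchangeable null ordinal responses.
simulate_null_items <- function(n, K, items, respondent_sd) {
  theta <- rnorm(n, 0, respondent_sd)
  marg_sd <- sqrt(1 + respondent_sd^2)
  cuts <- qnorm(seq_len(K - 1) / K) * marg_sd
  latent <- theta + matrix(rnorm(n * items), n, items)
  resp <- matrix(1L, n, items)
  for (cp in cuts) resp <- resp + (latent > cp)
  resp
}

#' Conjugate posterior draws of PSup from comparison counts
#'
#' Dirichlet(1, 1, 1) prior over the (greater, equal, less) probabilities;
#' each posterior draw gives `PSup = p_greater + 0.5 p_equal`. This is the
#' fast path for calibration — under the null the covariate structure is
#' uninformative, so the full MRP posterior and this conjugate posterior
#' target the same quantity.
#'
#' @param greater,equal,less Comparison-category counts.
#' @param draws Number of posterior draws.
#' @param prior Dirichlet concentration parameters.
#' @return Numeric vector of PSup draws.
#' @export
psup_posterior_dirichlet <- function(greater, equal, less, draws = 4000,
                                     prior = c(1, 1, 1)) {
  g <- rgamma(draws, greater + prior[1])
  e <- rgamma(draws, equal + prior[2])
  l <- rgamma(draws, less + prior[3])
  (g + 0.5 * e) / (g + e + l)
}

#' ROPE false-positive rate under null paired ratings
#'
#' Simulates exchangeable item pairs with no true difference and counts
#' how often the 95% PSup HDI escapes the ROPE entirely — the rate of
#' falsely concluding a reliable difference.
#'
#' @param cfg A [calibration_config()] (items is forced to 2).
#' @param method `"dirichlet"` for the conjugate fast posterior (default),
#'   `"mrp"` for full MRP fits on a small synthetic population (slow; used
#'   to confirm the fast path).
#' @param spec Population spec for `method = "mrp"`.
#' @param mrp_args Extra arguments passed to [psup_mrp()] for
#'   `method = "mrp"`.
#' @return List: `fraction` (false-positive fraction), `percent`, `count`,
#'   `replicates`, `se` (Monte-Carlo standard error of the fraction).
#' @export
simulate_rope_fpr <- function(cfg = calibration_config(), method = c("dirichlet", "mrp"),
                              spec = NULL, mrp_args = list()) {
  method <- match.arg(method)
  seeds <- child_seeds(cfg$seed, cfg$replicates)
  hits <- logical(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    hits[r] <- with_seed(seeds[r], {
      if (method == "dirichlet") {
        resp <- simulate_null_items(cfg$n, cfg$K, 2L, cfg$respondent_sd)
        cmp <- derive_comparison(resp[, 1], resp[, 2])
        counts <- table(cmp)
        ps <- psup_posterior_dirichlet(counts[["greater"]], counts[["equal"]],
                                       counts[["less"]], draws = cfg$psup_draws)
        h <- hdi(ps, prob = cfg$level)
        h[1] > cfg$rope$upper || h[2] < cfg$rope$lower
      } else {
        if (is.null(spec)) {
          spec <- population_spec(levels = default_levels(4),
                                  total_population = 50000)
        }
        tab <- build_poststrat_table(spec, seed = 1000 + r)
        roster <- sample_respondents(tab, cfg$n, seed = 2000 + r)
        resp <- simulate_null_items(cfg$n, cfg$K, 2L, cfg$respondent_sd)
        roster$item_a <- resp[, 1]
        roster$item_b <- resp[, 2]
        ps <- do.call(psup_mrp, c(
          list(roster, "item_a", "item_b", table = tab,
               scale = cfg$K, level = cfg$level, seed = 3000 + r),
          mrp_args
        ))
        ps$hdi_lower > cfg$rope$upper || ps$hdi_upper < cfg$rope$lower
      }
    })
  }
  frac <- mean(hits)
  list(fraction = frac, percent = 100 * frac, count = sum(hits),
       replicates = cfg$replicates,
       se = sqrt(frac * (1 - frac) / cfg$replicates))
}

#' Expected false-positive percentage of the cumulative c-value budget
#'
#' Simulates sets of null pairwise comparisons (all items exchangeable),
#' runs a randomization test per pair, applies the ascending cumulative
#' c-value selection, and averages the percentage of comparisons selected
#' per set — the expected false-discovery percentage of the rule.
#'
#' @param cfg A [calibration_config()]; `items` sets the set size
#'   (`items` choose 2 pairwise comparisons).
#' @return List: `percent` (mean percentage selected per set), `se`
#'   (Monte-Carlo standard error), `per_replicate`, `pairs`.
#' @export
simulate_permutation_fdr <- function(cfg = calibration_config(items = 7, n = 20,
                                                              K = 5, replicates = 200)) {
  m <- cfg$items
  if (m < 2) stop_mrpsup("need at least 2 items for pairwise comparisons")
  pairs <- utils::combn(m, 2)
  npairs <- ncol(pairs)
  seeds <- child_seeds(cfg$seed, cfg$replicates)
  pct <- numeric(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    pct[r] <- with_seed(seeds[r], {
      resp <- simulate_null_items(cfg$n, cfg$K, m, cfg$respondent_sd)
      cv <- numeric(npairs)
      for (p in seq_len(npairs)) {
        rt <- randomization_test(resp[, pairs[1, p]], resp[, pairs[2, p]],
                                 permutations = cfg$permutations,
                                 seed = sample.int(.Machine$integer.max - 1L, 1))
        cv[p] <- rt$c_value
      }
      sel <- select_within_budget(cv, budget = cfg$budget)
      100 * sum(sel$selected) / npairs
    })
  }
  list(percent = mean(pct), se = sd(pct) / sqrt(cfg$replicates),
       per_replicate = pct, pairs = npairs, replicates = cfg$replicates)
}
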