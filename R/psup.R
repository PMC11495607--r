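# Within-subject probability of superiority (PSup): the probability that a
# randomly chosen respondent rates item A above item B, counting ties as
# one half. 0.5 means equivalence; PSup(A,B) + PSup(B,A) = 1.

new_psup_result <- function(pair, point = NULL, draws = NULL, tie_prop = NA_real_,
                            n = NA_integer_, level = 0.95) {
  mean_val <- if (!is.null(draws)) mean(draws) else point
  h <- if (!is.null(draws)) hdi(draws, prob = level) else c(NA_real_, NA_real_)
  structure(
    list(pair = pair, point = point, draws = draws, mean = mean_val,
         hdi_lower = h[1], hdi_upper = h[2], level = level,
         tie_prop = tie_prop, n = n),
    class = "psup_result"
  )
}

#' @export
print.psup_result <- function(x, ...) {
  cat(sprintf("<psup_result: %s vs %s>\n", x$pair[1], x$pair[2]))
  if (!is.null(x$draws)) {
    cat(sprintf("  posterior mean %.3f, %d%% HDI [%.3f, %.3f] (%d draws)\n",
                x$mean, round(100 * x$level), x$hdi_lower, x$hdi_upper,
                length(x$draws)))
  } else {
    cat(sprintf("  point estimate %.3f (n = %d)\n", x$point, x$n))
  }
  if (is.finite(x$tie_prop)) cat(sprintf("  tie proportion %.3f\n", x$tie_prop))
  invisible(x)
}

#' Sample probability of superiority for paired ratings
#'
#' `PSup = (#(a > b) + 0.5 #(a == b)) / n` over pairwise-complete pairs.
#'
#' @param a,b Equal-length paired rating vectors (same scale).
#' @param pair Labels for the two items.
#' @return A `psup_result` with the point estimate and tie proportion.
#' @export
psup_point <- function(a, b, pair = c("A", "B")) {
  if (length(a) != length(b)) stop_mrpsup("psup_point: length mismatch")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 1) stop_mrpsup("psup_point: no complete pairs")
  ties <- sum(a == b)
  val <- (sum(a > b) + 0.5 * ties) / n
  new_psup_result(pair, point = val, tie_prop = ties / n, n = n)
}

#' Population probability of superiority by MRP
#'
#' Derives the 3-level greater/equal/less comparison variable for an item
#' pair, fits a hierarchical categorical logit to it, poststratifies, and
#' per posterior draw computes
#' `PSup = P(greater) + 0.5 P(equal)` at population level.
#'
#' @param data Survey data frame containing both items.
#' @param item_a,item_b Item column names (same scale).
#' @param table Poststratification table.
#' @param formula,priors,chains,iter,warmup,seed,rhat_max,check_convergence
#'   Passed to [fit_categorical_mrp()].
#' @param scale Declared scale size of both items (optional check).
#' @param level HDI mass.
#' @return A `psup_result` with posterior draws and HDI.
#' @export
psup_mrp <- function(data, item_a, item_b, table, formula = formula_spec(),
                     priors = prior_spec(), scale = NULL, level = 0.95,
                     chains = 4, iter = 1000, warmup = 1000, seed = 1,
                     rhat_max = 1.01, check_convergence = TRUE) {
  for (it in c(item_a, item_b)) {
    if (!it %in% names(data)) stop_mrpsup("item '", it, "' not in data")
  }
  dict <- attr(data, "dictionary")
  if (is.null(scale) && !is.null(dict)) {
    ka <- dict$items[[item_a]]$K
    kb <- dict$items[[item_b]]$K
    if (!is.null(ka) && !is.null(kb) && ka != kb) {
      stop_mrpsup("psup_mrp: items are on different scales (", ka, " vs ", kb, ")")
    }
    scale <- ka
  }
  cmp <- derive_comparison(data[[item_a]], data[[item_b]],
                           scale_a = scale, scale_b = scale)
  dat <- data
  dat[[".comparison"]] <- as.character(cmp)
  dat <- dat[!is.na(cmp), , drop = FALSE]
  fit <- fit_categorical_mrp(dat, ".comparison", formula = formula,
                             priors = priors,
                             categories = c("less", "equal", "greater"),
                             chains = chains, iter = iter, warmup = warmup,
                             seed = seed, rhat_max = rhat_max,
                             check_convergence = check_convergence)
  est <- poststratify(fit, table, estimand = "category_prob", level = level,
                      seed = seed)
  draws <- est$draws[, "greater"] + 0.5 * est$draws[, "equal"]
  ties <- mean(dat$.comparison == "equal")
  res <- new_psup_result(c(item_a, item_b), draws = draws, tie_prop = ties,
                         n = nrow(dat), level = level)
  res$fit <- fit
  res
}

#' Probability of superiority of a population posterior over a fixed sample
#'
#' Compares a posterior population distribution of responses (per-draw
#' category probabilities `p`) against the empirical distribution `q` of a
#' fixed small sample, without resampling the fixed side:
#' `PSup = sum_{i>j} p_i q_j + 0.5 sum_i p_i q_i` per draw.
#'
#' @param pop A `population_estimate` with `estimand = "category_prob"`
#'   over K ordinal categories.
#' @param fixed Integer ratings of the fixed sample on the same K-point
#'   scale.
#' @param pair Labels (population item, fixed item).
#' @param level HDI mass.
#' @return A `psup_result` with posterior draws.
#' @export
psup_pop_vs_fixed <- function(pop, fixed, pair = c("population", "fixed"),
                              level = 0.95) {
  stopifnot(inherits(pop, "population_estimate"))
  if (pop$estimand != "category_prob") {
    stop_mrpsup("psup_pop_vs_fixed: pop must hold category probabilities")
  }
  K <- ncol(pop$draws)
  fixed <- fixed[!is.na(fixed)]
  if (any(fixed < 1 | fixed > K | fixed != round(fixed))) {
    stop_mrpsup("psup_pop_vs_fixed: fixed ratings outside 1..", K,
                " (scale mismatch)")
  }
  q <- tabulate(fixed, K) / length(fixed)
  S <- matrix(0, K, K)
  S[lower.tri(S)] <- 1
  diag(S) <- 0.5
  draws <- as.vector(pop$draws %*% (S %*% q))
  new_psup_result(pair, draws = draws,
                  tie_prop = sum((pop$summary$mean) * q),
                  n = length(fixed), level = level)
}
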