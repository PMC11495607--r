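# Poststratification: per posterior draw, predict each population cell and
# average predictions weighted by cell counts.

# Linear predictor draws for the table's cells: draws x cells matrix for
# one "channel" (the ordinal latent mean, or one category's logit).
# Levels unseen at fit time get effects drawn from the fitted
# population-of-effects distribution (partial-pooling prediction), with a
# dedicated RNG stream so poststratification is reproducible.
cell_eta_draws <- function(fit, table, draw_idx, channel = 1L, unseen_cache) {
  D <- length(draw_idx)
  nc <- nrow(table)
  fd <- build_fixed_design(table, fit$formula$fixed, meta = fit$fixed_terms)
  X <- fd$X
  if (fit$family == "categorical_logit") X <- cbind(`(Intercept)` = 1, X)
  P <- ncol(X)
  NC <- if (fit$family == "categorical_logit") length(fit$categories) - 1L else 1L
  beta <- fit$draws$beta
  bcols <- if (fit$family == "categorical_logit") {
    (channel - 1L) * P + seq_len(P)
  } else {
    seq_len(P)
  }
  eta <- if (P > 0) {
    beta[draw_idx, bcols, drop = FALSE] %*% t(X)
  } else {
    matrix(0, D, nc)
  }
  gi <- build_group_index(table, fit$formula$varying, levels_list = fit$group_levels)
  sd_draws <- fit$draws$sd
  for (f in names(gi$index)) {
    idx <- gi$index[[f]]
    L <- length(fit$group_levels[[f]])
    ucols <- (channel - 1L) * L + seq_len(L)
    U <- fit$draws$u[[f]][draw_idx, ucols, drop = FALSE]
    unseen <- which(idx == 0L)
    if (length(unseen)) {
      key <- factor_key(table, f)
      new_levels <- unique(key[unseen])
      sd_col <- if (fit$family == "categorical_logit") {
        paste(f, fit$categories[channel + 1L], sep = "|")
      } else {
        f
      }
      sdv <- sd_draws[draw_idx, sd_col]
      extra <- unseen_cache$get(f, channel, new_levels, sdv, length(draw_idx))
      U <- cbind(U, extra)
      idx[unseen] <- L + match(key[unseen], new_levels)
    }
    eta <- eta + U[, idx, drop = FALSE]
  }
  eta
}

# Cache of simulated effects for unseen levels, keyed by factor/channel,
# so every chunk of draws reuses the same values.
make_unseen_cache <- function(seed) {
  store <- new.env(parent = emptyenv())
  seeds <- child_seeds(seed, 1000L)
  counter <- 0L
  list(get = function(f, channel, new_levels, sdv, D) {
    key <- paste(f, channel, sep = "@")
    if (!exists(key, store)) {
      counter <<- counter + 1L
      assign(key, list(seed = seeds[counter], vals = NULL), store)
    }
    entry <- get(key, store)
    with_seed(entry$seed, {
      matrix(rnorm(D * length(new_levels)), D) * sdv
    })
  })
}

#' Poststratify a fitted model to a population estimand
#'
#' For each posterior draw, predicts every cell of the poststratification
#' table and forms the count-weighted average, yielding posterior draws of
#' the population estimand.
#'
#' @param fit A `posterior_fit` from [fit_ordinal_mrp()] or
#'   [fit_categorical_mrp()].
#' @param table A `poststrat_table` (every factor in the fit's formula must
#'   be a column; levels unseen at fit time are predicted from the fitted
#'   group-effect distribution).
#' @param estimand `"category_prob"` (default: one column per response
#'   category), `"mean"` (expected ordinal response), or a named list of
#'   category index sets to collapse over, e.g.
#'   `list(oppose = 1:3, neutral = 4, support = 5:7)`.
#' @param level HDI mass for the summary.
#' @param chunk Draws processed per block (memory control).
#' @param seed Seed for unseen-level effect simulation.
#' @return A `population_estimate`: posterior draws (matrix, one column per
#'   reported quantity) plus a mean/HDI summary.
#' @export
poststratify <- function(fit, table, estimand = "category_prob",
                         level = 0.95, chunk = 250L, seed = 1) {
  if (!nrow(table)) stop_mrpsup("poststratify: empty table")
  if (any(table$count < 0)) stop_mrpsup("poststratify: negative counts")
  w <- table$count / sum(table$count)
  D <- n_draws(fit)
  cache <- make_unseen_cache(seed)
  K <- fit$K
  collapse <- NULL
  if (is.list(estimand)) {
    collapse <- estimand
    estimand <- "collapse"
  }
  ncol_out <- switch(estimand,
    mean = 1L,
    category_prob = K,
    collapse = length(collapse),
    stop_mrpsup("unknown estimand")
  )
  out <- matrix(NA_real_, D, ncol_out)
  colnames(out) <- switch(estimand,
    mean = "mean",
    category_prob = if (fit$family == "categorical_logit") fit$categories else paste0("cat", seq_len(K)),
    collapse = names(collapse)
  )
  starts <- seq(1L, D, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, D)
    pop <- pop_prob_chunk(fit, table, idx, cache, w) # draws x K categories
    out[idx, ] <- switch(estimand,
      mean = matrix(pop %*% seq_len(K), ncol = 1),
      category_prob = pop,
      collapse = vapply(collapse, function(ks) rowSums(pop[, ks, drop = FALSE]),
                        numeric(length(idx)))
    )
  }
  structure(
    list(draws = out, estimand = estimand, level = level,
         summary = summarize_posterior(out, level = level),
         item = fit$item, family = fit$family),
    class = "population_estimate"
  )
}

# Count-weighted population category probabilities for a chunk of draws:
# D x K matrix. For the ordinal family the weighted cumulative
# probabilities are aggregated before differencing, so only one
# draws x cells matrix is live at a time.
pop_prob_chunk <- function(fit, table, draw_idx, cache, w) {
  D <- length(draw_idx)
  if (fit$family == "ordinal_probit") {
    mu <- cell_eta_draws(fit, table, draw_idx, 1L, cache)
    cp <- fit$draws$cutpoints[draw_idx, , drop = FALSE]
    K <- fit$K
    pop <- matrix(NA_real_, D, K)
    prev <- 0
    for (k in seq_len(K - 1)) {
      v <- as.vector(pnorm(cp[, k] - mu) %*% w)
      pop[, k] <- v - prev
      prev <- v
    }
    pop[, K] <- 1 - prev
    pop
  } else {
    probs <- cell_prob_chunk(fit, table, draw_idx, cache)
    out <- vapply(probs, function(p) as.vector(p %*% w), numeric(D))
    matrix(out, nrow = D)
  }
}

# Category-probability draws for a chunk: list (length K) of D x cells.
cell_prob_chunk <- function(fit, table, draw_idx, cache) {
  if (fit$family == "ordinal_probit") {
    mu <- cell_eta_draws(fit, table, draw_idx, 1L, cache)
    cp <- fit$draws$cutpoints[draw_idx, , drop = FALSE]
    K <- fit$K
    probs <- vector("list", K)
    prev <- 0
    for (k in seq_len(K)) {
      cum <- if (k < K) pnorm(cp[, k] - mu) else 1
      probs[[k]] <- cum - prev
      prev <- cum
    }
    probs
  } else {
    C <- length(fit$categories)
    denom <- 1
    etas <- vector("list", C - 1L)
    for (cc in seq_len(C - 1L)) {
      etas[[cc]] <- exp(pmin(cell_eta_draws(fit, table, draw_idx, cc, cache), 500))
      denom <- denom + etas[[cc]]
    }
    c(list(1 / denom), lapply(etas, function(e) e / denom))
  }
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("<population_estimate: %s of '%s'>\n", x$estimand, x$item))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extend a poststratification table with party identification
#'
#' Splits each demographic cell into one cell per party, allocating
#' `count` proportionally to the posterior-mean party probabilities
#' predicted by a categorical fit (the synthetic analogue of extending a
#' census cross-tabulation with an election-study party model). Total
#' count is conserved.
#'
#' @param table Poststratification table without a `party` column.
#' @param party_fit A `posterior_fit` from [fit_categorical_mrp()] whose
#'   outcome is party identification and whose formula uses only factors
#'   present in `table`.
#' @return The extended `poststrat_table` with a `party` column.
#' @export
extend_table_with_party <- function(table, party_fit) {
  if ("party" %in% names(table)) stop_mrpsup("table already has a party column")
  needed <- unique(unlist(strsplit(c(party_fit$formula$fixed, party_fit$formula$varying),
                                   ":", fixed = TRUE)))
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_mrpsup("party fit uses factors absent from the table: ",
                paste(missing, collapse = ", "))
  }
  D <- n_draws(party_fit)
  cache <- make_unseen_cache(seed = 1L)
  parties <- party_fit$categories
  probs <- cell_prob_chunk(party_fit, table, seq_len(D), cache)
  mean_probs <- vapply(probs, colMeans, numeric(nrow(table)))
  mean_probs <- matrix(mean_probs, nrow = nrow(table))
  out <- table[rep(seq_len(nrow(table)), each = length(parties)), , drop = FALSE]
  out$party <- rep(parties, nrow(table))
  out$count <- as.vector(t(mean_probs * table$count))
  rownames(out) <- NULL
  class(out) <- c("poststrat_table", "data.frame")
  out
}
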