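#' Specify a synthetic population
#'
#' Defines the stratifiers of a census-style cross-tabulation: the
#' demographic level sets, a state-to-region map, a continuous state-level
#' covariate (a vaccine-hesitancy rate, later z-scored across states), the
#' total adult population size, and a multinomial-logit model generating
#' party identification from demographics.
#'
#' @param levels Named list of character vectors: level sets for `sex`,
#'   `age_band`, `education`, `income`, `race`, and `state`. Defaults mirror
#'   a five-band age, four-level education, six-level income, five-level
#'   race classification with binary sex.
#' @param state_region Named character vector mapping every state to its
#'   region.
#' @param state_covariate Named numeric vector: the raw hesitancy rate per
#'   state (z-scored across states when tables are built).
#' @param total_population Total population count spread over the cells.
#' @param party_model A [party_model()] object, or `NULL` for a single
#'   "All" party (no party stratification).
#' @param margins Optional named list of positive weights per level, one
#'   entry per stratifier; cell probabilities are the product of the
#'   normalized margins. Defaults to mildly unequal margins.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(levels = default_levels(),
                            state_region = default_state_region(levels$state),
                            state_covariate = default_state_covariate(levels$state),
                            total_population = 250000,
                            party_model = default_party_model(levels),
                            margins = NULL) {
  stopifnot(is.list(levels))
  need <- c("sex", "age_band", "education", "income", "race", "state")
  missing <- setdiff(need, names(levels))
  if (length(missing)) {
    stop_mrpsup("population_spec: missing level sets: ", paste(missing, collapse = ", "))
  }
  for (f in need) {
    if (!length(levels[[f]])) stop_mrpsup("population_spec: empty level set for ", f)
    if (anyDuplicated(levels[[f]])) stop_mrpsup("population_spec: duplicate levels in ", f)
  }
  if (!setequal(names(state_region), levels$state)) {
    stop_mrpsup("population_spec: every state must map to exactly one region")
  }
  if (!setequal(names(state_covariate), levels$state)) {
    stop_mrpsup("population_spec: state_covariate must cover every state")
  }
  total_population <- assert_scalar_count(total_population, "total_population")
  if (is.null(party_model)) {
    party_model <- party_model(parties = "All")
  }
  if (is.null(margins)) {
    margins <- lapply(levels[need], function(lv) {
      # mildly unequal, deterministic margins: heavier early levels
      w <- rev(seq_along(lv)) + 1
      w / sum(w)
    })
  } else {
    for (f in names(margins)) {
      if (length(margins[[f]]) != length(levels[[f]])) {
        stop_mrpsup("population_spec: margins for ", f, " have the wrong length")
      }
      if (any(margins[[f]] <= 0)) stop_mrpsup("population_spec: margins must be positive")
      margins[[f]] <- margins[[f]] / sum(margins[[f]])
    }
    missing_m <- setdiff(need, names(margins))
    margins[missing_m] <- lapply(levels[missing_m], function(lv) rep(1 / length(lv), length(lv)))
  }
  structure(
    list(
      levels = levels[need],
      state_region = state_region[levels$state],
      state_covariate = state_covariate[levels$state],
      total_population = total_population,
      party_model = party_model,
      margins = margins[need]
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  for (f in names(x$levels)) {
    cat(sprintf("  %-10s %d levels\n", f, length(x$levels[[f]])))
  }
  cat(sprintf("  regions    %d\n", length(unique(x$state_region))))
  cat(sprintf("  population %d, parties: %s\n", x$total_population,
              paste(x$party_model$parties, collapse = ", ")))
  invisible(x)
}

default_levels <- function(n_states = 8) {
  list(
    sex = c("Male", "Female"),
    age_band = c("18-24", "25-34", "35-44", "45-64", "65+"),
    education = c("HS or less", "Some college", "College grad", "Postgrad"),
    income = c("<20k", "20-50k", "50-80k", "80-100k", "100-150k", ">150k"),
    race = c("Asian", "Black", "Hispanic", "White", "Other"),
    state = sprintf("S%02d", seq_len(n_states))
  )
}

default_state_region <- function(states) {
  regions <- c("Northeast", "Midwest", "South", "West")
  setNames(regions[((seq_along(states) - 1L) %% 4L) + 1L], states)
}

default_state_covariate <- function(states) {
  # hesitancy rates spanning roughly the range seen across US states
  setNames(seq(0.08, 0.32, length.out = length(states)), states)
}

#' Multinomial-logit party-identification model
#'
#' Party probabilities for a demographic cell are
#' `softmax(intercept_p + sum_f effect[f][level_f, p])`.
#'
#' @param parties Character vector of party labels.
#' @param intercepts Numeric vector, one per party (default 0).
#' @param effects Named list: factor name -> numeric matrix
#'   (factor levels x parties) of log-odds deflections.
#' @return An object of class `party_model`.
#' @export
party_model <- function(parties = c("Democrat", "Independent", "Republican"),
                        intercepts = rep(0, length(parties)),
                        effects = list()) {
  stopifnot(is.character(parties), length(parties) >= 1)
  if (length(intercepts) != length(parties)) {
    stop_mrpsup("party_model: one intercept per party required")
  }
  for (f in names(effects)) {
    if (ncol(effects[[f]]) != length(parties)) {
      stop_mrpsup("party_model: effect matrix for ", f, " needs one column per party")
    }
  }
  structure(list(parties = parties, intercepts = intercepts, effects = effects),
            class = "party_model")
}

default_party_model <- function(levels) {
  parties <- c("Democrat", "Independent", "Republican")
  race_eff <- matrix(0, length(levels$race), 3,
                     dimnames = list(levels$race, parties))
  race_eff["Black", ] <- c(0.8, 0, -0.8)
  race_eff["White", ] <- c(-0.3, 0, 0.3)
  race_eff["Hispanic", ] <- c(0.3, 0.1, -0.4)
  edu_eff <- matrix(0, length(levels$education), 3,
                    dimnames = list(levels$education, parties))
  edu_eff[1, ] <- c(-0.2, 0, 0.2)
  edu_eff[length(levels$education), ] <- c(0.4, -0.1, -0.3)
  st_eff <- matrix(seq(-0.5, 0.5, length.out = length(levels$state)),
                   length(levels$state), 3)
  st_eff[, 1] <- -st_eff[, 3]
  st_eff[, 2] <- 0
  dimnames(st_eff) <- list(levels$state, parties)
  party_model(parties, intercepts = c(0.1, -0.2, 0.1),
              effects = list(race = race_eff, education = edu_eff, state = st_eff))
}

# Party probabilities for each row of a cell data frame.
party_probs <- function(pm, cells) {
  eta <- matrix(rep(pm$intercepts, each = nrow(cells)), nrow(cells))
  for (f in names(pm$effects)) {
    if (!f %in% names(cells)) stop_mrpsup("party model factor not in table: ", f)
    eta <- eta + pm$effects[[f]][cells[[f]], , drop = FALSE]
  }
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Ground-truth latent-variable model for ordinal responses
#'
#' Responses are generated from a cumulative probit model: a respondent's
#' latent value is the sum of their demographic effect values plus standard
#' normal noise (latent scale fixed at 1 for identification), and the
#' observed category is 1 plus the number of cutpoints below the latent
#' value.
#'
#' @param cutpoints Strictly increasing numeric vector of length K-1 for a
#'   K-point scale.
#' @param effects Named list: factor name -> named numeric vector of effect
#'   values, one per level. Interaction factors use names like
#'   `"sex:race"` with levels `"Male:White"`.
#' @param hesitancy_slope Coefficient on the z-scored state covariate.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(cutpoints, effects = list(), hesitancy_slope = 0) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || any(!is.finite(cutpoints))) {
    stop_mrpsup("truth_spec: cutpoints must be finite, length >= 1")
  }
  if (any(diff(cutpoints) <= 0)) {
    stop_mrpsup("truth_spec: cutpoints must be strictly increasing")
  }
  if (!is_scalar_number(hesitancy_slope)) {
    stop_mrpsup("truth_spec: hesitancy_slope must be a number")
  }
  for (f in names(effects)) {
    if (is.null(names(effects[[f]])) || any(!is.finite(effects[[f]]))) {
      stop_mrpsup("truth_spec: effects for ", f, " must be a named finite vector")
    }
  }
  structure(list(cutpoints = cutpoints, effects = effects,
                 hesitancy_slope = hesitancy_slope),
            class = "truth_spec")
}

#' Draw a random truth for parameter-recovery simulations
#'
#' Effect values are independent normals per factor level (including the
#' sex by race and education by age interactions), the hesitancy slope is
#' normal, and cutpoints are equal-mass probit quantiles jittered slightly.
#'
#' @param spec A [population_spec()].
#' @param K Scale size.
#' @param seed Integer seed.
#' @param effect_sd Standard deviation of the per-level effect values.
#' @param slope_sd Standard deviation of the hesitancy slope.
#' @return A [truth_spec()].
#' @export
random_truth_spec <- function(spec, K, seed, effect_sd = 0.3, slope_sd = 0.15) {
  K <- assert_scalar_count(K, "K")
  with_seed(seed, {
    lv <- spec$levels
    regions <- unique(unname(spec$state_region))
    fac_levels <- list(
      sex = lv$sex,
      region = regions,
      age_band = lv$age_band,
      education = lv$education,
      income = lv$income,
      race = lv$race,
      party = spec$party_model$parties,
      state = lv$state,
      "sex:race" = as.vector(outer(lv$sex, lv$race, paste, sep = ":")),
      "education:age_band" = as.vector(outer(lv$education, lv$age_band, paste, sep = ":"))
    )
    effects <- lapply(fac_levels, function(l) setNames(rnorm(length(l), 0, effect_sd), l))
    base <- qnorm(seq_len(K - 1) / K)
    cp <- sort(base + rnorm(K - 1, 0, 0.05))
    while (any(diff(cp) <= 1e-3)) cp <- sort(base + rnorm(K - 1, 0, 0.05))
    truth_spec(cutpoints = cp, effects = effects,
               hesitancy_slope = rnorm(1, 0, slope_sd))
  })
}

#' Selection-bias specification for respondent sampling
#'
#' Log-odds of inclusion added per demographic level; levels not named
#' default to 0, so an empty spec gives representative sampling.
#'
#' @param ... Named arguments, one per factor, each a named numeric vector
#'   of log-odds per level, e.g. `sex = c(Female = 0.6)`.
#' @return An object of class `selection_bias_spec`.
#' @export
selection_bias_spec <- function(...) {
  bias <- list(...)
  if (length(bias) == 1L && is.null(names(bias)) && is.list(bias[[1]])) {
    bias <- bias[[1]]
  }
  for (f in names(bias)) {
    if (any(!is.finite(bias[[f]])) || is.null(names(bias[[f]]))) {
      stop_mrpsup("selection_bias_spec: ", f, " must be a named vector of finite log-odds")
    }
  }
  structure(bias, class = "selection_bias_spec")
}

# Latent linear predictor (without noise) for each row of a demographic
# data frame, under a truth_spec.
truth_eta <- function(df, truth) {
  eta <- rep(0, nrow(df))
  for (f in names(truth$effects)) {
    vals <- truth$effects[[f]]
    key <- if (grepl(":", f, fixed = TRUE)) {
      parts <- strsplit(f, ":", fixed = TRUE)[[1]]
      do.call(paste, c(lapply(parts, function(p) df[[p]]), sep = ":"))
    } else {
      df[[f]]
    }
    idx <- match(key, names(vals))
    if (anyNA(idx)) {
      stop_mrpsup("truth_spec effects for '", f, "' are missing levels: ",
                  paste(unique(key[is.na(idx)]), collapse = ", "))
    }
    eta <- eta + unname(vals[idx])
  }
  if (truth$hesitancy_slope != 0) {
    eta <- eta + truth$hesitancy_slope * df$state_hesitancy_z
  }
  eta
}

#' Build a poststratification table from a population spec
#'
#' Enumerates every demographic cell, spreads `total_population` over the
#' cells by a multinomial draw with product-of-margins probabilities, and
#' splits each cell by party with a multinomial draw from the party model.
#' Region and the z-scored state covariate are attached per state.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A data frame of class `poststrat_table` with one row per
#'   demographic cell (including party) and a `count` column summing to
#'   `total_population`.
#' @export
build_poststrat_table <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  seed <- assert_scalar_count(seed, "seed")
  lv <- spec$levels
  cells <- expand.grid(
    sex = lv$sex, age_band = lv$age_band, education = lv$education,
    income = lv$income, race = lv$race, state = lv$state,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  prob <- rep(1, nrow(cells))
  for (f in names(spec$margins)) {
    prob <- prob * spec$margins[[f]][match(cells[[f]], lv[[f]])]
  }
  prob <- prob / sum(prob)
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, spec$total_population, prob))
    pm <- spec$party_model
    nparty <- length(pm$parties)
    if (nparty == 1L) {
      party_counts <- matrix(counts, ncol = 1)
    } else {
      pp <- party_probs(pm, cells)
      if (any(abs(rowSums(pp) - 1) > 1e-9)) {
        stop_mrpsup("party probabilities do not sum to 1")
      }
      party_counts <- t(vapply(
        seq_len(nrow(cells)),
        function(i) {
          if (counts[i] == 0L) return(integer(nparty))
          as.integer(rmultinom(1, counts[i], pp[i, ]))
        },
        integer(nparty)
      ))
    }
    out <- cells[rep(seq_len(nrow(cells)), each = nparty), , drop = FALSE]
    out$party <- rep(pm$parties, nrow(cells))
    out$count <- as.vector(t(party_counts))
    out$region <- unname(spec$state_region[out$state])
    hz <- if (length(unique(spec$state_covariate)) < 2) {
      setNames(rep(0, length(spec$state_covariate)), names(spec$state_covariate))
    } else {
      zscore_state_covariate(spec$state_covariate)
    }
    out$state_hesitancy_z <- unname(hz[out$state])
    rownames(out) <- NULL
    out <- out[, c("sex", "age_band", "education", "income", "race", "state",
                   "region", "state_hesitancy_z", "party", "count")]
    structure(out, class = c("poststrat_table", "data.frame"),
              levels = lv, parties = pm$parties)
  })
}

#' Draw a selection-biased respondent roster from a poststratification table
#'
#' Respondents are sampled with replacement from the table's cells with
#' probability proportional to `count * exp(bias score)`, where the bias
#' score sums the log-odds of the cell's levels in `bias`.
#'
#' @param table A `poststrat_table`.
#' @param n Number of respondents.
#' @param bias A [selection_bias_spec()]; the default (no bias) samples
#'   representatively.
#' @param seed Integer seed.
#' @return A data frame roster with `respondent_id` plus the table's
#'   demographic columns.
#' @export
sample_respondents <- function(table, n, bias = selection_bias_spec(), seed = 1) {
  if (!nrow(table)) stop_mrpsup("sample_respondents: empty poststratification table")
  n <- assert_scalar_count(n, "n")
  score <- rep(0, nrow(table))
  for (f in names(bias)) {
    if (!f %in% names(table)) stop_mrpsup("bias factor not in table: ", f)
    b <- bias[[f]]
    idx <- match(table[[f]], names(b))
    score <- score + ifelse(is.na(idx), 0, b[idx])
  }
  w <- table$count * exp(score - max(score))
  if (all(w == 0)) stop_mrpsup("sample_respondents: all cell weights are zero")
  with_seed(seed, {
    pick <- sample.int(nrow(table), n, replace = TRUE, prob = w)
    out <- table[pick, setdiff(names(table), "count"), drop = FALSE]
    out <- cbind(respondent_id = sprintf("R%05d", seq_len(n)), out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate ordinal Likert responses under a ground-truth model
#'
#' @param roster Respondent roster from [sample_respondents()].
#' @param truth A [truth_spec()] with cutpoints of length `K - 1`.
#' @param K Scale size (K >= 2).
#' @param seed Integer seed.
#' @param item Column name for the simulated responses.
#' @return The roster with an added integer response column in `1..K`.
#' @export
simulate_ordinal_responses <- function(roster, truth, K, seed = 1, item = "response") {
  stopifnot(inherits(truth, "truth_spec"))
  K <- assert_scalar_count(K, "K")
  if (K < 2) stop_mrpsup("K must be >= 2")
  if (length(truth$cutpoints) != K - 1) {
    stop_mrpsup("truth cutpoints must have length K - 1")
  }
  eta <- truth_eta(roster, truth)
  with_seed(seed, {
    latent <- eta + rnorm(nrow(roster))
    r <- rep(1L, nrow(roster))
    for (cp in truth$cutpoints) r <- r + (latent > cp)
    roster[[item]] <- as.integer(r)
    roster
  })
}

# Closed-form per-cell category probabilities under a truth_spec.
cell_category_probs <- function(table, truth, K) {
  eta <- truth_eta(table, truth)
  cum <- vapply(truth$cutpoints, function(cp) pnorm(cp - eta), numeric(nrow(table)))
  cum <- matrix(cum, nrow = nrow(table))
  cbind(cum, 1)[, seq_len(K), drop = FALSE] -
    cbind(0, cum)[, seq_len(K), drop = FALSE]
}

#' Exact population value of an estimand under a synthetic truth
#'
#' Enumerates the cells of a poststratification table and integrates the
#' probit response model in closed form, weighting by cell counts. Serves
#' as the brute-force oracle for parameter-recovery tests.
#'
#' @param table A `poststrat_table`.
#' @param truth A [truth_spec()] for the (first) item.
#' @param estimand `"mean"` (expected response), `"category_prob"`
#'   (vector of K category probabilities), or `"psup"` (paired
#'   probability of superiority of the `truth` item over `truth_b`,
#'   with independent latent noise and half-weighted ties).
#' @param K Scale size.
#' @param truth_b Second item's [truth_spec()] (for `estimand = "psup"`).
#' @return A number, or a length-K vector for `"category_prob"`.
#' @export
true_population_value <- function(table, truth, estimand = c("mean", "category_prob", "psup"),
                                  K, truth_b = NULL) {
  estimand <- match.arg(estimand)
  K <- assert_scalar_count(K, "K")
  w <- table$count / sum(table$count)
  pa <- cell_category_probs(table, truth, K)
  if (estimand == "mean") {
    return(sum(w * (pa %*% seq_len(K))))
  }
  if (estimand == "category_prob") {
    return(setNames(as.vector(w %*% pa), paste0("cat", seq_len(K))))
  }
  if (is.null(truth_b)) stop_mrpsup("estimand 'psup' needs truth_b")
  pb <- cell_category_probs(table, truth_b, K)
  S <- matrix(0, K, K)
  S[lower.tri(S)] <- 1 # row index = category of item A, col = item B; A > B below diagonal
  diag(S) <- 0.5
  sum(w * rowSums((pa %*% S) * pb))
}

#' Simulate a complete synthetic survey
#'
#' Convenience wrapper: draws a roster and simulates one response column
#' per item, adding a comprehension-pass flag (all `TRUE`; exclusions are
#' exercised separately).
#'
#' @param table A `poststrat_table`.
#' @param n Number of respondents.
#' @param truths Named list: item name -> [truth_spec()].
#' @param K Named integer vector or single integer: scale size per item.
#' @param bias A [selection_bias_spec()].
#' @param seed Integer seed.
#' @return A survey data frame with one response column per item.
#' @export
simulate_survey <- function(table, n, truths, K, bias = selection_bias_spec(), seed = 1) {
  if (length(K) == 1L && is.null(names(K))) K <- setNames(rep(K, length(truths)), names(truths))
  seeds <- child_seeds(seed, length(truths) + 1L)
  roster <- sample_respondents(table, n, bias, seed = seeds[1])
  for (i in seq_along(truths)) {
    item <- names(truths)[i]
    roster <- simulate_ordinal_responses(roster, truths[[item]], K = K[[item]],
                                         seed = seeds[i + 1L], item = item)
  }
  roster$comprehension_pass <- TRUE
  roster
}
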