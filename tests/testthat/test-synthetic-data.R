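# Synthetic population, selection-biased sampling, and the ordinal
# response generator with its closed-form oracle.

test_that("degenerate one-level spec yields a single cell holding everyone", {
  lv <- list(sex = "Male", age_band = "18-24", education = "HS or less",
             income = "<20k", race = "White", state = "S01")
  spec <- population_spec(
    levels = lv,
    state_region = c(S01 = "South"),
    state_covariate = c(S01 = 0.2),
    total_population = 1000,
    party_model = party_model(parties = "All")
  )
  tab <- build_poststrat_table(spec, seed = 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$count, 1000)
  expect_equal(tab$state_hesitancy_z, 0)
})

test_that("cell counts always conserve the total population", {
  for (seed in 1:3) {
    spec <- population_spec(levels = default_levels(3 + seed),
                            total_population = 10000 * seed)
    tab <- build_poststrat_table(spec, seed = seed)
    expect_equal(sum(tab$count), spec$total_population)
  }
  expect_error(population_spec(total_population = 0), "positive integer")
})

test_that("uniform two-party model splits cells within binomial 99% bounds", {
  lv <- default_levels(2)
  pm <- party_model(parties = c("P1", "P2"))
  spec <- population_spec(levels = lv, total_population = 400000,
                          party_model = pm)
  tab <- build_poststrat_table(spec, seed = 42)
  big <- tab[tab$party == "P1" & tab$count + 0 > 0, ]
  # pool across cells: overall P1 share must sit inside binomial bounds
  n_tot <- sum(tab$count)
  share <- sum(tab$count[tab$party == "P1"]) / n_tot
  bounds <- binom_bounds99(0.5, n_tot)
  expect_gte(share, bounds[1])
  expect_lte(share, bounds[2])
  # and per-cell for the 20 largest base cells
  base <- aggregate(count ~ sex + age_band + education + income + race + state,
                    data = as.data.frame(tab), FUN = sum)
  base <- base[order(-base$count), ][1:20, ]
  for (i in seq_len(20)) {
    sel <- tab$sex == base$sex[i] & tab$age_band == base$age_band[i] &
      tab$education == base$education[i] & tab$income == base$income[i] &
      tab$race == base$race[i] & tab$state == base$state[i]
    cnt <- tab$count[sel & tab$party == "P1"]
    b <- binom_bounds99(0.5, base$count[i]) * base$count[i]
    expect_gte(cnt, b[1])
    expect_lte(cnt, b[2])
  }
})

test_that("unbiased sampling reproduces population shares; bias limit dominates", {
  spec <- small_spec(total = 100000)
  tab <- build_poststrat_table(spec, seed = 3)
  roster <- sample_respondents(tab, 20000, seed = 9)
  # education margin within multinomial 99% bounds of population shares
  pop_share <- tapply(tab$count, tab$education, sum) / sum(tab$count)
  for (lev in names(pop_share)) {
    obs <- mean(roster$education == lev)
    b <- binom_bounds99(pop_share[[lev]], 20000)
    expect_gte(obs, b[1])
    expect_lte(obs, b[2])
  }
  # a huge log-odds on one level swamps everything else
  biased <- sample_respondents(tab, 500,
                               selection_bias_spec(race = c(Black = 50)),
                               seed = 4)
  expect_true(all(biased$race == "Black"))
  # same seed, same roster
  r1 <- sample_respondents(tab, 250, seed = 11)
  r2 <- sample_respondents(tab, 250, seed = 11)
  expect_identical(r1, r2)
  empty <- tab[0, ]
  expect_error(sample_respondents(empty, 10), "empty")
})

test_that("null ordinal generator matches probit closed form and saturates", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 10000, seed = 6)
  truth <- truth_spec(cutpoints = qnorm(c(0.2, 0.5, 0.8)))
  sv <- simulate_ordinal_responses(roster, truth, K = 4, seed = 7, item = "y")
  expect_true(all(sv$y %in% 1:4))
  target <- c(0.2, 0.3, 0.3, 0.2)
  for (k in 1:4) {
    b <- binom_bounds99(target[k], 10000)
    expect_gte(mean(sv$y == k), b[1])
    expect_lte(mean(sv$y == k), b[2])
  }
  # saturated thresholds force the middle category
  sat <- simulate_ordinal_responses(roster, truth_spec(cutpoints = c(-10, 10)),
                                    K = 3, seed = 8, item = "y")
  expect_true(all(sat$y == 2L))
  # non-increasing cutpoints are rejected
  expect_error(truth_spec(cutpoints = c(0.5, 0.5)), "strictly increasing")
})

test_that("mean response is monotone in a common latent shift", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 10000, seed = 16)
  means <- vapply(seq(-1, 1, by = 0.5), function(delta) {
    tr <- truth_spec(cutpoints = qnorm(c(0.25, 0.5, 0.75)),
                     effects = list(sex = c(Male = delta, Female = delta)))
    mean(simulate_ordinal_responses(roster, tr, K = 4, seed = 17, item = "y")$y)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("closed-form population values match direct computation and simulation", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  # all effects zero: category probabilities are exactly the probit increments
  truth0 <- truth_spec(cutpoints = qnorm(c(0.2, 0.5, 0.8)))
  expect_equal(unname(true_population_value(tab, truth0, "category_prob", K = 4)),
               c(0.2, 0.3, 0.3, 0.2), tolerance = 1e-12)
  # single-cell table equals that cell's closed form
  one <- tab[which.max(tab$count), , drop = FALSE]
  tr <- random_truth_spec(spec, K = 4, seed = 30)
  eta <- mrpsup:::truth_eta(one, tr)
  probs <- diff(c(0, pnorm(tr$cutpoints - eta), 1))
  expect_equal(unname(true_population_value(one, tr, "category_prob", K = 4)),
               probs, tolerance = 1e-12)
  # Monte-Carlo agreement at n = 1e6, within 3 simulation standard errors
  n <- 1e6
  roster <- sample_respondents(tab, n, seed = 31)
  sv <- simulate_ordinal_responses(roster, tr, K = 4, seed = 32, item = "y")
  mc_mean <- mean(sv$y)
  mc_se <- sd(sv$y) / sqrt(n)
  expect_lt(abs(mc_mean - true_population_value(tab, tr, "mean", K = 4)),
            3 * mc_se)
  # paired PSup against an independent second item
  trb <- random_truth_spec(spec, K = 4, seed = 33)
  svb <- simulate_ordinal_responses(sv, trb, K = 4, seed = 34, item = "yb")
  ps <- oracle_psup(svb$y, svb$yb)
  se <- sqrt(0.25 / n) # PSup contributions bounded in [0,1]
  expect_lt(abs(ps - true_population_value(tab, tr, "psup", K = 4, truth_b = trb)),
            3 * se)
})

test_that("table and response generation are deterministic given the seed", {
  spec <- small_spec()
  t1 <- build_poststrat_table(spec, seed = 77)
  t2 <- build_poststrat_table(spec, seed = 77)
  expect_identical(t1, t2)
  tr <- random_truth_spec(spec, K = 5, seed = 1)
  r <- sample_respondents(t1, 100, seed = 2)
  s1 <- simulate_ordinal_responses(r, tr, K = 5, seed = 3, item = "y")
  s2 <- simulate_ordinal_responses(r, tr, K = 5, seed = 3, item = "y")
  expect_identical(s1, s2)
  # and the generator does not disturb the caller's RNG stream
  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(build_poststrat_table(spec, seed = 5)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})
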