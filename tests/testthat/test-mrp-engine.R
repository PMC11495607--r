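# Ordinal-probit and categorical-logit MRP fits, poststratification,
# and the party-extension step. Fits here run at reduced sizes; the
# acceptance suite carries the full recovery sweep.

# A hand-built ordinal fit whose two cells deterministically predict mean
# responses 1 and 2, for checking the poststratification weighting alone.
fake_two_cell_fit <- function(D = 200) {
  structure(list(
    family = "ordinal_probit", item = "y", K = 3, n = 2,
    draws = list(
      beta = matrix(numeric(0), D, 0),
      cutpoints = matrix(rep(c(0, 40), each = D), D,
                         dimnames = list(NULL, c("cut1", "cut2"))),
      sd = matrix(1, D, 1, dimnames = list(NULL, "cell")),
      u = list(cell = matrix(rep(c(-20, 20), each = D), D,
                             dimnames = list(NULL, c("c1", "c2"))))
    ),
    fixed_terms = list(), fixed_columns = character(0),
    group_levels = list(cell = c("c1", "c2")),
    formula = formula_spec(fixed = character(0), varying = "cell"),
    priors = prior_spec(), seed = 1, chains = 1, iter_per_chain = D,
    diagnostics = list(rhat = 1, ess = D, rhat_max = 1, ess_min = D)
  ), class = "posterior_fit")
}

test_that("poststratification is the count-weighted mean of cell predictions", {
  fit <- fake_two_cell_fit()
  tab <- data.frame(cell = c("c1", "c2"), count = c(100, 300))
  est <- poststratify(fit, tab, estimand = "mean")
  expect_equal(unique(as.vector(round(est$draws, 10))), 1.75)
  uni <- poststratify(fit, data.frame(cell = c("c1", "c2"), count = c(7, 7)),
                      estimand = "mean")
  expect_equal(unique(as.vector(round(uni$draws, 10))), 1.5)
  expect_error(poststratify(fit, tab[0, ]), "empty")
})

test_that("null-data ordinal fit recovers closed-form category probabilities", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 800, seed = 6)
  truth <- truth_spec(cutpoints = qnorm(c(0.2, 0.5, 0.8)))
  sv <- simulate_ordinal_responses(roster, truth, K = 4, seed = 7, item = "y")
  fit <- fit_ordinal_mrp(sv, "y", formula = small_formula(), K = 4,
                         chains = 2, iter = 300, warmup = 300, seed = 8,
                         check_convergence = FALSE)
  est <- poststratify(fit, tab, estimand = "category_prob", seed = 9)
  target <- true_population_value(tab, truth, "category_prob", K = 4)
  for (k in 1:4) {
    expect_gte(target[[k]], est$summary$hdi_lower[k] - 0.01)
    expect_lte(target[[k]], est$summary$hdi_upper[k] + 0.01)
  }
  # category-probability draws are a simplex per draw
  expect_true(all(est$draws >= 0 & est$draws <= 1))
  expect_lt(max(abs(rowSums(est$draws) - 1)), 1e-9)
  # a table matching the sample's own composition reproduces the
  # sample-level mean response
  comp <- aggregate(count ~ sex + age_band + education + income + race +
                      state + region + state_hesitancy_z,
                    data = cbind(as.data.frame(roster), count = 1), FUN = sum)
  own <- poststratify(fit, comp, estimand = "mean", seed = 10)
  expect_lt(abs(own$summary$mean - mean(sv$y)), 0.1)
})

test_that("degenerate one-category data concentrates mass on that category", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 500, seed = 16)
  roster$y <- 3L
  fit <- fit_ordinal_mrp(roster, "y", formula = small_formula(), K = 3,
                         chains = 2, iter = 250, warmup = 250, seed = 17,
                         check_convergence = FALSE)
  est <- poststratify(fit, tab, estimand = "category_prob", seed = 18)
  expect_gt(est$summary$mean[3], 0.9)
})

test_that("fits fail loudly on single-level factors and non-convergence", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 200, seed = 20)
  roster$y <- sample.int(3, 200, replace = TRUE)
  one_sex <- roster
  one_sex$sex <- "Male"
  expect_error(
    fit_ordinal_mrp(one_sex, "y", formula = small_formula(), K = 3,
                    chains = 2, iter = 50, warmup = 50, seed = 1),
    "single observed level"
  )
  expect_error(
    fit_ordinal_mrp(roster, "y", formula = small_formula(), K = 3,
                    chains = 2, iter = 25, warmup = 5, seed = 1,
                    rhat_max = 1.001),
    "converge"
  )
})

test_that("fits are deterministic given the seed", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 200, seed = 21)
  truth <- truth_spec(cutpoints = c(-0.5, 0.5))
  sv <- simulate_ordinal_responses(roster, truth, K = 3, seed = 22, item = "y")
  f1 <- fit_ordinal_mrp(sv, "y", formula = small_formula(), K = 3,
                        chains = 2, iter = 60, warmup = 60, seed = 23,
                        check_convergence = FALSE)
  f2 <- fit_ordinal_mrp(sv, "y", formula = small_formula(), K = 3,
                        chains = 2, iter = 60, warmup = 60, seed = 23,
                        check_convergence = FALSE)
  expect_identical(f1$draws, f2$draws)
})

test_that("balanced categorical null recovers the uniform simplex", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 600, seed = 26)
  set.seed(27)
  roster$choice <- sample(c("a", "b", "c"), 600, replace = TRUE)
  fit <- fit_categorical_mrp(roster, "choice", formula = small_formula(),
                             chains = 2, iter = 250, warmup = 250, seed = 28,
                             check_convergence = FALSE)
  est <- poststratify(fit, tab, estimand = "category_prob", seed = 29)
  expect_lt(max(abs(rowSums(est$draws) - 1)), 1e-9)
  for (k in 1:3) {
    expect_gte(1 / 3, est$summary$hdi_lower[k] - 0.02)
    expect_lte(1 / 3, est$summary$hdi_upper[k] + 0.02)
  }
})

test_that("categorical fit recovers known party-style composition", {
  lv <- default_levels(4)
  pm <- default_party_model(lv)
  spec <- population_spec(levels = lv, total_population = 80000,
                          party_model = party_model(parties = "All"))
  tab <- build_poststrat_table(spec, seed = 31)
  roster <- sample_respondents(tab, 1500, seed = 32)
  probs <- mrpsup:::party_probs(pm, roster)
  set.seed(33)
  roster$pid <- pm$parties[max.col(log(probs) - log(-log(matrix(
    runif(nrow(roster) * 3), ncol = 3))))] # Gumbel-max draw per row
  fit <- fit_categorical_mrp(roster, "pid", formula = small_formula(),
                             categories = pm$parties,
                             chains = 2, iter = 300, warmup = 300, seed = 34,
                             check_convergence = FALSE)
  est <- poststratify(fit, tab, estimand = "category_prob", seed = 35)
  truth <- colSums(mrpsup:::party_probs(pm, tab) * tab$count) / sum(tab$count)
  expect_lt(max(abs(est$summary$mean - truth)), 0.05)
})

test_that("psup_mrp on exchangeable items reduces to the sample estimate", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 600, seed = 41)
  truth <- truth_spec(cutpoints = qnorm(c(0.25, 0.5, 0.75)))
  sv <- simulate_ordinal_responses(roster, truth, K = 4, seed = 42, item = "a")
  sv <- simulate_ordinal_responses(sv, truth, K = 4, seed = 43, item = "b")
  ps <- psup_mrp(sv, "a", "b", table = tab, formula = small_formula(),
                 scale = 4, chains = 2, iter = 250, warmup = 250, seed = 44,
                 check_convergence = FALSE)
  expect_gt(ps$mean, 0.45)
  expect_lt(ps$mean, 0.55)
  expect_true(ps$hdi_lower <= 0.5 && ps$hdi_upper >= 0.5)
  point <- psup_point(sv$a, sv$b)$point
  expect_lt(abs(ps$mean - point), 0.04)
  expect_true(all(ps$draws >= 0 & ps$draws <= 1))
})

test_that("party extension splits cells proportionally and conserves totals", {
  D <- 150
  parties <- c("D", "I", "R")
  p_target <- c(0.5, 0.3, 0.2)
  b2 <- log(p_target[2] / p_target[1])
  b3 <- log(p_target[3] / p_target[1])
  fake_party_fit <- structure(list(
    family = "categorical_logit", item = "pid", K = 3, n = 10,
    categories = parties,
    draws = list(
      beta = matrix(rep(c(b2, b3), each = D), D,
                    dimnames = list(NULL, c("(Intercept)|I", "(Intercept)|R"))),
      sd = matrix(0.2, D, 2, dimnames = list(NULL, c("sex|I", "sex|R"))),
      u = list(sex = matrix(0, D, 4,
                            dimnames = list(NULL, c("Female|I", "Male|I",
                                                    "Female|R", "Male|R"))))
    ),
    fixed_terms = list(), fixed_columns = character(0),
    group_levels = list(sex = c("Female", "Male")),
    formula = formula_spec(fixed = character(0), varying = "sex"),
    priors = prior_spec(), seed = 1, chains = 1, iter_per_chain = D,
    diagnostics = list(rhat = 1, ess = D, rhat_max = 1, ess_min = D)
  ), class = "posterior_fit")

  tab <- data.frame(sex = c("Male", "Female"), count = c(100, 60))
  ext <- extend_table_with_party(tab, fake_party_fit)
  expect_equal(nrow(ext), 6L)
  expect_equal(ext$count[ext$sex == "Male"], c(50, 30, 20))
  expect_lt(abs(sum(ext$count) - 160) / 160, 1e-6)
  expect_error(extend_table_with_party(ext, fake_party_fit), "already has")
  expect_error(extend_table_with_party(data.frame(age = "x", count = 1),
                                       fake_party_fit), "absent")
})

test_that("levels unseen at fit time are predicted from the effect distribution", {
  # 8 states, two per region: dropping S08 leaves its region observed
  # through S04, so only the state-level effect must be imputed
  spec <- population_spec(levels = default_levels(8),
                          total_population = 60000,
                          party_model = party_model(parties = "All"))
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 400, seed = 51)
  truth <- truth_spec(cutpoints = c(-0.5, 0.5))
  sv <- simulate_ordinal_responses(roster, truth, K = 3, seed = 52, item = "y")
  sv <- sv[sv$state != "S08", , drop = FALSE]
  fit <- fit_ordinal_mrp(sv, "y", formula = small_formula(), K = 3,
                         chains = 2, iter = 150, warmup = 150, seed = 53,
                         check_convergence = FALSE)
  expect_false("S08" %in% fit$group_levels$state)
  est <- poststratify(fit, tab, estimand = "mean", seed = 54)
  expect_true(all(is.finite(est$draws)))
  expect_true(est$summary$mean > 1 && est$summary$mean < 3)
})

test_that("a common upward latent shift moves the poststratified mass upward", {
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 500, seed = 61)
  base <- truth_spec(cutpoints = qnorm(c(0.3, 0.6, 0.85)))
  up <- truth_spec(cutpoints = qnorm(c(0.3, 0.6, 0.85)),
                   effects = list(sex = c(Male = 0.5, Female = 0.5)))
  means <- vapply(list(base, up), function(tr) {
    sv <- simulate_ordinal_responses(roster, tr, K = 4, seed = 62, item = "y")
    fit <- fit_ordinal_mrp(sv, "y", formula = small_formula(), K = 4,
                           chains = 2, iter = 150, warmup = 150, seed = 63,
                           check_convergence = FALSE)
    poststratify(fit, tab, estimand = "mean", seed = 64)$summary$mean
  }, 0)
  expect_gt(means[2], means[1])
})

test_that("the Gibbs sampler agrees with an independent MCMC implementation", {
  # tiny hierarchical cumulative probit fitted both by this package and by
  # JAGS with identical priors; posterior means must agree to Monte-Carlo
  # accuracy
  library(rjags)
  spec <- small_spec()
  tab <- build_poststrat_table(spec, seed = 5)
  roster <- sample_respondents(tab, 100, seed = 71)
  truth <- truth_spec(cutpoints = c(-0.6, 0.7),
                      effects = list(sex = c(Male = 0, Female = 0.5),
                                     age_band = setNames(c(-0.3, 0, 0.1, 0.2, 0.4),
                                                         spec$levels$age_band)))
  sv <- simulate_ordinal_responses(roster, truth, K = 3, seed = 72, item = "y")
  fml <- formula_spec(fixed = "sex", varying = "age_band")
  fit <- fit_ordinal_mrp(sv, "y", formula = fml, K = 3,
                         chains = 2, iter = 1500, warmup = 500, seed = 73,
                         check_convergence = FALSE)

  jm_code <- "model {
    for (i in 1:N) {
      mu[i] <- b * x[i] + u[g[i]]
      q1[i] <- phi(cp[1] - mu[i]); q2[i] <- phi(cp[2] - mu[i])
      p[i,1] <- q1[i]; p[i,2] <- q2[i] - q1[i]; p[i,3] <- 1 - q2[i]
      y[i] ~ dcat(p[i,1:3])
    }
    b ~ dnorm(0, 0.25)
    for (j in 1:L) { u[j] ~ dnorm(0, tau) }
    sdu ~ dnorm(0, 1) T(0,)
    tau <- pow(sdu, -2)
    cr[1] ~ dnorm(0, 0.0625); cr[2] ~ dnorm(0, 0.0625)
    cp <- sort(cr)
  }"
  dat <- list(N = nrow(sv), x = as.numeric(sv$sex == "Male"),
              g = match(sv$age_band, spec$levels$age_band),
              L = 5, y = sv$y)
  jm <- jags.model(textConnection(jm_code), data = dat, n.chains = 2,
                   n.adapt = 300, quiet = TRUE,
                   inits = function() list(cr = c(-0.5, 0.5), b = 0))
  update(jm, 300, progress.bar = "none")
  sam <- coda.samples(jm, c("b", "cp", "sdu", "u"), n.iter = 1500,
                      progress.bar = "none")
  jags_mean <- colMeans(as.matrix(sam))

  expect_lt(abs(mean(fit$draws$beta[, "sex=Male"]) - jags_mean[["b"]]), 0.1)
  expect_lt(abs(mean(fit$draws$cutpoints[, 1]) - jags_mean[["cp[1]"]]), 0.1)
  expect_lt(abs(mean(fit$draws$cutpoints[, 2]) - jags_mean[["cp[2]"]]), 0.1)
  expect_lt(abs(mean(fit$draws$sd[, "age_band"]) - jags_mean[["sdu"]]), 0.12)
  for (j in 1:5) {
    expect_lt(abs(mean(fit$draws$u$age_band[, j]) -
                    jags_mean[[sprintf("u[%d]", j)]]), 0.12)
  }
})
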