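# End-to-end orchestration: synthetic data -> exclusions -> MRP fits ->
# poststratified summaries -> PSup comparisons -> ROPE / permutation
# decisions, from a single YAML (or list) configuration.

#' Load and normalize a pipeline configuration
#'
#' @param config Path to a YAML file, or a list with the same structure.
#'   Top-level keys (all optional except `seed`): `population`
#'   (`states`, `total`), `public` (`n`, `items` as name->K map,
#'   `effect_sd`, `bias`), `personnel` (`n`), `psup_pairs` (list of
#'   2-item lists), `sampler` (`chains`, `iter`, `warmup`, `rhat_max`),
#'   `rope` (`lower`, `upper`, `thresholds`), `permutation`
#'   (`permutations`, `budget`), `seed`.
#' @return Normalized config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1,
    population = list(states = 8, total = 100000),
    public = list(n = 800, items = list(support_treatments = 7, support_vaccines = 7),
                  effect_sd = 0.25, bias = list(education = list(Postgrad = 0.8))),
    personnel = list(n = 21),
    psup_pairs = list(list("support_treatments", "support_vaccines")),
    sampler = list(chains = 2, iter = 400, warmup = 400, rhat_max = 1.05),
    rope = list(lower = 0.47, upper = 0.53, thresholds = c(0.53, 0.60, 0.67, 0.75)),
    permutation = list(permutations = 1000, budget = 0.05)
  )
  out <- utils::modifyList(defaults, config)
  # modifyList merges by name, which silently keeps defaults inside
  # unnamed or wholesale-replaced structures; take these verbatim
  if (!is.null(config$psup_pairs)) out$psup_pairs <- config$psup_pairs
  if (!is.null(config$public$items)) out$public$items <- config$public$items
  if (!is.null(config$public$bias)) out$public$bias <- config$public$bias
  out$seed <- assert_scalar_count(out$seed, "seed")
  if (!length(out$public$items)) stop_mrpsup("run_config: no public items declared")
  for (p in out$psup_pairs) {
    if (length(p) != 2 || !all(unlist(p) %in% names(out$public$items))) {
      stop_mrpsup("run_config: psup_pairs must name two declared items")
    }
  }
  structure(out, class = "run_config")
}

#' Run the full synthetic-survey analysis pipeline
#'
#' Generates the population and survey, applies exclusions, fits one
#' cumulative-probit MRP model per item, poststratifies support
#' distributions, estimates pairwise population PSup with ROPE decisions,
#' analyses a small fixed "personnel" sample with randomization tests
#' under the cumulative c-value budget, compares the population posterior
#' against that fixed sample, and writes tidy CSV tables plus a JSON run
#' manifest. Deterministic given the config seed.
#'
#' @param config A [run_config()], YAML path, or config list.
#' @param output_dir Directory for result tables; `NULL` skips writing.
#' @return (Invisibly) a list with all result tables, fits, and manifest.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  seeds <- child_seeds(config$seed, 10)
  items <- names(config$public$items)
  Ks <- vapply(config$public$items, function(x) as.integer(x), 0L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mrpsup(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  spec <- stage("population", population_spec(
    levels = default_levels(config$population$states),
    total_population = config$population$total
  ))
  table <- stage("poststrat_table", build_poststrat_table(spec, seed = seeds[1]))
  truths <- stage("truths", {
    ts <- lapply(seq_along(items), function(i) {
      random_truth_spec(spec, K = Ks[i], seed = seeds[2] + i,
                        effect_sd = config$public$effect_sd)
    })
    names(ts) <- items
    ts
  })
  bias <- stage("bias", do.call(selection_bias_spec,
                                lapply(config$public$bias, unlist)))
  survey <- stage("survey", simulate_survey(table, config$public$n, truths,
                                            K = Ks, bias = bias, seed = seeds[3]))
  survey <- stage("exclusions", apply_exclusions(survey, mode = "public"))

  smp <- config$sampler
  fits <- stage("fit", {
    out <- lapply(seq_along(items), function(i) {
      fit_ordinal_mrp(survey, items[i], K = Ks[i],
                      chains = smp$chains, iter = smp$iter, warmup = smp$warmup,
                      seed = seeds[4] + i, rhat_max = smp$rhat_max)
    })
    names(out) <- items
    out
  })

  support <- stage("poststratify", report_support_summary(
    fits[Ks == 7], table,
    collapse = list(oppose = 1:3, neutral = 4, support = 5:7)
  ))

  rope <- rope_config(config$rope$lower, config$rope$upper,
                      unlist(config$rope$thresholds))
  psup_tab <- stage("psup", {
    rows <- lapply(seq_along(config$psup_pairs), function(i) {
      pr <- unlist(config$psup_pairs[[i]])
      ps <- psup_mrp(survey, pr[1], pr[2], table = table, scale = Ks[[pr[1]]],
                     chains = smp$chains, iter = smp$iter, warmup = smp$warmup,
                     seed = seeds[5] + i, rhat_max = smp$rhat_max)
      cbind(rope_classify(ps, rope), tie_prop = ps$tie_prop)
    })
    do.call(rbind, rows)
  })

  personnel <- stage("personnel", {
    roster <- sample_respondents(table, config$personnel$n, seed = seeds[6])
    for (i in seq_along(items)) {
      roster <- simulate_ordinal_responses(roster, truths[[i]], K = Ks[i],
                                           seed = seeds[7] + i, item = items[i])
    }
    roster$conducted_hct <- FALSE
    roster
  })

  rand_tab <- stage("randomization", {
    prs <- utils::combn(items, 2)
    rows <- lapply(seq_len(ncol(prs)), function(i) {
      rt <- randomization_test(personnel[[prs[1, i]]], personnel[[prs[2, i]]],
                               permutations = config$permutation$permutations,
                               seed = seeds[8] + i, pair = prs[, i])
      data.frame(item_a = prs[1, i], item_b = prs[2, i],
                 psup = rt$observed, c_value = rt$c_value)
    })
    tab <- do.call(rbind, rows)
    sel <- select_within_budget(tab$c_value, budget = config$permutation$budget,
                                labels = paste(tab$item_a, tab$item_b, sep = " vs "))
    tab$selected <- sel$selected[match(paste(tab$item_a, tab$item_b, sep = " vs "),
                                       sel$label)]
    tab
  })

  pop_vs_fixed <- stage("pop_vs_fixed", {
    rows <- lapply(items, function(it) {
      est <- poststratify(fits[[it]], table, estimand = "category_prob",
                          seed = seeds[9])
      ps <- psup_pop_vs_fixed(est, personnel[[it]],
                              pair = c(paste0(it, " (population)"),
                                       paste0(it, " (personnel)")))
      data.frame(item = it, psup_mean = ps$mean,
                 hdi_lower = ps$hdi_lower, hdi_upper = ps$hdi_upper)
    })
    do.call(rbind, rows)
  })

  manifest <- list(
    package_version = as.character(packageVersion("mrpsup")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_public = nrow(survey),
    n_personnel = nrow(personnel),
    items = as.list(setNames(as.integer(Ks), items)),
    diagnostics = lapply(fits, function(f) list(
      rhat_max = f$diagnostics$rhat_max, ess_min = f$diagnostics$ess_min
    ))
  )

  results <- list(support_summary = support, psup_decisions = psup_tab,
                  personnel_randomization = rand_tab,
                  population_vs_personnel = pop_vs_fixed,
                  fits = fits, table = table, survey = survey,
                  personnel = personnel, manifest = manifest, config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(support, file.path(output_dir, "support_summary.csv"), row.names = FALSE)
    write.csv(psup_tab, file.path(output_dir, "psup_decisions.csv"), row.names = FALSE)
    write.csv(rand_tab, file.path(output_dir, "personnel_randomization.csv"),
              row.names = FALSE)
    write.csv(pop_vs_fixed, file.path(output_dir, "population_vs_personnel.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}

#' Poststratified 3-category support summary per item
#'
#' Collapses each fitted 7-point support item to oppose/neutral/support at
#' population level: per posterior draw the collapsed probabilities sum to
#' 1, and each category is summarized by mean and HDI.
#'
#' @param fits Named list of ordinal `posterior_fit`s.
#' @param table Poststratification table.
#' @param collapse Named list of category index sets.
#' @param level HDI mass.
#' @param seed Seed for unseen-level prediction.
#' @return Tidy data frame: item, category, mean, hdi_lower, hdi_upper.
#' @export
report_support_summary <- function(fits, table,
                                   collapse = list(oppose = 1:3, neutral = 4,
                                                   support = 5:7),
                                   level = 0.95, seed = 1) {
  rows <- lapply(names(fits), function(it) {
    est <- poststratify(fits[[it]], table, estimand = collapse, level = level,
                        seed = seed)
    s <- est$summary
    data.frame(item = it, category = s$quantity, mean = s$mean,
               hdi_lower = s$hdi_lower, hdi_upper = s$hdi_upper,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
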