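#' Read and write survey tables with a data dictionary
#'
#' Surveys are plain CSV (UTF-8, header row) with a JSON sidecar dictionary
#' declaring the ordinal scale size per item and the level ordering per
#' demographic factor.
#'
#' @param path CSV file path.
#' @param dictionary Path to a JSON dictionary, or a dictionary list as
#'   returned by [read_dictionary()]. When supplied, responses are checked
#'   against their declared `1..K` range and demographics against their
#'   level sets.
#' @return A data frame; the dictionary (if any) is attached as attribute
#'   `"dictionary"`.
#' @export
read_survey <- function(path, dictionary = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.character(dictionary)) dictionary <- read_dictionary(dictionary)
  if (!is.null(dictionary)) {
    for (item in names(dictionary$items)) {
      if (!item %in% names(df)) next
      K <- dictionary$items[[item]]$K
      v <- df[[item]]
      bad <- !is.na(v) & (v < 1 | v > K | v != round(v))
      if (any(bad)) {
        stop_mrpsup(sprintf("item '%s': responses outside 1..%d", item, K))
      }
    }
    for (f in names(dictionary$levels)) {
      if (!f %in% names(df)) next
      bad <- !is.na(df[[f]]) & !df[[f]] %in% dictionary$levels[[f]]
      if (any(bad)) {
        stop_mrpsup(sprintf("factor '%s': undeclared levels: %s", f,
                            paste(unique(df[[f]][bad]), collapse = ", ")))
      }
    }
    attr(df, "dictionary") <- dictionary
  }
  df
}

#' @rdname read_survey
#' @param data Survey data frame to write.
#' @export
write_survey <- function(data, path, dictionary = NULL) {
  write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dictionary)) {
    write_dictionary(dictionary, sub("\\.csv$", ".dictionary.json", path))
  }
  invisible(path)
}

#' @rdname read_survey
#' @export
read_poststrat <- function(path, dictionary = NULL) {
  df <- read_survey(path, dictionary)
  if (!"count" %in% names(df)) stop_mrpsup("poststratification table needs a 'count' column")
  if (any(!is.finite(df$count)) || any(df$count < 0)) {
    stop_mrpsup("poststratification counts must be finite and non-negative")
  }
  key <- do.call(paste, df[setdiff(names(df), "count")])
  if (anyDuplicated(key)) stop_mrpsup("duplicate cells in poststratification table")
  class(df) <- c("poststrat_table", "data.frame")
  df
}

#' @rdname read_survey
#' @export
write_poststrat <- function(data, path, dictionary = NULL) {
  write_survey(as.data.frame(data), path, dictionary)
}

#' Data dictionary: declared scale sizes and level orderings
#'
#' @param items Named list: item name -> list with at least `K` (scale size).
#' @param levels Named list: factor name -> ordered character vector of levels.
#' @return Dictionary list of class `survey_dictionary`.
#' @export
survey_dictionary <- function(items = list(), levels = list()) {
  for (nm in names(items)) {
    K <- items[[nm]]$K
    if (!is_scalar_number(K) || K < 2) {
      stop_mrpsup("dictionary item '", nm, "' needs a scale size K >= 2")
    }
  }
  structure(list(items = items, levels = levels), class = "survey_dictionary")
}

#' @rdname survey_dictionary
#' @param path JSON file path.
#' @export
read_dictionary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- lapply(raw$items, function(x) list(K = as.integer(x$K), labels = x$labels))
  survey_dictionary(items = items, levels = lapply(raw$levels, as.character))
}

#' @rdname survey_dictionary
#' @param dictionary Dictionary to write.
#' @export
write_dictionary <- function(dictionary, path) {
  jsonlite::write_json(unclass(dictionary), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Apply the study exclusion rules
#'
#' Public mode removes respondents who failed any comprehension check and
#' respondents whose sex is outside the male/female binary (the
#' poststratification frame records sex as binary, so other respondents
#' cannot be poststratified). Personnel mode keeps only personnel who have
#' not conducted an HCT for general-support and interest/barrier outcomes,
#' and retains everyone for importance and acceptability ratings; rows
#' missing any of `items` are dropped (complete case within outcome).
#'
#' @param raw Survey data frame.
#' @param mode `"public"` or `"personnel"`.
#' @param outcome_context For personnel: one of `"general_support"`,
#'   `"interest_barriers"`, `"allowed"`, `"importance"`, `"acceptability"`.
#' @param items Optional character vector of item columns that must be
#'   non-missing.
#' @return The filtered data frame.
#' @export
apply_exclusions <- function(raw, mode = c("public", "personnel"),
                             outcome_context = NULL, items = NULL) {
  mode <- match.arg(mode)
  keep <- rep(TRUE, nrow(raw))
  if (mode == "public") {
    for (col in c("comprehension_pass", "sex")) {
      if (!col %in% names(raw)) {
        stop_mrpsup("apply_exclusions: missing required column '", col, "'")
      }
    }
    keep <- keep & raw$comprehension_pass %in% TRUE
    keep <- keep & raw$sex %in% c("Male", "Female")
  } else {
    hct_gated <- c("general_support", "interest_barriers", "allowed")
    if (is.null(outcome_context)) {
      stop_mrpsup("apply_exclusions: personnel mode needs an outcome_context")
    }
    outcome_context <- match.arg(outcome_context,
                                 c(hct_gated, "importance", "acceptability"))
    if (outcome_context %in% hct_gated) {
      if (!"conducted_hct" %in% names(raw)) {
        stop_mrpsup("apply_exclusions: missing required column 'conducted_hct'")
      }
      keep <- keep & !(raw$conducted_hct %in% TRUE)
    }
  }
  for (item in items) {
    if (!item %in% names(raw)) {
      stop_mrpsup("apply_exclusions: missing item column '", item, "'")
    }
    keep <- keep & !is.na(raw[[item]])
  }
  raw[keep, , drop = FALSE]
}

#' Collapse a 7-point support rating to oppose / neutral / support
#'
#' Ratings 1-3 (the three "oppose" anchors) map to `oppose`, the scale
#' midpoint 4 ("Neither support nor oppose") to `neutral`, and 5-7 to
#' `support`.
#'
#' @param rating Integer vector of ratings in `1..7` (NAs pass through).
#' @return Factor with levels `oppose`, `neutral`, `support`.
#' @export
collapse_support <- function(rating) {
  ok <- is.na(rating) | (rating %in% 1:7)
  if (!all(ok)) stop_mrpsup("collapse_support: ratings must be in 1..7")
  out <- ifelse(rating <= 3, "oppose", ifelse(rating == 4, "neutral", "support"))
  factor(out, levels = c("oppose", "neutral", "support"))
}

#' Paired comparison category for two ratings on a shared scale
#'
#' For each respondent, the sign of `a - b` is mapped to
#' `greater` / `equal` / `less` — the 3-level outcome on which the
#' population probability of superiority is modelled.
#'
#' @param a,b Integer rating vectors of equal length, on the same scale.
#' @param scale_a,scale_b Declared scale sizes; supplying different values
#'   is an error, and ratings are checked against the scale when given.
#' @return Factor with levels `less`, `equal`, `greater`.
#' @export
derive_comparison <- function(a, b, scale_a = NULL, scale_b = scale_a) {
  if (length(a) != length(b)) stop_mrpsup("derive_comparison: length mismatch")
  if (!is.null(scale_a) && !is.null(scale_b) && scale_a != scale_b) {
    stop_mrpsup("derive_comparison: items are on different scales (",
                scale_a, " vs ", scale_b, ")")
  }
  if (!is.null(scale_a)) {
    if (any(stats::na.omit(c(a, b)) < 1) || any(stats::na.omit(c(a, b)) > scale_a)) {
      stop_mrpsup("derive_comparison: ratings outside 1..", scale_a)
    }
  }
  out <- ifelse(a > b, "greater", ifelse(a == b, "equal", "less"))
  factor(out, levels = c("less", "equal", "greater"))
}

#' Z-score a state-level covariate across states
#'
#' Centered and scaled across states (sample standard deviation, n-1
#' denominator) — not across respondents.
#'
#' @param rates Named numeric vector, one rate per state (>= 2 states).
#' @return Named numeric vector of z-scores.
#' @export
zscore_state_covariate <- function(rates) {
  if (length(rates) < 2) stop_mrpsup("zscore_state_covariate: need >= 2 states")
  if (any(!is.finite(rates))) stop_mrpsup("zscore_state_covariate: rates must be finite")
  s <- sd(rates)
  if (s < 1e-12) stop_mrpsup("zscore_state_covariate: rates are constant")
  (rates - mean(rates)) / s
}

#' Load the deposited study data (user-supplied download)
#'
#' The study's respondent-level deposit is not distributed with the
#' package; download it from the archive it is published in and point
#' `dir` at the folder holding the public-sample and personnel CSVs.
#'
#' @param dir Directory containing `public_sample.csv` and
#'   `research_personnel.csv`.
#' @return List with elements `public` and `personnel`.
#' @export
load_deposited_survey <- function(dir) {
  pub <- file.path(dir, "public_sample.csv")
  per <- file.path(dir, "research_personnel.csv")
  for (f in c(pub, per)) {
    if (!file.exists(f)) {
      stop_mrpsup("deposited data not found: ", f,
                  " (download the study deposit and point `dir` at it)")
    }
  }
  list(public = read_survey(pub), personnel = read_survey(per))
}
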