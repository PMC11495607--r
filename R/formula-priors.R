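#' Model formula for MRP fits
#'
#' The study formula has population-level (fixed) terms for sex, region and
#' the z-scored state hesitancy covariate, and varying intercepts for age
#' band, education, income, race, party, state, and the sex x race and
#' education x age interactions:
#'
#' `Outcome ~ Sex + (1|Age) + (1|Education) + (1|Income) + (1|Race) +
#'  (1|Party) + (1|State) + (1|Sex:Race) + (1|Education:Age) + Region +
#'  State_Vaccine_Hesitancy`
#'
#' @param fixed Character vector of fixed-effect columns (numeric columns
#'   enter as slopes, character columns as treatment-coded dummies).
#' @param varying Character vector of varying-intercept factors;
#'   interactions are written `"a:b"`.
#' @return An object of class `formula_spec`.
#' @export
formula_spec <- function(fixed = c("sex", "region", "state_hesitancy_z"),
                         varying = c("age_band", "education", "income", "race",
                                     "party", "state", "sex:race",
                                     "education:age_band")) {
  stopifnot(is.character(fixed), is.character(varying))
  structure(list(fixed = fixed, varying = varying), class = "formula_spec")
}

#' Prior scales for MRP fits
#'
#' All priors are zero-centered and weakly informative: normal for
#' intercepts/cutpoints and fixed effects, half-normal for group standard
#' deviations. The default cutpoint/intercept scale of 4 follows the
#' widened-intercept convention for these ordinal models; fixed effects
#' default to normal(0, 2) and group sds to half-normal(0, 1).
#'
#' @param cutpoint_scale SD of the normal prior on cutpoints (ordinal) and
#'   category intercepts (categorical).
#' @param fixed_scale SD of the normal prior on fixed-effect coefficients.
#' @param group_sd_scale Scale of the half-normal prior on group sds.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(cutpoint_scale = 4, fixed_scale = 2, group_sd_scale = 1) {
  for (s in c(cutpoint_scale, fixed_scale, group_sd_scale)) {
    if (!is_scalar_number(s) || s <= 0) stop_mrpsup("prior scales must be positive")
  }
  structure(list(cutpoint_scale = cutpoint_scale, fixed_scale = fixed_scale,
                 group_sd_scale = group_sd_scale),
            class = "prior_spec")
}

# Interaction-aware column lookup: "a:b" pastes columns a and b.
factor_key <- function(data, f) {
  if (grepl(":", f, fixed = TRUE)) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    for (p in parts) {
      if (!p %in% names(data)) stop_mrpsup("formula factor not in data: ", p)
    }
    do.call(paste, c(lapply(parts, function(p) data[[p]]), sep = ":"))
  } else {
    if (!f %in% names(data)) stop_mrpsup("formula factor not in data: ", f)
    as.character(data[[f]])
  }
}

# Build the fixed-effect design matrix (no intercept; treatment contrasts
# with the first sorted level as reference) plus reusable term metadata.
build_fixed_design <- function(data, fixed, meta = NULL) {
  cols <- list()
  terms <- meta %||% list()
  for (term in fixed) {
    if (!term %in% names(data)) stop_mrpsup("formula factor not in data: ", term)
    v <- data[[term]]
    if (is.numeric(v)) {
      terms[[term]] <- terms[[term]] %||% list(type = "numeric")
      cols[[term]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      if (is.null(terms[[term]])) {
        levs <- sort(unique(v))
        if (length(levs) < 2) {
          stop_mrpsup("fixed factor '", term, "' has a single observed level")
        }
        terms[[term]] <- list(type = "factor", levels = levs)
      }
      levs <- terms[[term]]$levels
      unseen <- setdiff(unique(v), levs)
      if (length(unseen)) {
        stop_mrpsup("fixed factor '", term, "' has levels unseen at fit time: ",
                    paste(unseen, collapse = ", "))
      }
      for (l in levs[-1]) cols[[paste0(term, "=", l)]] <- as.numeric(v == l)
    }
  }
  X <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(0, nrow(data), 0)
  }
  colnames(X) <- names(cols)
  list(X = X, terms = terms)
}

# Integer group indices per varying factor; `levels_list` reuses a fit's
# level sets (returning 0 for unseen levels) when supplied.
build_group_index <- function(data, varying, levels_list = NULL) {
  idx <- list()
  levels_out <- list()
  for (f in varying) {
    key <- factor_key(data, f)
    levs <- levels_list[[f]] %||% sort(unique(key))
    if (is.null(levels_list) && length(levs) < 2) {
      stop_mrpsup("varying factor '", f, "' has a single observed level")
    }
    m <- match(key, levs)
    m[is.na(m)] <- 0L
    idx[[f]] <- m
    levels_out[[f]] <- levs
  }
  list(index = idx, levels = levels_out)
}
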