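# Slice-within-Gibbs sampler for the hierarchical categorical logit model
# (2-3 unordered categories, first category as the fixed reference). Each
# non-reference category has its own intercept, fixed-effect coefficients
# and varying intercepts; every scalar gets a univariate slice update on
# its exact conditional, which is derivative-free and needs no tuning.

#' Fit a hierarchical categorical (multinomial logit) model
#'
#' The MRP stage for unordered outcomes — e.g. the 3-level
#' greater/equal/less comparison variable behind population PSup, or party
#' identification when extending a poststratification table.
#'
#' @inheritParams fit_ordinal_mrp
#' @param item Name of the categorical response column.
#' @param categories Category labels in order; the first is the reference.
#'   Defaults to the sorted observed values.
#' @return A `posterior_fit` with `family = "categorical_logit"`.
#' @export
fit_categorical_mrp <- function(data, item, formula = formula_spec(),
                                priors = prior_spec(), categories = NULL,
                                chains = 4, iter = 1000, warmup = 1000, seed = 1,
                                rhat_max = 1.01, check_convergence = TRUE) {
  if (!item %in% names(data)) stop_mrpsup("item '", item, "' not in data")
  fac_cols <- unique(unlist(strsplit(c(formula$fixed, formula$varying), ":", fixed = TRUE)))
  fac_cols <- intersect(fac_cols, names(data))
  cc <- complete.cases(data[, c(item, fac_cols), drop = FALSE])
  data <- data[cc, , drop = FALSE]
  yv <- as.character(data[[item]])
  categories <- categories %||% sort(unique(yv))
  if (length(categories) < 2 || length(categories) > 3) {
    stop_mrpsup("categorical outcomes must have 2-3 categories")
  }
  if (!all(yv %in% categories)) {
    stop_mrpsup("responses outside declared categories: ",
                paste(setdiff(unique(yv), categories), collapse = ", "))
  }
  y <- match(yv, categories)
  fd <- build_fixed_design(data, formula$fixed)
  gi <- build_group_index(data, formula$varying)
  Xc <- cbind(`(Intercept)` = 1, fd$X)
  prep <- list(y = y, C = length(categories), item = item, n = length(y),
               X = Xc, fixed_terms = fd$terms,
               G = gi$index, group_levels = gi$levels,
               categories = categories, K = length(categories),
               moves = detect_translation_moves(Xc, gi$index, gi$levels))
  seeds <- child_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(c) {
    categorical_chain(prep, priors, iter = iter, warmup = warmup, seed = seeds[c])
  })
  finish_fit(runs, prep, "categorical_logit", priors, formula, seed,
             rhat_max, check_convergence)
}

categorical_chain <- function(prep, priors, iter, warmup, seed) {
  y <- prep$y; C <- prep$C; n <- prep$n
  X <- prep$X; P <- ncol(X)
  G <- lapply(prep$G, as.integer)
  L <- vapply(prep$group_levels, length, 0L)
  Fg <- length(G)
  NC <- C - 1L # modelled (non-reference) categories
  s_int <- priors$cutpoint_scale
  s_fix <- priors$fixed_scale
  s_gsd <- priors$group_sd_scale
  prior_sd_beta <- c(s_int, rep(s_fix, P - 1L))
  moves <- index_moves(prep$moves, names(G))
  # drop intercept-vs-factor moves: the dedicated intercept translation
  # above already covers them
  moves$fixed <- Filter(function(mv) mv$p != 1L, moves$fixed)

  with_seed(seed, {
    B <- matrix(0, P, NC)
    u <- lapply(seq_len(Fg), function(f) matrix(0, L[f], NC))
    sd_u <- matrix(0.5, Fg, NC)
    eta <- matrix(0, n, NC)
    # start intercepts at empirical log-odds vs the reference
    cnt <- pmax(tabulate(y, C), 0.5)
    B[1, ] <- log(cnt[-1] / cnt[1])
    eta <- eta + matrix(B[1, ], n, NC, byrow = TRUE)

    rows_by_level <- lapply(seq_len(Fg), function(f) split(seq_len(n), G[[f]]))
    is_cat <- lapply(seq_len(NC), function(c) as.numeric(y == c + 1L))

    draws_beta <- matrix(NA_real_, iter, P * NC)
    colnames(draws_beta) <- as.vector(outer(colnames(X), prep$categories[-1],
                                            paste, sep = "|"))
    draws_sd <- matrix(NA_real_, iter, Fg * NC)
    colnames(draws_sd) <- as.vector(outer(names(G), prep$categories[-1],
                                          paste, sep = "|"))
    draws_u <- lapply(seq_len(Fg), function(f) {
      m <- matrix(NA_real_, iter, L[f] * NC)
      colnames(m) <- as.vector(outer(prep$group_levels[[f]], prep$categories[-1],
                                     paste, sep = "|"))
      m
    })
    names(draws_u) <- names(G)

    for (t in seq_len(warmup + iter)) {
      for (cc in seq_len(NC)) {
        # part of the likelihood denominator not involving category cc
        M <- if (NC == 1L) rep(1, n) else 1 + exp(eta[, -cc])
        ind <- is_cat[[cc]]

        # fixed effects (incl. intercept)
        for (p in seq_len(P)) {
          x <- X[, p]
          S <- if (p == 1L) seq_len(n) else which(x != 0)
          if (!length(S)) next
          old <- B[p, cc]
          eta0 <- eta[S, cc] - x[S] * old
          MS <- M[S]; indS <- ind[S]; xS <- x[S]
          logf <- function(v) {
            e <- eta0 + xS * v
            sum(indS * e - log(MS + exp(pmin(e, 500)))) -
              v^2 / (2 * prior_sd_beta[p]^2)
          }
          B[p, cc] <- slice1(old, logf, w = 0.5)
          eta[S, cc] <- eta0 + xS * B[p, cc]
        }

        # varying intercepts
        for (f in seq_len(Fg)) {
          sdc <- sd_u[f, cc]
          for (j in seq_len(L[f])) {
            S <- rows_by_level[[f]][[as.character(j)]]
            old <- u[[f]][j, cc]
            if (is.null(S)) {
              u[[f]][j, cc] <- rnorm(1, 0, sdc)
              next
            }
            eta0 <- eta[S, cc] - old
            MS <- M[S]; indS <- ind[S]
            logf <- function(v) {
              e <- eta0 + v
              sum(indS * e - log(MS + exp(pmin(e, 500)))) - v^2 / (2 * sdc^2)
            }
            u[[f]][j, cc] <- slice1(old, logf, w = 0.5)
            eta[S, cc] <- eta0 + u[[f]][j, cc]
          }
        }

        # group sds: centered slice update interweaved with a
        # non-centered one (rescales the effects, breaking the funnel)
        for (f in seq_len(Fg)) {
          SS <- sum(u[[f]][, cc]^2)
          Lf <- L[f]
          sd_u[f, cc] <- slice1(sd_u[f, cc], function(s) {
            if (s <= 0) return(-Inf)
            -Lf * log(s) - SS / (2 * s^2) - s^2 / (2 * s_gsd^2)
          }, w = 0.3, lower = 1e-6, upper = 50)

          g <- G[[f]]
          s_old <- sd_u[f, cc]
          ut_g <- u[[f]][g, cc] / s_old
          eta_base <- eta[, cc] - u[[f]][g, cc]
          sd_u[f, cc] <- slice1(s_old, function(s) {
            if (s <= 0) return(-Inf)
            e <- eta_base + s * ut_g
            sum(ind * e - log(M + exp(pmin(e, 500)))) - s^2 / (2 * s_gsd^2)
          }, w = 0.3, lower = 1e-6, upper = 50)
          if (sd_u[f, cc] != s_old) {
            u[[f]][, cc] <- u[[f]][, cc] * (sd_u[f, cc] / s_old)
            eta[, cc] <- eta_base + u[[f]][g, cc]
          }

          prec_d <- Lf / sd_u[f, cc]^2 + 1 / s_int^2
          mean_d <- (-sum(u[[f]][, cc]) / sd_u[f, cc]^2 + B[1, cc] / s_int^2) / prec_d
          delta <- rnorm(1, mean_d, sqrt(1 / prec_d))
          u[[f]][, cc] <- u[[f]][, cc] + delta
          B[1, cc] <- B[1, cc] - delta
        }

        # likelihood-invariant translation moves between nested terms
        # (eta is unchanged, so no update to it is needed)
        for (mv in moves$fixed) {
          f <- mv$f_idx
          prec_d <- 1 / prior_sd_beta[mv$p]^2 + mv$xss / sd_u[f, cc]^2
          mean_d <- (-B[mv$p, cc] / prior_sd_beta[mv$p]^2 +
                       sum(mv$xlev * u[[f]][, cc]) / sd_u[f, cc]^2) / prec_d
          delta <- rnorm(1, mean_d, sqrt(1 / prec_d))
          B[mv$p, cc] <- B[mv$p, cc] + delta
          u[[f]][, cc] <- u[[f]][, cc] - delta * mv$xlev
        }
        for (mv in moves$varying) {
          f <- mv$f_idx; h <- mv$h_idx
          prec_d <- 1 / sd_u[f, cc]^2 + mv$m / sd_u[h, cc]^2
          sums <- rowsum_by(u[[h]][, cc], mv$map, L[f])
          mean_d <- (-u[[f]][, cc] / sd_u[f, cc]^2 + sums / sd_u[h, cc]^2) / prec_d
          delta <- rnorm(L[f], mean_d, sqrt(1 / prec_d))
          u[[f]][, cc] <- u[[f]][, cc] + delta
          u[[h]][, cc] <- u[[h]][, cc] - delta[mv$map]
        }
      }

      if (t > warmup) {
        k <- t - warmup
        draws_beta[k, ] <- as.vector(B)
        draws_sd[k, ] <- as.vector(sd_u)
        for (f in seq_len(Fg)) draws_u[[f]][k, ] <- as.vector(u[[f]])
      }
    }
    list(beta = draws_beta, sd = draws_sd, u = draws_u)
  })
}
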