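# Gibbs sampler for the hierarchical cumulative ordinal probit model.
#
# Data augmentation (Albert & Chib): each response y in 1..K arises from a
# latent normal z with mean mu and unit sd, cut at ordered thresholds.
# Conditional on z, all regression coefficients and varying intercepts are
# conjugate normals; group sds get slice updates under a half-normal
# prior; cutpoints get a joint Metropolis update on the marginal
# (z integrated out) multinomial likelihood, after which z is redrawn from
# its exact conditional. A translation move per varying factor resamples
# the prior-identified common-location direction (u_f and cutpoints shift
# together), which the plain Gibbs scan mixes slowly over.

#' Fit a hierarchical cumulative ordinal probit model
#'
#' The first MRP stage for a Likert item: a Bayesian cumulative probit
#' regression with the study's fixed effects and varying intercepts,
#' sampled by a data-augmentation Gibbs sampler.
#'
#' @param data Survey data frame (post-exclusion).
#' @param item Name of the ordinal response column (values in `1..K`).
#' @param formula A [formula_spec()].
#' @param priors A [prior_spec()].
#' @param K Scale size; defaults to the data dictionary's declared size,
#'   else the maximum observed response.
#' @param chains Number of chains (run sequentially).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup iterations per chain (adaptation + burn-in).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param rhat_max Convergence gate: error if any monitored split-R-hat
#'   exceeds this (set `check_convergence = FALSE` to override).
#' @param check_convergence Logical; gate on `rhat_max` when `TRUE`.
#' @return A `posterior_fit` object holding draws of fixed effects, group
#'   effects, group sds and cutpoints, plus split-R-hat / ESS diagnostics.
#' @export
fit_ordinal_mrp <- function(data, item, formula = formula_spec(),
                            priors = prior_spec(), K = NULL,
                            chains = 4, iter = 1000, warmup = 1000, seed = 1,
                            rhat_max = 1.01, check_convergence = TRUE) {
  prep <- prepare_fit_data(data, item, formula, K, min_K = 3)
  seeds <- child_seeds(seed, chains)
  runs <- lapply(seq_len(chains), function(c) {
    ordinal_chain(prep, priors, iter = iter, warmup = warmup, seed = seeds[c])
  })
  finish_fit(runs, prep, "ordinal_probit", priors, formula, seed,
             rhat_max, check_convergence)
}

# Shared response/design preparation for both families.
prepare_fit_data <- function(data, item, formula, K, min_K) {
  if (!item %in% names(data)) stop_mrpsup("item '", item, "' not in data")
  dict <- attr(data, "dictionary")
  if (is.null(K)) K <- dict$items[[item]]$K
  fac_cols <- unique(unlist(strsplit(c(formula$fixed, formula$varying), ":", fixed = TRUE)))
  fac_cols <- intersect(fac_cols, names(data))
  cc <- complete.cases(data[, c(item, fac_cols), drop = FALSE])
  data <- data[cc, , drop = FALSE]
  y <- as.integer(data[[item]])
  if (is.null(K)) K <- max(y)
  K <- assert_scalar_count(K, "K")
  if (K < min_K) stop_mrpsup("item scale must have at least ", min_K, " categories")
  if (any(y < 1 | y > K)) stop_mrpsup("responses outside 1..", K)
  fd <- build_fixed_design(data, formula$fixed)
  gi <- build_group_index(data, formula$varying)
  list(y = y, K = K, item = item, n = length(y),
       X = fd$X, fixed_terms = fd$terms,
       G = gi$index, group_levels = gi$levels, data = data,
       moves = detect_translation_moves(fd$X, gi$index, gi$levels))
}

# Likelihood-invariant translation directions between nested terms. A
# fixed column x that is a function of a varying factor's levels (region
# or the state covariate vs state; the sex dummy vs sex:race) trades off
# location with that factor's intercepts, as does a coarse varying factor
# against a finer one it is measurable from (education vs education:age).
# The plain Gibbs scan random-walks along these prior-identified
# directions; resampling each direction from its Gaussian conditional
# under the priors (the likelihood is exactly invariant) restores mixing.
detect_translation_moves <- function(X, G, group_levels) {
  level_value <- function(x, g, L) {
    rng <- tapply(x, g, function(v) diff(range(v)))
    if (any(rng > 1e-12)) return(NULL)
    as.numeric(tapply(x, g, function(v) v[1]))[seq_len(L)]
  }
  fixed_moves <- list()
  for (p in seq_len(ncol(X))) {
    for (f in names(G)) {
      L <- length(group_levels[[f]])
      if (length(unique(G[[f]])) < L) next
      xlev <- level_value(X[, p], G[[f]], L)
      if (!is.null(xlev) && sum(xlev^2) > 0) {
        fixed_moves[[length(fixed_moves) + 1L]] <- list(p = p, f = f, xlev = xlev)
      }
    }
  }
  varying_moves <- list()
  fac <- names(G)
  for (f in fac) {
    for (h in setdiff(fac, f)) {
      Lf <- length(group_levels[[f]])
      Lh <- length(group_levels[[h]])
      if (Lf >= Lh) next
      if (length(unique(G[[h]])) < Lh) next
      map <- level_value(G[[f]], G[[h]], Lh)
      if (!is.null(map) && !anyNA(map) && all(map == round(map))) {
        varying_moves[[length(varying_moves) + 1L]] <-
          list(f = f, h = h, map = as.integer(map))
      }
    }
  }
  list(fixed = fixed_moves, varying = varying_moves)
}

ordinal_chain <- function(prep, priors, iter, warmup, seed) {
  y <- prep$y; K <- prep$K; n <- prep$n
  X <- prep$X; P <- ncol(X)
  G <- lapply(prep$G, as.integer)
  L <- vapply(prep$group_levels, length, 0L)
  Fg <- length(G)
  s_cut <- priors$cutpoint_scale
  s_fix <- priors$fixed_scale
  s_gsd <- priors$group_sd_scale
  moves <- index_moves(prep$moves, names(G))

  with_seed(seed, {
    # init: empirical cutpoints, zero effects
    freq <- cumsum(tabulate(y, K))[-K] / n
    freq <- pmin(pmax(freq, 1 / (n + 1)), n / (n + 1))
    cp <- qnorm(freq)
    cp <- cummax(cp + seq(0, 1e-3, length.out = K - 1)) + seq_len(K - 1) * 1e-6
    beta <- rep(0, P)
    u <- lapply(seq_len(Fg), function(f) rep(0, L[f]))
    sd_u <- rep(0.5, Fg)
    mu_fixed <- as.vector(X %*% beta)
    mu_group <- rep(0, n)

    XtX <- crossprod(X)
    group_n <- lapply(seq_len(Fg), function(f) tabulate(G[[f]], L[f]))

    step <- 2 / sqrt(n)
    lo_idx <- y - 1L
    hi_idx <- y
    n_keep <- iter
    draws_beta <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, colnames(X)))
    draws_cp <- matrix(NA_real_, n_keep, K - 1,
                       dimnames = list(NULL, paste0("cut", seq_len(K - 1))))
    draws_sd <- matrix(NA_real_, n_keep, Fg, dimnames = list(NULL, names(G)))
    draws_u <- lapply(seq_len(Fg), function(f) {
      matrix(NA_real_, n_keep, L[f],
             dimnames = list(NULL, prep$group_levels[[f]]))
    })
    names(draws_u) <- names(G)

    cut_loglik <- function(cp, mu) {
      bounds <- c(-Inf, cp, Inf)
      p <- pnorm(bounds[hi_idx + 1L] - mu) - pnorm(bounds[lo_idx + 1L] - mu)
      sum(log(pmax(p, 1e-300)))
    }

    mu <- mu_fixed + mu_group
    ll <- cut_loglik(cp, mu)

    for (t in seq_len(warmup + iter)) {
      ## cutpoints: joint random-walk MH on (c1, log diffs), z marginalized
      d <- c(cp[1], if (K > 2) log(diff(cp)))
      d_new <- d + rnorm(K - 1, 0, step)
      cp_new <- cumsum(c(d_new[1], if (K > 2) exp(d_new[-1])))
      ll_new <- cut_loglik(cp_new, mu)
      lp_new <- ll_new + sum(dnorm(cp_new, 0, s_cut, log = TRUE)) +
        sum(d_new[-1])
      lp_old <- ll + sum(dnorm(cp, 0, s_cut, log = TRUE)) + sum(d[-1])
      acc <- log(runif(1)) < lp_new - lp_old
      if (acc) {
        cp <- cp_new
        ll <- ll_new
      }
      if (t <= warmup) step <- step * exp(0.05 * ((if (acc) 1 else 0) - 0.25))

      ## latent responses z | cp, mu, y
      bounds <- c(-Inf, cp, Inf)
      cl <- bounds[lo_idx + 1L]
      cu <- bounds[hi_idx + 1L]
      plo <- pnorm(cl - mu)
      phi_ <- pnorm(cu - mu)
      uu <- plo + runif(n) * (phi_ - plo)
      uu <- pmin(pmax(uu, 1e-15), 1 - 1e-15)
      z <- mu + qnorm(uu)
      z <- pmin(pmax(z, ifelse(is.finite(cl), cl + 1e-10, -Inf)),
                ifelse(is.finite(cu), cu - 1e-10, Inf))

      ## fixed effects beta | z
      if (P > 0) {
        r <- z - mu_group
        prec <- XtX + diag(1 / s_fix^2, P)
        ch <- chol(prec)
        m <- backsolve(ch, forwardsolve(t(ch), crossprod(X, r)))
        beta <- as.vector(m + backsolve(ch, rnorm(P)))
        mu_fixed <- as.vector(X %*% beta)
      }

      ## varying intercepts u_f | z, with conjugate per-level updates
      for (f in seq_len(Fg)) {
        g <- G[[f]]
        mu_group <- mu_group - u[[f]][g]
        r <- z - mu_fixed - mu_group
        s_j <- rowsum_by(r, g, L[f])
        v_j <- 1 / (group_n[[f]] + 1 / sd_u[f]^2)
        u[[f]] <- rnorm(L[f], s_j * v_j, sqrt(v_j))
        mu_group <- mu_group + u[[f]][g]
      }

      ## group sds | u (half-normal prior, slice update), interweaved with
      ## a non-centered update (u = sd * u_tilde; conditional on u_tilde
      ## and z the sd is conjugate truncated-normal), which breaks the
      ## funnel coupling between small sds and shrunken effects
      for (f in seq_len(Fg)) {
        SS <- sum(u[[f]]^2)
        Lf <- L[f]
        sd_u[f] <- slice1(sd_u[f], function(s) {
          if (s <= 0) return(-Inf)
          -Lf * log(s) - SS / (2 * s^2) - s^2 / (2 * s_gsd^2)
        }, w = 0.3, lower = 1e-6, upper = 50)

        g <- G[[f]]
        ut <- u[[f]] / sd_u[f]
        a <- ut[g]
        r <- z - mu_fixed - (mu_group - u[[f]][g])
        prec_s <- sum(a^2) + 1 / s_gsd^2
        mean_s <- sum(a * r) / prec_s
        sd_s <- sqrt(1 / prec_s)
        plo <- pnorm(0, mean_s, sd_s)
        sd_new <- mean_s + sd_s * qnorm(plo + runif(1) * (1 - plo))
        if (is.finite(sd_new) && sd_new > 1e-6) {
          sd_u[f] <- sd_new
          mu_group <- mu_group - u[[f]][g]
          u[[f]] <- ut * sd_new
          mu_group <- mu_group + u[[f]][g]
        }
      }

      ## translation moves along likelihood-invariant directions, each
      ## drawn from its Gaussian conditional under the priors:
      ## (a) factor location vs cutpoints
      for (f in seq_len(Fg)) {
        prec_d <- L[f] / sd_u[f]^2 + (K - 1) / s_cut^2
        mean_d <- -(sum(u[[f]]) / sd_u[f]^2 + sum(cp) / s_cut^2) / prec_d
        delta <- rnorm(1, mean_d, sqrt(1 / prec_d))
        u[[f]] <- u[[f]] + delta
        cp <- cp + delta
      }
      ## (b) fixed column vs a varying factor it is measurable from
      for (mv in moves$fixed) {
        f <- mv$f_idx
        prec_d <- 1 / s_fix^2 + mv$xss / sd_u[f]^2
        mean_d <- (-beta[mv$p] / s_fix^2 + sum(mv$xlev * u[[f]]) / sd_u[f]^2) / prec_d
        delta <- rnorm(1, mean_d, sqrt(1 / prec_d))
        beta[mv$p] <- beta[mv$p] + delta
        u[[f]] <- u[[f]] - delta * mv$xlev
      }
      ## (c) coarse varying factor vs a finer one it is measurable from
      for (mv in moves$varying) {
        f <- mv$f_idx; h <- mv$h_idx
        prec_d <- 1 / sd_u[f]^2 + mv$m / sd_u[h]^2
        sums <- rowsum_by(u[[h]], mv$map, L[f])
        mean_d <- (-u[[f]] / sd_u[f]^2 + sums / sd_u[h]^2) / prec_d
        delta <- rnorm(L[f], mean_d, sqrt(1 / prec_d))
        u[[f]] <- u[[f]] + delta
        u[[h]] <- u[[h]] - delta[mv$map]
      }
      mu_fixed <- as.vector(X %*% beta)
      mu_group <- rep(0, n)
      for (f in seq_len(Fg)) mu_group <- mu_group + u[[f]][G[[f]]]

      mu <- mu_fixed + mu_group
      ll <- cut_loglik(cp, mu)

      if (t > warmup) {
        k <- t - warmup
        draws_beta[k, ] <- beta
        draws_cp[k, ] <- cp
        draws_sd[k, ] <- sd_u
        for (f in seq_len(Fg)) draws_u[[f]][k, ] <- u[[f]]
      }
    }
    list(beta = draws_beta, cutpoints = draws_cp, sd = draws_sd, u = draws_u)
  })
}

# Resolve factor names in translation moves to indices and precompute
# sums of squares / level multiplicities.
index_moves <- function(moves, fac_names) {
  fixed <- lapply(moves$fixed, function(mv) {
    mv$f_idx <- match(mv$f, fac_names)
    mv$xss <- sum(mv$xlev^2)
    mv
  })
  varying <- lapply(moves$varying, function(mv) {
    mv$f_idx <- match(mv$f, fac_names)
    mv$h_idx <- match(mv$h, fac_names)
    mv$m <- tabulate(mv$map, max(mv$map))
    mv
  })
  list(fixed = fixed, varying = varying)
}

# Fast grouped sums (levels 1..L; index 0 would mean unseen and cannot
# occur at fit time).
rowsum_by <- function(x, g, L) {
  out <- rep(0, L)
  s <- rowsum(x, g, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Assemble chains into a posterior_fit, compute diagnostics, apply the
# convergence gate.
finish_fit <- function(runs, prep, family, priors, formula, seed,
                       rhat_max, check_convergence) {
  comp_names <- names(runs[[1]])
  draws <- list()
  for (nm in comp_names) {
    if (nm == "u") {
      draws$u <- lapply(seq_along(runs[[1]]$u), function(f) {
        do.call(rbind, lapply(runs, function(r) r$u[[f]]))
      })
      names(draws$u) <- names(runs[[1]]$u)
    } else {
      draws[[nm]] <- do.call(rbind, lapply(runs, function(r) r[[nm]]))
    }
  }
  # diagnostics over every scalar parameter
  flat_chain <- function(run) {
    mats <- c(list(run$beta), list(run$cutpoints), list(run$sd),
              unname(run$u %||% list()))
    mats <- Filter(function(m) !is.null(m) && ncol(m) > 0, mats)
    do.call(cbind, mats)
  }
  chain_mats <- lapply(runs, flat_chain)
  npar <- ncol(chain_mats[[1]])
  rhat <- ess <- rep(NA_real_, npar)
  for (j in seq_len(npar)) {
    per_chain <- lapply(chain_mats, function(m) m[, j])
    rhat[j] <- split_rhat(per_chain)
    ess[j] <- ess_basic(per_chain)
  }
  names(rhat) <- names(ess) <- colnames(chain_mats[[1]])
  fit <- structure(
    list(
      family = family, item = prep$item, K = prep$K, n = prep$n,
      draws = draws,
      fixed_terms = prep$fixed_terms,
      fixed_columns = colnames(prep$X),
      group_levels = prep$group_levels,
      formula = formula, priors = priors, seed = seed,
      chains = length(runs), iter_per_chain = nrow(chain_mats[[1]]),
      diagnostics = list(rhat = rhat, ess = ess,
                         rhat_max = max(rhat, na.rm = TRUE),
                         ess_min = min(ess, na.rm = TRUE)),
      categories = prep$categories %||% NULL
    ),
    class = "posterior_fit"
  )
  if (check_convergence && is.finite(fit$diagnostics$rhat_max) &&
      fit$diagnostics$rhat_max > rhat_max) {
    worst <- names(which.max(rhat))
    stop_mrpsup(sprintf(
      "fit did not converge: split-R-hat %.3f on '%s' exceeds %.2f (raise iter/warmup, or set check_convergence = FALSE)",
      fit$diagnostics$rhat_max, worst, rhat_max))
  }
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit: %s>\n", x$family))
  cat(sprintf("  item '%s' (K = %d), n = %d\n", x$item, x$K, x$n))
  cat(sprintf("  %d chains x %d draws; max split-R-hat %.3f, min ESS %.0f\n",
              x$chains, x$iter_per_chain,
              x$diagnostics$rhat_max, x$diagnostics$ess_min))
  invisible(x)
}

#' Total posterior draws in a fit
#' @param fit A `posterior_fit`.
#' @return Integer number of draws (all chains pooled).
#' @export
n_draws <- function(fit) {
  if (!is.null(fit$draws$beta)) return(nrow(fit$draws$beta))
  nrow(fit$draws$cutpoints)
}
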