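#' Highest density interval of a sample of draws
#'
#' The narrowest contiguous interval containing `prob` of the draws,
#' computed by scanning all windows of the sorted sample.
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Probability mass the interval must contain (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(1e4))
hdi <- function(x, prob = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop_mrpsup("hdi() needs at least 2 finite draws")
  if (!is_scalar_number(prob) || prob <= 0 || prob >= 1) {
    stop_mrpsup("`prob` must be in (0, 1)")
  }
  s <- sort(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(s[1], s[n]))
  k <- n - m
  widths <- s[(m + 1):n] - s[1:k]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

#' Summarize posterior draws by mean and highest density interval
#'
#' @param draws Numeric vector, or matrix with one column per quantity.
#' @param level Mass of the HDI (default 0.95).
#' @return A data frame with columns `mean`, `hdi_lower`, `hdi_upper`,
#'   one row per quantity.
#' @export
summarize_posterior <- function(draws, level = 0.95) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 100L) {
    stop_mrpsup("summarize_posterior() needs at least 100 draws")
  }
  out <- data.frame(
    quantity = colnames(draws) %||% paste0("q", seq_len(ncol(draws))),
    mean = colMeans(draws),
    hdi_lower = NA_real_,
    hdi_upper = NA_real_,
    row.names = NULL
  )
  for (j in seq_len(ncol(draws))) {
    h <- hdi(draws[, j], prob = level)
    out$hdi_lower[j] <- h[1]
    out$hdi_upper[j] <- h[2]
  }
  attr(out, "level") <- level
  out
}
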