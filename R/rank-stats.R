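#' Exact Mann-Whitney U test by full enumeration
#'
#' Two-sample rank test designed for the very small group sizes of
#' incubation experiments (3-5 vessels per treatment), where
#' normal-approximation p-values are unreliable. For `n1 + n2 <= 16`
#' (always, at those sizes) the two-sided p-value is computed by full
#' enumeration of all `choose(n1 + n2, n1)` assignments of the pooled
#' observations, which handles ties naturally through average ranks:
#' the observed tie pattern is part of the enumerated multiset. The
#' two-sided p is `2 * min(P(U <= u), P(U >= u))` capped at 1 (no
#' mid-p). Larger samples fall back to the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   enumerates when `n1 + n2 <= 16`.
#' @return An object of class `iptflux_rank_test` with elements
#'   `statistic` (U for `x`), `p_value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8)) # p = 2/70
mann_whitney_exact <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "iptflux_validation_error")
  }
  if (any(!is.finite(c(x, y)))) {
    abort("samples must be finite", class = "iptflux_validation_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  do_exact <- exact %||% (n <= 16)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (do_exact) {
    idx <- combn(n, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p_low <- mean(u_all <= u_obs + tol)
    p_high <- mean(u_all >= u_obs - tol)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(
    list(statistic = u_obs, p_value = p, n1 = n1, n2 = n2, method = method),
    class = "iptflux_rank_test"
  )
}

#' @export
print.iptflux_rank_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test (%s)\nU = %g, n1 = %d, n2 = %d, two-sided p = %.4g\n",
    x$method, x$statistic, x$n1, x$n2, x$p_value
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.iptflux_rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n1 = x$n1, n2 = x$n2, method = x$method)
}

#' @export
glance.iptflux_rank_test <- function(x, ...) tidy(x)

#' Regression slope test for a production time series
#'
#' Ordinary least-squares slope of value vs time with a two-sided t-test
#' of slope = 0; the significance machinery behind every rate gate.
#' Residual-free series resolve to p = 0 (nonzero slope) or p = 1
#' (flat). With fewer than 3 points the p-value is undefined (`NA`).
#'
#' @param data Data frame holding the series.
#' @param time,value Column names (tidy-eval) of time (h) and
#'   concentration; defaults `time_h` and `conc_uM`.
#' @return A one-row tibble: `slope`, `se`, `statistic`, `p.value`, `n`.
#' @export
slope_test <- function(data, time = "time_h", value = "conc_uM") {
  t <- data[[time]]
  y <- data[[value]]
  if (length(t) < 2) {
    abort("need >= 2 points", class = "iptflux_validation_error")
  }
  fit <- fit_slope(t, y)
  tibble(
    slope = fit$slope, se = fit$se,
    statistic = ifelse(fit$se > 0, fit$slope / fit$se, NA_real_),
    p.value = fit$p_value, n = fit$n
  )
}
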