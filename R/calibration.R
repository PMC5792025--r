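# Effect-size calibration: Cohen's f for one-way ANOVA power, and mean
# vectors realizing a target design power.

#' Cohen's effect size for one-way ANOVA power
#'
#' Solves for the effect size `f` such that a balanced one-way ANOVA with
#' `K` groups of `m` patients (total `N = K * m`), tested at level `alpha`,
#' attains the target power. The standard noncentrality convention
#' `lambda = f^2 * N` is used, so the power function is
#' `P(F_{K-1, N-K}(lambda) > q_{1-alpha})` with the singly noncentral F.
#' The root is bracketed and solved to machine precision; the returned `f`
#' reproduces the target power to well below `1e-8`.
#'
#' `f` decreases in both `m` and `K` at fixed `m`: larger trials need
#' smaller standardized effects for the same power.
#'
#' @param K number of groups (>= 2).
#' @param m patients per group (>= 2 so that `N > K`).
#' @param alpha significance level.
#' @param power target power, in `(alpha, 1)`.
#' @return Effect size `f` (> 0 for `power > alpha`).
#' @examples
#' cohens_f(K = 3, m = 4)    # about 1.07
#' @export
cohens_f <- function(K, m, alpha = 0.05, power = 0.8) {
  if (K < 2 || m < 2) stop("need K >= 2 and m >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    stop("need 0 < alpha < power < 1", call. = FALSE)
  N <- K * m
  df1 <- K - 1
  df2 <- N - K
  qcrit <- stats::qf(1 - alpha, df1, df2)
  pw <- function(f) stats::pf(qcrit, df1, df2, ncp = f^2 * N, lower.tail = FALSE)
  upper <- 1
  while (pw(upper) < power) {
    upper <- upper * 2
    if (upper > 1e4) stop("target power unreachable", call. = FALSE)
  }
  stats::uniroot(function(f) pw(f) - power, c(1e-12, upper), tol = 1e-12)$root
}

#' Group-mean vector attaining a target design power
#'
#' Scales a mean-vector shape so that the one-way ANOVA design power (no
#' selection bias) equals the target. For the `"last-arm-only"` pattern,
#' `mu = (0, ..., 0, delta)`, Cohen's f and delta are linked by
#' `f = delta * sqrt(K - 1) / K`; for `"equally-spaced"`,
#' `mu_k = delta * (k - 1)/(K - 1)`. In both cases
#' `f = sd_pop(mu) / sigma` with the population (divide-by-K) standard
#' deviation, so the scale factor is computed in closed form from
#' [cohens_f()].
#'
#' @inheritParams cohens_f
#' @param pattern mean-vector shape.
#' @param sigma residual standard deviation (default 1; `delta` scales
#'   proportionally).
#' @return A list with `delta` (the pattern scale), `mu` (length-`K` mean
#'   vector), `f` (the Cohen's f realized) and `power`.
#' @examples
#' delta_for_power(K = 3, m = 16)$mu
#' @export
delta_for_power <- function(K, m, alpha = 0.05, power = 0.8,
                            pattern = c("last-arm-only", "equally-spaced"),
                            sigma = 1) {
  pattern <- match.arg(pattern)
  f <- cohens_f(K, m, alpha = alpha, power = power)
  shape <- switch(pattern,
    "last-arm-only" = c(rep(0, K - 1), 1),
    "equally-spaced" = (seq_len(K) - 1) / (K - 1)
  )
  unit_f <- sqrt(mean((shape - mean(shape))^2))
  delta <- sigma * f / unit_f
  list(delta = delta, mu = delta * shape, f = f, power = power)
}
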