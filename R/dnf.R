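# Distribution theory: noncentrality parameters of the F statistic under a
# selection-bias shift, the doubly noncentral F CDF, and the exact
# conditional rejection probability r(X).

#' Noncentrality parameters of the F statistic under selection bias
#'
#' Under the shifted outcome model `y = X beta + eta * b + eps` with a true
#' null (equal group means) and `eps ~ N(0, sigma^2 I)`, the one-way ANOVA F
#' statistic follows a doubly noncentral F distribution with `K - 1` and
#' `N - K` degrees of freedom. Writing `n = N / K` for the (balanced) group
#' size, the noncentrality parameters are
#' \deqn{\lambda_1 = \eta^2 \Big(\tfrac{1}{n}\sum_k (b^t x_k)^2 -
#'   \tfrac{1}{N}(b^t 1)^2\Big), \quad
#'   \lambda_2 = \eta^2 \Big(b^t b - \tfrac{1}{n}\sum_k (b^t x_k)^2\Big),}
#' the quadratic forms of `b` in the between-group and residual projection
#' matrices. They always satisfy the conservation identity
#' `lambda1 + lambda2 = eta^2 * (b'b - (b'1)^2 / N)`. `eta` is expressed in
#' units of the residual standard deviation (`sigma = 1` throughout; the F
#' statistic is scale invariant).
#'
#' @param seq integer allocation sequence (balanced; validated).
#' @param design a [pbd_design()] object.
#' @param b bias vector of length `N` (any numeric vector is accepted;
#'   policies produce entries in `{-1, 0, 1}`).
#' @param eta selection effect.
#'
#' @return A list with `lambda1`, `lambda2`, `df1 = K - 1`, `df2 = N - K`.
#' @examples
#' d <- pbd_design(3, c = 2, M = 1)
#' s <- c(1, 2, 1, 3, 3, 2)
#' b <- bias_vector(s, d, biasing_policy("I", 1, K = 3))
#' noncentrality(s, d, b, eta = 1)   # lambda1 = 1, lambda2 = 0.5
#' @export
noncentrality <- function(seq, design, b, eta) {
  stopifnot(inherits(design, "pbd_design"))
  seq <- .validate_sequence(seq, design)
  if (length(b) != design$N)
    stop("'b' must have length N = ", design$N, call. = FALSE)
  b <- as.numeric(b)
  n <- design$N / design$K
  btx <- vapply(seq_len(design$K), function(k) sum(b[seq == k]), numeric(1))
  s2 <- sum(btx^2)
  l1 <- eta^2 * (s2 / n - sum(b)^2 / design$N)
  l2 <- eta^2 * (sum(b^2) - s2 / n)
  # both are quadratic forms in idempotent matrices, nonnegative up to rounding
  list(lambda1 = max(l1, 0), lambda2 = max(l2, 0),
       df1 = design$K - 1L, df2 = design$N - design$K)
}

# Sufficient statistics of b for lambda computation, vectorized over the
# rows of a sequence matrix. eta is applied later so that a single pass
# serves a whole grid of selection effects.
.lambda_parts <- function(seqs, bmat, design) {
  n <- design$N / design$K
  s2 <- 0
  for (k in seq_len(design$K)) s2 <- s2 + rowSums(bmat * (seqs == k))^2
  bt1 <- rowSums(bmat)
  btb <- rowSums(bmat^2)
  list(l1_unit = pmax(s2 / n - bt1^2 / design$N, 0),
       l2_unit = pmax(btb - s2 / n, 0))
}

#' Doubly noncentral F cumulative distribution function
#'
#' `P(F'' <= x)` for `F'' = (chi^2_{df1}(lambda1)/df1) /
#' (chi^2_{df2}(lambda2)/df2)` with independent numerator and denominator.
#' Computed as the double Poisson mixture of regularized incomplete beta
#' functions
#' \deqn{\sum_{j,k} p_j(\lambda_1/2)\, p_k(\lambda_2/2)\,
#'   I_u(df_1/2 + j,\ df_2/2 + k), \quad u = \frac{df_1 x}{df_1 x + df_2},}
#' with `p_j` Poisson weights. The mixture is truncated at Poisson tail
#' quantiles chosen so that the neglected weight mass — and hence the
#' absolute CDF error, every beta factor being at most 1 — is below `tol`.
#'
#' With `lambda1 = lambda2 = 0` this is the central F CDF; with
#' `lambda2 = 0` the singly noncentral F CDF.
#'
#' @param q quantile (vectorized).
#' @param df1,df2 degrees of freedom (>= 1).
#' @param lambda1,lambda2 noncentrality parameters (>= 0).
#' @param tol absolute truncation error bound, default `1e-10`.
#' @param max_terms cap on the number of mixture terms; exceeding it raises
#'   a convergence error rather than returning a silently truncated value.
#'
#' @return Vector of probabilities.
#' @examples
#' pdnf(2, 2, 9, 0, 0) - pf(2, 2, 9)        # 0 (central limit case)
#' pdnf(2, 2, 9, lambda1 = 3, lambda2 = 1.5)
#' @export
pdnf <- function(q, df1, df2, lambda1 = 0, lambda2 = 0,
                 tol = 1e-10, max_terms = 1e6) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0)
    stop("noncentrality parameters must be nonnegative", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  # Poisson index ranges covering all but tol/2 of each weight sequence
  jmax <- stats::qpois(tol / 4, lambda1 / 2, lower.tail = FALSE) + 1L
  kmax <- stats::qpois(tol / 4, lambda2 / 2, lower.tail = FALSE) + 1L
  if ((jmax + 1) * (kmax + 1) > max_terms)
    stop("doubly noncentral F series needs more than 'max_terms' terms at this tolerance",
         call. = FALSE)
  w1 <- stats::dpois(0:jmax, lambda1 / 2)
  w2 <- stats::dpois(0:kmax, lambda2 / 2)
  if (1 - sum(w1) * sum(w2) > tol)
    stop("doubly noncentral F series failed to reach the requested tolerance",
         call. = FALSE)
  a <- df1 / 2 + 0:jmax
  bb <- df2 / 2 + 0:kmax
  arep <- rep(a, times = length(bb))
  brep <- rep(bb, each = length(a))
  vapply(q, function(x) {
    if (!is.finite(x)) return(if (x > 0) 1 else 0)
    if (x <= 0) return(0)
    u <- df1 * x / (df1 * x + df2)
    P <- matrix(stats::pbeta(u, arep, brep), nrow = length(a))
    drop(w1 %*% P %*% w2)
  }, numeric(1))
}

# Memoized batch evaluation of r = P(F'' > qf(1 - alpha)) over vectors of
# lambda pairs. Lambdas from integer-valued bias vectors live on a coarse
# rational grid, so the number of distinct pairs is typically far below the
# number of sequences.
.rejection_from_lambdas <- function(l1, l2, df1, df2, alpha, tol = 1e-10) {
  qcrit <- stats::qf(1 - alpha, df1, df2)
  key <- paste(signif(l1, 12), signif(l2, 12))
  uk <- !duplicated(key)
  r_unique <- mapply(function(a, b) {
    # central case analytically: r = alpha exactly, with no roundoff from
    # inverting the F CDF (keeps the strict inflation indicator honest)
    if (a == 0 && b == 0) return(alpha)
    1 - pdnf(qcrit, df1, df2, a, b, tol = tol)
  }, l1[uk], l2[uk])
  unname(r_unique[match(key, key[uk])])
}

#' Exact conditional type I error probability of the F-test
#'
#' Given a realized randomization sequence `X` and the bias vector `b` of a
#' biasing policy, the probability that the nominal-level one-way ANOVA
#' F-test rejects a *true* null under the shifted model
#' `y = X beta + eta b + eps`:
#' \deqn{r(X) = 1 - F''_{K-1,\,N-K}(\lambda_1, \lambda_2)
#'   \big(F^{-1}_{K-1,\,N-K,\,1-\alpha}\big),}
#' the upper tail of the doubly noncentral F law at the central-F critical
#' value. With `eta = 0` this is exactly `alpha`; values above `alpha` mean
#' the sequence's type I error is inflated by selection bias.
#'
#' @inheritParams noncentrality
#' @param alpha nominal significance level, in (0, 1).
#' @param tol CDF truncation tolerance passed to [pdnf()].
#' @return A single probability `r(X)`.
#' @examples
#' d <- pbd_design(3, c = 2, M = 1)
#' s <- c(1, 2, 1, 3, 3, 2)
#' b <- bias_vector(s, d, biasing_policy("I", 1, K = 3))
#' rejection_probability(s, d, b, eta = 1.07, alpha = 0.05)
#' @export
rejection_probability <- function(seq, design, b, eta, alpha = 0.05,
                                  tol = 1e-10) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  nc <- noncentrality(seq, design, b, eta)
  if (nc$lambda1 == 0 && nc$lambda2 == 0) return(alpha)
  1 - pdnf(stats::qf(1 - alpha, nc$df1, nc$df2), nc$df1, nc$df2,
           nc$lambda1, nc$lambda2, tol = tol)
}
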