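# Biasing policies: models of how an unmasked investigator, favouring a
# subset of arms, shifts the expected response of the patient enrolled next.

#' Specify a biasing policy
#'
#' A biasing policy maps the history of group counts `N_k(i-1)` and a
#' favoured arm set `F` (a non-empty proper subset of `1..K`) to a bias
#' value `b_i` in `{-1, 0, +1}`: the investigator enrols a patient with
#' better (`+1`), neutral (`0`) or worse (`-1`) expected response according
#' to which arm they guess will be allocated next.
#'
#' * **Policy I** (strict): guess a favoured arm only when *all* favoured
#'   arms trail *all* unfavoured arms — `b_i = +1` iff
#'   `max_F N_j(i-1) < min_FC N_k(i-1)`, and `b_i = -1` iff
#'   `min_F N_j(i-1) > max_FC N_k(i-1)`; ties give 0.
#' * **Policy II**: guess a favoured arm as soon as *some* favoured arm
#'   trails all unfavoured arms — `b_i = +1` iff
#'   `min_F N_j(i-1) < min_FC N_k(i-1)`, and (default reading) `b_i = -1`
#'   iff `min_F N_j(i-1) > min_FC N_k(i-1)`. The alternative, stricter
#'   reading of the `-1` branch (`min_F > max_FC`) is available as
#'   `variant = "strict_minus"`; no published worked example discriminates
#'   between the two.
#'
#' Wherever Policy I is nonzero, Policy II (same `F`) takes the same value,
#' so Policy I biases at most as many patients as Policy II.
#'
#' @param kind `"I"` or `"II"`.
#' @param favoured integer vector: the favoured arm set `F`; must be a
#'   non-empty proper subset of `1..K`.
#' @param K number of treatment groups.
#' @param direction `+1` (default) if guessing a favoured arm attracts
#'   patients with *higher* expected response, `-1` for the mirrored
#'   preference; multiplies the bias vector.
#' @param variant Policy II only: `"default"` (min-vs-min comparator) or
#'   `"strict_minus"` (see above). Ignored for Policy I.
#'
#' @return An object of class `biasing_policy`.
#' @examples
#' biasing_policy("I", favoured = 1, K = 3)
#' biasing_policy("II", favoured = c(2, 3), K = 3)
#' @export
biasing_policy <- function(kind = c("I", "II"), favoured, K,
                           direction = 1, variant = c("default", "strict_minus")) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (length(K) != 1L || !is.numeric(K) || K < 2L)
    stop("'K' must be a single integer >= 2", call. = FALSE)
  K <- as.integer(K)
  favoured <- unique(as.integer(favoured))
  if (length(favoured) == 0L || anyNA(favoured) ||
      any(favoured < 1L) || any(favoured > K) || length(favoured) >= K)
    stop("'favoured' must be a non-empty proper subset of 1..K", call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("'direction' must be +1 or -1", call. = FALSE)
  structure(
    list(kind = kind, favoured = sort(favoured),
         not_favoured = setdiff(seq_len(K), favoured),
         K = K, direction = as.integer(direction), variant = variant),
    class = "biasing_policy"
  )
}

#' @export
print.biasing_policy <- function(x, ...) {
  cat(sprintf("Biasing policy %s: K = %d, favoured F = {%s}%s%s\n",
              x$kind, x$K, paste(x$favoured, collapse = ","),
              if (x$direction == -1L) ", direction = -1" else "",
              if (x$kind == "II" && x$variant != "default")
                paste0(", variant = ", x$variant) else ""))
  invisible(x)
}

# Row-wise max/min over a small set of columns without matrixStats.
.row_extreme <- function(counts, cols, fun) {
  out <- counts[, cols[1L]]
  for (j in cols[-1L]) out <- fun(out, counts[, j])
  out
}

# Vectorized core: bias vectors for all rows of an n x N sequence matrix.
# Counts are updated patient by patient; at step i the comparison uses the
# counts *before* patient i (N_k(i-1)), so b[, 1] is always 0.
.bias_matrix <- function(seqs, policy) {
  n <- nrow(seqs); N <- ncol(seqs); K <- policy$K
  Fs <- policy$favoured; Cs <- policy$not_favoured
  counts <- matrix(0L, nrow = n, ncol = K)
  b <- matrix(0L, nrow = n, ncol = N)
  for (i in seq_len(N)) {
    if (i > 1L) {
      minF <- .row_extreme(counts, Fs, pmin)
      minC <- .row_extreme(counts, Cs, pmin)
      if (policy$kind == "I") {
        maxF <- .row_extreme(counts, Fs, pmax)
        maxC <- .row_extreme(counts, Cs, pmax)
        b[, i] <- (maxF < minC) - (minF > maxC)
      } else {
        minus <- if (policy$variant == "strict_minus") {
          maxC <- .row_extreme(counts, Cs, pmax)
          minF > maxC
        } else minF > minC
        b[, i] <- (minF < minC) - minus
      }
    }
    counts[cbind(seq_len(n), seqs[, i])] <- counts[cbind(seq_len(n), seqs[, i])] + 1L
  }
  policy$direction * b
}

#' Bias vector of an allocation sequence under a biasing policy
#'
#' @param seq integer allocation sequence with entries in `1..K`.
#' @param design a [pbd_design()] object; the sequence is validated
#'   against it.
#' @param policy a [biasing_policy()] with matching `K`.
#'
#' @return Integer vector `b` of length `N` with entries in `{-1, 0, +1}`;
#'   `b[1]` is always 0 because all counts are zero before patient 1.
#'
#' @examples
#' d <- pbd_design(3, c = 2, M = 1)
#' bias_vector(c(1, 2, 1, 3, 3, 2), d, biasing_policy("I", 1, K = 3))
#' bias_vector(c(1, 2, 1, 3, 3, 2), d, biasing_policy("II", c(2, 3), K = 3))
#' @export
bias_vector <- function(seq, design, policy) {
  stopifnot(inherits(design, "pbd_design"), inherits(policy, "biasing_policy"))
  if (policy$K != design$K)
    stop("policy K does not match design K", call. = FALSE)
  seq <- .validate_sequence(seq, design)
  drop(.bias_matrix(matrix(seq, nrow = 1L), policy))
}

#' Blackwell-Hodges convergence strategy (two arms)
#'
#' The classic two-arm guessing strategy: guess the arm that has so far been
#' allocated less often. Equivalent to Policy I (and II) with `F = {1}` when
#' `K = 2`; elementwise it equals `sign(N_2(i-1) - N_1(i-1))`.
#'
#' @inheritParams bias_vector
#' @return Integer bias vector.
#' @export
blackwell_hodges_bias <- function(seq, design) {
  stopifnot(inherits(design, "pbd_design"))
  if (design$K != 2L)
    stop("the Blackwell-Hodges strategy is defined for K = 2 arms", call. = FALSE)
  bias_vector(seq, design, biasing_policy("I", favoured = 1L, K = 2L))
}

#' Worked bias-vector table for one sequence
#'
#' Lays out, patient by patient, the allocation indicators `x_1..x_K`, the
#' pre-enrolment counts `N_1(i-1)..N_K(i-1)` and the bias value `b_i` — the
#' layout used in worked examples of biasing policies.
#'
#' @inheritParams bias_vector
#' @return A data frame with columns `patient`, `x_1..x_K`,
#'   `N_1..N_K` (counts before the patient) and `b`.
#' @export
bias_table <- function(seq, design, policy) {
  seq <- .validate_sequence(seq, design)
  b <- bias_vector(seq, design, policy)
  counts <- group_counts(seq, design)
  x <- matrix(0L, nrow = design$N, ncol = design$K)
  x[cbind(seq_len(design$N), seq)] <- 1L
  df <- data.frame(patient = seq_len(design$N), x,
                   counts[seq_len(design$N), , drop = FALSE], b = b)
  names(df) <- c("patient", paste0("x_", seq_len(design$K)),
                 paste0("N_", seq_len(design$K)), "b")
  rownames(df) <- NULL
  df
}
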