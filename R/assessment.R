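# Procedure-level assessment: distribution of the conditional type I error
# r(X) across randomization sequences and the proportion of sequences with
# inflated type I error, by Monte Carlo or exhaustive enumeration.

#' Scenario configuration for a selection-bias assessment
#'
#' Bundles the design, biasing policy, bias magnitude and simulation
#' settings for one assessment scenario. The selection effect defaults to
#' `eta = rho * f` where `f` is Cohen's effect size for a one-way ANOVA
#' with the scenario's `K` and per-group size `m` at level `alpha` and 80%
#' power (see [cohens_f()]); `eta` may also be given directly, in which
#' case `rho` and `f` are ignored.
#'
#' @param K number of treatment groups.
#' @param m patients per group (`N = K * m`).
#' @param scheme block-length scheme: `"PBD_K"` (blocks of length `K`),
#'   `"PBD_N_HALF"` (two blocks of length `N/2`) or `"PBD_N"` (one block,
#'   the random allocation rule).
#' @param policy a [biasing_policy()]; default Policy I favouring arm 1.
#' @param rho bias magnitude as a fraction of the effect size `f`.
#' @param f effect size used to scale `eta`; default
#'   `cohens_f(K, m, alpha, power = 0.8)`.
#' @param eta optional explicit selection effect overriding `rho * f`.
#' @param alpha nominal significance level.
#' @param replicates Monte Carlo sample size (number of sequences).
#' @param seed optional integer seed for reproducible sequence draws.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(K, m, scheme = c("PBD_K", "PBD_N_HALF", "PBD_N"),
                            policy = NULL, rho = 1, f = NULL, eta = NULL,
                            alpha = 0.05, replicates = 10000, seed = NULL) {
  scheme <- match.arg(scheme)
  design <- .design_for_scheme(K, m, scheme)
  if (is.null(policy)) policy <- biasing_policy("I", favoured = 1L, K = K)
  if (!inherits(policy, "biasing_policy") || policy$K != design$K)
    stop("'policy' must be a biasing_policy with matching K", call. = FALSE)
  if (is.null(eta)) {
    if (length(rho) != 1L || rho < 0) stop("'rho' must be a single value >= 0", call. = FALSE)
    if (is.null(f)) f <- if (rho > 0) cohens_f(K, m, alpha = alpha, power = 0.8) else 0
    eta <- rho * f
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be at least 1", call. = FALSE)
  structure(
    list(design = design, scheme = scheme, policy = policy, rho = rho, f = f,
         eta = eta, alpha = alpha, replicates = as.integer(replicates),
         seed = seed),
    class = "scenario_config"
  )
}

# Shared tail: distribution summary + inflation proportion from per-sequence
# rejection probabilities and their (possibly uniform) weights.
.assessment_result <- function(r, prob, alpha, mode) {
  p_infl <- sum(prob * (r > alpha))
  qs <- stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  structure(
    list(rejection_probs = r, probabilities = prob, p_infl = p_infl,
         summary = c(min = qs[1], q1 = qs[2], median = qs[3],
                     mean = sum(prob * r), q3 = qs[4], max = qs[5]),
         alpha = alpha, mode = mode),
    class = "pbd_assessment"
  )
}

#' @export
print.pbd_assessment <- function(x, digits = 4, ...) {
  cat(sprintf("Selection-bias assessment (%s, %d sequences)\n", x$mode,
              length(x$rejection_probs)))
  cat(sprintf("  proportion with r(X) > %.3g: %.*f\n", x$alpha, digits, x$p_infl))
  cat("  r(X): ", paste(sprintf("%s = %.*f", names(x$summary), digits, x$summary),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

# One pass over a sequence matrix: bias vectors, lambda parts, r(X).
.assess_matrix <- function(seqs, prob, cfg, mode) {
  d <- cfg$design
  bmat <- .bias_matrix(seqs, cfg$policy)
  parts <- .lambda_parts(seqs, bmat, d)
  r <- .rejection_from_lambdas(cfg$eta^2 * parts$l1_unit,
                               cfg$eta^2 * parts$l2_unit,
                               d$K - 1L, d$N - d$K, cfg$alpha)
  .assessment_result(r, prob, cfg$alpha, mode)
}

#' Monte Carlo assessment of a randomization procedure
#'
#' Draws `replicates` sequences from the scenario's permuted block design,
#' computes each sequence's bias vector and exact conditional type I error
#' probability `r(X)` (see [rejection_probability()]), and summarizes the
#' distribution together with the proportion of sequences whose type I
#' error exceeds the nominal level (`p_infl`). "Inflated" means strictly
#' `r(X) > alpha`: with `eta = 0` every sequence has `r(X) = alpha` exactly
#' and the proportion is 0.
#'
#' @param cfg a [scenario_config()].
#' @return An object of class `pbd_assessment` with elements
#'   `rejection_probs`, `probabilities` (uniform weights), `p_infl`,
#'   `summary` (min/Q1/median/mean/Q3/max) and `mode = "monte_carlo"`.
#' @examples
#' cfg <- scenario_config(K = 3, m = 4, scheme = "PBD_K", rho = 0.25,
#'                        replicates = 200, seed = 1)
#' assess_monte_carlo(cfg)
#' @export
assess_monte_carlo <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  seqs <- .with_seed(cfg$seed, .generate_pbd_matrix(cfg$design, cfg$replicates))
  .assess_matrix(seqs, rep.int(1 / nrow(seqs), nrow(seqs)), cfg, "monte_carlo")
}

#' Exact assessment by exhaustive enumeration
#'
#' Enumerates the full sequence space of the design (refused above `cap`
#' sequences) and evaluates the probability-weighted inflation proportion
#' `sum_X P(X) * 1{r(X) > alpha}` exactly, along with the exact weighted
#' distribution of `r(X)`.
#'
#' @inheritParams assess_monte_carlo
#' @param cap enumeration cap forwarded to [enumerate_pbd()].
#' @return A `pbd_assessment` with `mode = "exact_enumeration"`.
#' @export
assess_exact <- function(cfg, cap = 1e6) {
  stopifnot(inherits(cfg, "scenario_config"))
  en <- enumerate_pbd(cfg$design, cap = cap)
  .assess_matrix(en$sequences, en$probabilities, cfg, "exact_enumeration")
}

#' Invariance of the inflation proportion in the bias magnitude
#'
#' Evaluates `p_infl` for a common design/policy across several values of
#' `rho` (with `eta = rho * f`) and reports the spread. By default the same
#' sequence sample is reused for every `rho` (only the scaling of the
#' noncentrality parameters changes), isolating the effect of the bias
#' magnitude from sampling noise; set `shared_sequences = FALSE` to redraw.
#'
#' @param K,m,scheme,policy,f,alpha,replicates,seed as in
#'   [scenario_config()].
#' @param rho vector of positive bias fractions.
#' @param shared_sequences reuse one sequence sample across `rho` values.
#' @return A data frame with columns `rho`, `eta`, `p_infl`, `mean_r`;
#'   attribute `max_spread` holds `max(p_infl) - min(p_infl)`.
#' @export
eta_invariance_report <- function(K, m, scheme = c("PBD_K", "PBD_N_HALF", "PBD_N"),
                                  rho = c(0.25, 0.5, 1), policy = NULL,
                                  f = NULL, alpha = 0.05, replicates = 10000,
                                  seed = NULL, shared_sequences = TRUE) {
  scheme <- match.arg(scheme)
  if (any(rho <= 0)) stop("'rho' values must be positive", call. = FALSE)
  base <- scenario_config(K, m, scheme, policy = policy, rho = rho[1L], f = f,
                          alpha = alpha, replicates = replicates, seed = seed)
  d <- base$design
  if (shared_sequences) {
    seqs <- .with_seed(seed, .generate_pbd_matrix(d, base$replicates))
    bmat <- .bias_matrix(seqs, base$policy)
    parts <- .lambda_parts(seqs, bmat, d)
    rows <- lapply(rho, function(rr) {
      eta <- rr * base$f
      r <- .rejection_from_lambdas(eta^2 * parts$l1_unit, eta^2 * parts$l2_unit,
                                   d$K - 1L, d$N - d$K, alpha)
      data.frame(rho = rr, eta = eta, p_infl = mean(r > alpha), mean_r = mean(r))
    })
  } else {
    rows <- lapply(seq_along(rho), function(i) {
      cfg <- scenario_config(K, m, scheme, policy = base$policy, rho = rho[i],
                             f = base$f, alpha = alpha, replicates = replicates,
                             seed = if (is.null(seed)) NULL else seed + i - 1L)
      a <- assess_monte_carlo(cfg)
      data.frame(rho = rho[i], eta = cfg$eta, p_infl = a$p_infl,
                 mean_r = unname(a$summary["mean"]))
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "max_spread") <- max(out$p_infl) - min(out$p_infl)
  out
}
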