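# Permuted block designs: construction, random generation, exhaustive
# enumeration, sequence probabilities and allocation-count trajectories.

#' Permuted block design parameters
#'
#' Defines a balanced permuted block design `PBD(cK)` for a `K`-arm parallel
#' group trial: the patient stream is divided into `M` blocks of length
#' `c * K`, and within each block exactly `c` patients are allocated to each
#' of the `K` arms. The total sample size is `N = c * K * M` and the final
#' per-group size is `m = c * M`. The last block is always complete;
#' incomplete designs are rejected rather than truncated.
#'
#' Two special cases have standard names: `c = 1` gives blocks of length `K`
#' (balance after every K-th patient), and `M = 1` gives the *random
#' allocation rule* RAR = PBD(N), where balance is forced only at the end of
#' the trial.
#'
#' @param K integer number of treatment groups, at least 2.
#' @param c integer number of patients per group within one block, at least 1.
#' @param M integer number of blocks, at least 1.
#'
#' @return An object of class `pbd_design`: a list with elements `K`, `c`,
#'   `M`, `N` (total sample size), `m` (patients per group) and
#'   `block_length` (`c * K`).
#'
#' @examples
#' pbd_design(K = 3, c = 1, M = 4)   # PBD(K) with N = 12
#' pbd_design(K = 3, c = 4, M = 1)   # random allocation rule, N = 12
#' @export
pbd_design <- function(K, c = 1, M = 1) {
  for (nm in c("K", "c", "M")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != as.integer(v))
      stop("'", nm, "' must be a single integer", call. = FALSE)
  }
  K <- as.integer(K); c <- as.integer(c); M <- as.integer(M)
  if (K < 2L) stop("'K' must be at least 2", call. = FALSE)
  if (c < 1L) stop("'c' must be at least 1", call. = FALSE)
  if (M < 1L) stop("'M' must be at least 1", call. = FALSE)
  structure(
    list(K = K, c = c, M = M, N = c * K * M, m = c * M, block_length = c * K),
    class = "pbd_design"
  )
}

#' @export
print.pbd_design <- function(x, ...) {
  cat(sprintf("Permuted block design PBD(%d): K = %d arms, %d block(s) of length %d, N = %d (m = %d per group)\n",
              x$block_length, x$K, x$M, x$block_length, x$N, x$m))
  invisible(x)
}

# Map a block-length scheme label onto concrete design parameters.
# PBD_K: c = 1, M = m; PBD_N_HALF: two blocks of length N/2; PBD_N: RAR.
.design_for_scheme <- function(K, m, scheme) {
  scheme <- match.arg(scheme, c("PBD_K", "PBD_N_HALF", "PBD_N"))
  switch(scheme,
    PBD_K = pbd_design(K, c = 1L, M = m),
    PBD_N_HALF = {
      if (m %% 2L != 0L)
        stop("PBD_N_HALF requires an even per-group size m", call. = FALSE)
      pbd_design(K, c = m %/% 2L, M = 2L)
    },
    PBD_N = pbd_design(K, c = m, M = 1L)
  )
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means: use (and advance) the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
    add = TRUE
  )
  set.seed(seed)
  code
}

# Fast path used by the assessment machinery: n sequences as an n x N
# integer matrix. Each block is an independent uniform permutation of the
# multiset {1,...,1,...,K,...,K} (c copies each), drawn by ranking iid
# uniforms, which is distributionally equivalent to Fisher-Yates.
.generate_pbd_matrix <- function(design, n) {
  base <- rep.int(seq_len(design$K), rep.int(design$c, design$K))
  bl <- design$block_length
  out <- matrix(0L, nrow = n, ncol = design$N)
  for (blk in seq_len(design$M)) {
    cols <- ((blk - 1L) * bl + 1L):(blk * bl)
    keys <- matrix(stats::runif(n * bl), nrow = n, ncol = bl)
    ord <- t(apply(keys, 1L, order))
    out[, cols] <- matrix(base[ord], nrow = n, ncol = bl)
  }
  out
}

#' Generate permuted-block randomization sequences
#'
#' Draws `n` independent allocation sequences from the permuted block design:
#' every block is an independent uniformly random arrangement of `c` copies
#' of each treatment label `1..K`.
#'
#' @param design a [pbd_design()] object.
#' @param n number of sequences to draw.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return For `n = 1` an integer vector of length `N` with entries in
#'   `1..K`; for `n > 1` an `n x N` integer matrix with one sequence per row.
#'
#' @examples
#' d <- pbd_design(3, c = 1, M = 2)
#' generate_pbd(d, seed = 1)
#' @export
generate_pbd <- function(design, n = 1, seed = NULL) {
  stopifnot(inherits(design, "pbd_design"))
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  out <- .with_seed(seed, .generate_pbd_matrix(design, as.integer(n)))
  if (n == 1) out[1L, ] else out
}

# All distinct arrangements of the multiset with `counts[k]` copies of label
# k, as a matrix with one arrangement per row. Recursive lexicographic
# construction; sizes here are tiny by design (enumeration is capped).
.multiset_perms <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  blocks <- lapply(which(counts > 0L), function(k) {
    cnt <- counts
    cnt[k] <- cnt[k] - 1L
    rest <- .multiset_perms(cnt)
    cbind(rep.int(k, nrow(rest)), rest)
  })
  do.call(rbind, blocks)
}

#' Enumerate all sequences of a permuted block design
#'
#' Produces the full sequence space `Omega` of `PBD(cK)` together with the
#' (uniform) sequence probabilities. The number of sequences is
#' `((cK)! / (c!)^K)^M`; enumeration is refused above `cap` because the
#' exhaustive route is intended for small designs only (validation,
#' exact inflation proportions) — use Monte Carlo otherwise.
#'
#' @param design a [pbd_design()] object.
#' @param cap maximum number of sequences to enumerate (default `1e6`).
#'
#' @return A list with `sequences` (matrix, one sequence per row),
#'   `probabilities` (all equal, summing to 1) and `design`.
#'
#' @examples
#' enumerate_pbd(pbd_design(2, c = 1, M = 3))$sequences
#' @export
enumerate_pbd <- function(design, cap = 1e6) {
  stopifnot(inherits(design, "pbd_design"))
  n_block <- exp(lfactorial(design$block_length) - design$K * lfactorial(design$c))
  total <- n_block^design$M
  if (total > cap)
    stop(sprintf(
      "design has %.3g sequences, above the enumeration cap (%.3g); use Monte Carlo (assess_monte_carlo / generate_pbd)",
      total, cap), call. = FALSE)
  block_perms <- .multiset_perms(rep.int(design$c, design$K))
  B <- nrow(block_perms)
  idx <- as.matrix(expand.grid(rep(list(seq_len(B)), design$M)))
  seqs <- do.call(cbind, lapply(seq_len(design$M), function(blk) {
    block_perms[idx[, blk], , drop = FALSE]
  }))
  storage.mode(seqs) <- "integer"
  list(
    sequences = seqs,
    probabilities = rep.int(1 / nrow(seqs), nrow(seqs)),
    design = design
  )
}

# Balance check: within every block each label 1..K appears exactly c times.
.validate_sequence <- function(seq, design, what = "sequence") {
  seq <- as.integer(seq)
  if (length(seq) != design$N)
    stop(sprintf("%s has length %d, expected N = %d", what, length(seq), design$N),
         call. = FALSE)
  if (anyNA(seq) || any(seq < 1L) || any(seq > design$K))
    stop(sprintf("%s has labels outside 1..K", what), call. = FALSE)
  bl <- design$block_length
  for (blk in seq_len(design$M)) {
    tab <- tabulate(seq[((blk - 1L) * bl + 1L):(blk * bl)], nbins = design$K)
    if (any(tab != design$c))
      stop(sprintf("%s violates block balance in block %d", what, blk),
           call. = FALSE)
  }
  seq
}

#' Probability of a permuted-block sequence
#'
#' Every sequence the design can produce is equally likely; its probability
#' is `((c!)^K / (cK)!)^M`, i.e. `1 / |Omega|`. The sequence is validated
#' against the design's block balance before the probability is returned.
#'
#' @inheritParams group_counts
#' @return A single probability.
#' @export
sequence_probability <- function(seq, design) {
  stopifnot(inherits(design, "pbd_design"))
  .validate_sequence(seq, design)
  exp(design$M * (design$K * lfactorial(design$c) - lfactorial(design$block_length)))
}

#' Group-count trajectory of an allocation sequence
#'
#' Running allocation counts `N_k(i)` = number of patients among the first
#' `i` allocated to arm `k`, for `i = 0..N`. Row `i + 1` holds the counts
#' known to an unmasked observer just before patient `i + 1` is enrolled;
#' these are the inputs of the biasing policies.
#'
#' @param seq integer allocation sequence with entries in `1..K`.
#' @param design a [pbd_design()] object.
#' @return An `(N + 1) x K` integer matrix; row `i + 1` is `N_.(i)`.
#' @examples
#' d <- pbd_design(3, c = 2, M = 1)
#' group_counts(c(1, 2, 1, 3, 3, 2), d)
#' @export
group_counts <- function(seq, design) {
  stopifnot(inherits(design, "pbd_design"))
  seq <- .validate_sequence(seq, design)
  counts <- matrix(0L, nrow = design$N + 1L, ncol = design$K)
  ind <- matrix(0L, nrow = design$N, ncol = design$K)
  ind[cbind(seq_len(design$N), seq)] <- 1L
  counts[-1L, ] <- apply(ind, 2L, cumsum)
  dimnames(counts) <- list(paste0("i=", 0:design$N), paste0("N_", seq_len(design$K)))
  counts
}

#' Read allocation sequences from a plain-text file
#'
#' One trial per line, comma-separated treatment labels, e.g.
#' `"1,2,1,3,3,2"`. Every line is validated against the design.
#'
#' @param path file path.
#' @param design a [pbd_design()] object used for validation.
#' @return An integer matrix with one sequence per row.
#' @export
read_sequences <- function(path, design) {
  stopifnot(inherits(design, "pbd_design"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences found in ", path, call. = FALSE)
  seqs <- t(vapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[[i]]), ",")[[1L]]))
    if (anyNA(v)) stop("line ", i, ": non-integer treatment label", call. = FALSE)
    .validate_sequence(v, design, what = paste0("line ", i))
  }, integer(design$N)))
  seqs
}

#' Write allocation sequences as long-format CSV
#'
#' Columns `seq_id`, `position`, `treatment`, one row per allocation.
#'
#' @param seqs integer vector (one sequence) or matrix (one per row).
#' @param path output file path.
#' @return Invisibly, the data frame written.
#' @export
write_sequences <- function(seqs, path) {
  if (is.vector(seqs)) seqs <- matrix(seqs, nrow = 1L)
  df <- data.frame(
    seq_id = rep(seq_len(nrow(seqs)), each = ncol(seqs)),
    position = rep(seq_len(ncol(seqs)), times = nrow(seqs)),
    treatment = as.integer(t(seqs))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
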