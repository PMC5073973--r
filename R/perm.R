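# Adaptive permutation machinery. One seeded stream of sample-label
# permutations is shared by every statistic computed on a dataset, so that
# all p-values (expression, methylation, combined, feature-level) are
# computed from the same set of permutations regardless of where each
# statistic stops early. Permutations are generated in fixed-size blocks
# whose seeds derive from (stream seed, block index): permutation b is
# addressable by regenerating its block only, independent of any
# statistic's stopping point.

PERM_BLOCK <- 512L

#' Permutation engine configuration
#'
#' @param B0 Early-stopping exceedance target (default 100).
#' @param B1 Maximum number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `PermutationConfig`.
#' @export
permutation_config <- function(B0 = 100L, B1 = 10000L, seed = 1L) {
  B0 <- as.integer(B0); B1 <- as.integer(B1)
  if (B0 < 1L || B1 < 1L || B0 > B1)
    stop("need 1 <= B0 <= B1")
  structure(list(B0 = B0, B1 = B1, seed = as.integer(seed)),
            class = "PermutationConfig")
}

block_seed <- function(seed, block) {
  as.integer((abs(as.numeric(seed)) * 48271 + block * 16807) %%
               2147483647)
}

#' Reproducible stream of sample-label permutations
#'
#' Returns a stream object whose b-th permutation depends only on
#' `(seed, n, b)`. All statistics evaluated on one dataset should share
#' one stream so their p-values come from the same set of permutations.
#'
#' @param seed Integer seed.
#' @param n Number of sample labels (>= 2).
#' @param B1 Upper bound on permutations the stream will be asked for.
#' @return An object of class `PermutationStream` with function
#'   `$get(from, to)` returning an `n x (to - from + 1)` matrix whose
#'   columns are permutations `from, ..., to`.
#' @export
permutation_stream <- function(seed, n, B1 = 10000L) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  get_block <- function(i) {
    old <- if (exists(".Random.seed", globalenv()))
      base::get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(block_seed(seed, i))
    # one radix sort of random keys yields the whole block of independent
    # uniform permutations (column-wise order of iid keys)
    u <- stats::runif(n * PERM_BLOCK)
    g <- rep.int(seq_len(PERM_BLOCK), rep.int(n, PERM_BLOCK))
    o <- order(g, u)
    P <- as.integer(o - (g - 1L) * n)
    dim(P) <- c(n, PERM_BLOCK)
    P
  }
  cache <- new.env(parent = emptyenv())
  get <- function(from, to) {
    stopifnot(from >= 1L, to >= from)
    b_lo <- (from - 1L) %/% PERM_BLOCK + 1L
    b_hi <- (to - 1L) %/% PERM_BLOCK + 1L
    blocks <- lapply(b_lo:b_hi, function(i) {
      key <- as.character(i)
      if (is.null(cache[[key]])) {
        # keep at most two blocks cached
        if (length(ls(cache)) >= 2L) rm(list = ls(cache)[1L], envir = cache)
        cache[[key]] <- get_block(i)
      }
      cache[[key]]
    })
    all <- do.call(cbind, blocks)
    off <- (b_lo - 1L) * PERM_BLOCK
    all[, (from - off):(to - off), drop = FALSE]
  }
  structure(list(seed = as.integer(seed), n = n, B1 = as.integer(B1),
                 get = get),
            class = "PermutationStream")
}

#' Stream that enumerates all permutations in a fixed order
#'
#' A drop-in replacement for [permutation_stream()] that walks through all
#' `n!` permutations exactly once (lexicographic order); used to check
#' that the adaptive procedure with `B1 = n!` reproduces the exact
#' enumeration p-value.
#'
#' @param n Number of labels, `n <= 8`.
#' @return A `PermutationStream` whose b-th column is the b-th
#'   permutation in lexicographic order.
#' @export
enumeration_stream <- function(n) {
  if (n > 8L) stop("refusing to enumerate permutations for n > 8")
  P <- t(all_permutations(n))
  structure(list(seed = NA_integer_, n = as.integer(n),
                 B1 = ncol(P),
                 get = function(from, to) P[, from:to, drop = FALSE]),
            class = "PermutationStream")
}

# all n! permutations of 1..n, one per row, lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

perm_result <- function(count, performed, B0, B1) {
  stopped <- count >= B0 && performed < B1
  structure(list(p = max(1L, count) / performed,
                 exceed_count = as.integer(count),
                 performed = as.integer(performed),
                 stopped_early = stopped),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: p = %.4g (%d/%d%s)\n", x$p,
              x$exceed_count, x$performed,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

exceed_tol <- function(t0) 1e-12 * (1 + abs(t0))

#' Adaptive permutation p-value with early stopping
#'
#' Walks the permutation stream counting permutations whose statistic
#' magnitude is at least that of the observed statistic, and stops as soon
#' as `B0` exceedances are seen or `B1` permutations are performed. The
#' p-value is the proportion of performed permutations that exceed:
#' for example, reaching `B0 = 100` exceedances at permutation 200 stops
#' with p = 100/200 = 0.50. When no permutation exceeds (possible only for
#' an extreme observed statistic) the exceedance count is floored at 1, so
#' p is never below `1/B1`.
#'
#' @param t0 Observed statistic (finite).
#' @param stat_fun Function `(P, b_idx)` receiving a matrix of
#'   permutations (one per column) and their indices, returning the
#'   permuted statistics as a numeric vector.
#' @param cfg A [permutation_config()].
#' @param n Number of sample labels (ignored when `stream` is given).
#' @param stream Optional [permutation_stream()] to share across
#'   statistics; defaults to a fresh stream seeded from `cfg$seed`.
#' @return A `PermutationResult`: `p`, `exceed_count`, `performed`,
#'   `stopped_early`.
#' @export
adaptive_pvalue <- function(t0, stat_fun, cfg, n = NULL, stream = NULL) {
  stopifnot(inherits(cfg, "PermutationConfig"), is.finite(t0))
  if (is.null(stream)) {
    if (is.null(n)) stop("supply n or a stream")
    stream <- permutation_stream(cfg$seed, n, cfg$B1)
  }
  thr <- abs(t0) - exceed_tol(t0)
  count <- 0L; b <- 0L
  while (b < cfg$B1) {
    to <- min(b + PERM_BLOCK, cfg$B1)
    idx <- (b + 1L):to
    tb <- stat_fun(stream$get(b + 1L, to), idx)
    ex <- abs(tb) >= thr
    cum <- count + cumsum(ex)
    hit <- which(cum >= cfg$B0)
    if (length(hit)) {
      return(perm_result(cfg$B0, b + hit[1L], cfg$B0, cfg$B1))
    }
    count <- cum[length(cum)]
    b <- to
  }
  perm_result(count, cfg$B1, cfg$B0, cfg$B1)
}

#' Exact permutation p-value by full enumeration
#'
#' Enumerates all `n!` permutations (n <= 8) and applies the same
#' magnitude-exceedance proportion definition as [adaptive_pvalue()];
#' serves as the small-n reference for the adaptive procedure.
#'
#' @param t0 Observed statistic.
#' @param stat_fun Function taking a single permutation (integer vector)
#'   and returning the permuted statistic.
#' @param n Number of labels, `n <= 8`.
#' @return The exact p-value.
#' @export
exact_reference_pvalue <- function(t0, stat_fun, n) {
  if (n > 8L) stop("refusing to enumerate permutations for n > 8")
  P <- all_permutations(n)
  tb <- apply(P, 1L, stat_fun)
  mean(abs(tb) >= abs(t0) - exceed_tol(t0))
}

# Joint adaptive p-values for S statistics sharing one stream.
# batch_fun(P, b_idx) must return an S x ncol(P) matrix of permuted
# statistics. Each statistic stops by its own rule; results are identical
# to running adaptive_pvalue per statistic on the same stream.
adaptive_pvalues_multi <- function(t0s, batch_fun, cfg, stream) {
  S <- length(t0s)
  thr <- abs(t0s) - vapply(t0s, exceed_tol, numeric(1))
  count <- integer(S)
  res <- vector("list", S)
  active <- rep(TRUE, S)
  b <- 0L
  while (b < cfg$B1 && any(active)) {
    to <- min(b + PERM_BLOCK, cfg$B1)
    idx <- (b + 1L):to
    tb <- batch_fun(stream$get(b + 1L, to), idx)  # S x B
    for (s in which(active)) {
      cum <- count[s] + cumsum(abs(tb[s, ]) >= thr[s])
      hit <- which(cum >= cfg$B0)
      if (length(hit)) {
        res[[s]] <- perm_result(cfg$B0, b + hit[1L], cfg$B0, cfg$B1)
        active[s] <- FALSE
      } else {
        count[s] <- cum[length(cum)]
      }
    }
    b <- to
  }
  for (s in which(active))
    res[[s]] <- perm_result(count[s], cfg$B1, cfg$B0, cfg$B1)
  res
}
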