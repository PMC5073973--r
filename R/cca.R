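#' Per-gene canonical correlation analysis
#'
#' Computes the first canonical correlation between two data blocks for one
#' gene: an expression block `X` (samples x features) and a methylation
#' block `M` (samples x markers). Columns are standardized, each block is
#' whitened through its singular value decomposition with rank truncation
#' at relative tolerance `tol` (pseudoinverse behaviour, so markers may
#' outnumber samples), and the leading singular value of the whitened
#' cross-covariance is the canonical correlation. Per-sample canonical
#' scores are scaled to unit sample variance. Significance of the
#' hypothesis that all canonical correlations are zero is assessed with
#' Bartlett's chi-square approximation to Wilks' Lambda over the retained
#' ranks.
#'
#' @param X Numeric matrix, n samples x F expression features.
#' @param M Numeric matrix, n samples x L methylation markers.
#' @param tol Relative singular value tolerance for rank truncation.
#' @return An object of class `CCAResult`: `r_cc` (in \[0, 1\]),
#'   `expr_weights`, `meth_weights` (combination weights on the
#'   standardized retained columns, `NA` for dropped constant columns),
#'   `expr_scores`, `meth_scores` (length n, unit sample variance),
#'   `p_cc`, `effective_rank` (retained ranks of the two blocks),
#'   `combine_sign` (sign multiplier for the gene-level combined
#'   statistic; +1 after [orient_scores()]).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2); M <- matrix(rnorm(60), 20, 3)
#' fit <- fit_cca(X, M)
#' fit$r_cc
#' @export
fit_cca <- function(X, M, tol = 1e-8) {
  X <- as.matrix(X); M <- as.matrix(M)
  n <- nrow(X)
  if (nrow(M) != n) stop("X and M must have the same number of rows")
  if (n < 4L) stop("at least 4 samples are required for CCA")
  if (anyNA(X) || anyNA(M))
    stop("CCA requires complete matrices; drop incomplete features first")

  prep <- function(A, label) {
    keep <- which(apply(A, 2L, stats::var) > 1e-12)
    if (length(keep) == 0L)
      stop("degenerate gene: all ", label, " columns are constant")
    As <- scale(A[, keep, drop = FALSE])
    sv <- svd(As)
    r <- sum(sv$d > tol * sv$d[1L])
    list(keep = keep, std = As, u = sv$u[, seq_len(r), drop = FALSE],
         d = sv$d[seq_len(r)], v = sv$v[, seq_len(r), drop = FALSE],
         rank = r, p_all = ncol(A))
  }
  px <- prep(X, "expression"); pm <- prep(M, "methylation")

  cc <- svd(crossprod(px$u, pm$u))
  d <- pmin(pmax(cc$d, 0), 1)
  r_cc <- d[1L]

  # scores: left/right singular vectors mapped back to sample space;
  # columns of u are orthonormal and zero-mean, so * sqrt(n-1) gives unit
  # sample variance
  xs <- drop(px$u %*% cc$u[, 1L]) * sqrt(n - 1)
  ms <- drop(pm$u %*% cc$v[, 1L]) * sqrt(n - 1)

  wts <- function(p, vec) {
    w <- rep(NA_real_, p$p_all)
    w[p$keep] <- drop(p$v %*% (vec / p$d)) * sqrt(n - 1)
    w
  }

  k <- length(d)
  lam <- pmax(1 - d[seq_len(k)]^2, 1e-300)
  stat <- -(n - 1 - (px$rank + pm$rank + 1) / 2) * sum(log(lam))
  p_cc <- max(stats::pchisq(stat, df = px$rank * pm$rank,
                            lower.tail = FALSE),
              .Machine$double.xmin)

  structure(list(r_cc = r_cc,
                 expr_weights = wts(px, cc$u[, 1L]),
                 meth_weights = wts(pm, cc$v[, 1L]),
                 expr_scores = xs, meth_scores = ms,
                 p_cc = p_cc,
                 effective_rank = c(expr = px$rank, meth = pm$rank),
                 combine_sign = NA_real_),
            class = "CCAResult")
}

#' @export
print.CCAResult <- function(x, ...) {
  cat(sprintf("CCAResult: r_cc = %.4f, p_cc = %.3g, ranks (%d, %d)%s\n",
              x$r_cc, x$p_cc, x$effective_rank[1L], x$effective_rank[2L],
              if (is.na(x$combine_sign)) " [unoriented]" else ""))
  invisible(x)
}

#' Resolve the sign ambiguity of canonical scores
#'
#' Canonical score vectors are defined only up to a joint sign flip. This
#' canonical form flips the expression scores, if needed, so that their
#' correlation with the mean of the standardized expression columns is
#' non-negative (exact zero: no flip), then flips the methylation scores,
#' if needed, so that the two score vectors correlate non-negatively.
#' After orientation the sign multiplier entering the gene-level combined
#' statistic is +1 (`combine_sign`).
#'
#' @param result A `CCAResult` from [fit_cca()].
#' @param X The expression matrix the result was fitted on.
#' @return The oriented `CCAResult`.
#' @export
orient_scores <- function(result, X) {
  stopifnot(inherits(result, "CCAResult"))
  X <- as.matrix(X)
  keep <- which(apply(X, 2L, stats::var) > 1e-12)
  mref <- rowMeans(scale(X[, keep, drop = FALSE]))
  c1 <- if (stats::sd(mref) == 0) 0 else
    stats::cor(result$expr_scores, mref)
  if (!is.na(c1) && c1 < 0) {
    result$expr_scores <- -result$expr_scores
    result$expr_weights <- -result$expr_weights
  }
  c2 <- stats::cor(result$expr_scores, result$meth_scores)
  if (!is.na(c2) && c2 < 0) {
    result$meth_scores <- -result$meth_scores
    result$meth_weights <- -result$meth_weights
  }
  result$combine_sign <- 1
  result
}
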