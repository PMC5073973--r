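#' Build the most-interesting-evidence direction
#'
#' The composite statistic projects the vector of per-endpoint association
#' statistics onto a predefined direction lambda whose entries are +/-1
#' (up to an optional 1/K scaling). By symmetry the first entry is
#' constrained to +1, so the direction is
#' `lambda_k = direction_sign_k / direction_sign_1`. With
#' `normalized = TRUE` (the default) each entry is divided by K, keeping
#' the projected statistic on a correlation-like scale (|t| <= 1 for a
#' single-source statistic); permutation p-values are invariant to this
#' scaling.
#'
#' @param endpoints A list of [endpoint_spec()] objects or an
#'   [endpoint_table()].
#' @param normalized Divide entries by K? Default `TRUE`.
#' @return An object of class `EvidenceDirection`: `lambdas`,
#'   `normalized`, `endpoint_names`.
#' @examples
#' sp <- list(endpoint_spec("a", "quantitative", 1),
#'            endpoint_spec("b", "quantitative", -1))
#' build_evidence_vector(sp, normalized = FALSE)$lambdas # c(1, -1)
#' @export
build_evidence_vector <- function(endpoints, normalized = TRUE) {
  if (inherits(endpoints, "EndpointTable")) endpoints <- endpoints$endpoints
  if (length(endpoints) < 1L) stop("at least one endpoint is required")
  signs <- vapply(endpoints, `[[`, numeric(1), "direction_sign")
  lam <- signs / signs[1L]
  K <- length(lam)
  if (normalized) lam <- lam / K
  structure(list(lambdas = lam, normalized = normalized,
                 endpoint_names = vapply(endpoints, `[[`, character(1),
                                         "name")),
            class = "EvidenceDirection")
}

#' Project association statistics onto the evidence direction
#'
#' The composite statistic `t = sum_k lambda_k a_k`: the magnitude
#' measures how strongly the observed endpoint associations align with the
#' predefined most interesting evidence, the sign gives the direction of
#' that alignment. Missing entries of `a` contribute 0 (no evidence), with
#' a warning.
#'
#' @param a Numeric vector of per-endpoint association statistics on the
#'   correlation-like scale (length K; entries in \[-1, 1\] or `NA`).
#' @param lambda An `EvidenceDirection` from [build_evidence_vector()].
#' @param kind One of `"expression"`, `"methylation"`, `"combined"`
#'   (bookkeeping only).
#' @return An object of class `PromiseStat`: `t`, `kind`, `components`
#'   (the `a` vector and lambda used).
#' @export
promise_stat <- function(a, lambda, kind = c("expression", "methylation",
                                             "combined")) {
  kind <- match.arg(kind)
  stopifnot(inherits(lambda, "EvidenceDirection"))
  if (length(a) != length(lambda$lambdas))
    stop("a and lambda have different lengths")
  if (anyNA(a)) {
    warning(sum(is.na(a)), " missing association statistic(s) contribute",
            " zero evidence")
    a[is.na(a)] <- 0
  }
  structure(list(t = sum(lambda$lambdas * a), kind = kind,
                 components = list(a = a, lambda = lambda,
                                   sign_multiplier = NA_real_)),
            class = "PromiseStat")
}

#' Combine expression and methylation projection statistics
#'
#' The pair-level combined statistic `t* = t_expr + sign(r) t_meth`,
#' where `r` is the methylation-expression correlation of the pair (at
#' gene level, the post-orientation canonical score correlation, so
#' sign(r) = +1). `sign(0) = 0`: with exactly uncorrelated blocks the
#' methylation term carries no directional information and is dropped.
#'
#' @param t_expr,t_meth `PromiseStat` objects computed against the same
#'   evidence direction.
#' @param r The methylation-expression correlation of the pair.
#' @return A `PromiseStat` of kind `"combined"`.
#' @export
combined_stat <- function(t_expr, t_meth, r) {
  stopifnot(inherits(t_expr, "PromiseStat"),
            inherits(t_meth, "PromiseStat"))
  la <- t_expr$components$lambda; lb <- t_meth$components$lambda
  if (!isTRUE(all.equal(la$lambdas, lb$lambdas)) ||
      la$normalized != lb$normalized)
    stop("t_expr and t_meth were computed against different",
         " evidence directions")
  s <- sign(r)
  structure(list(t = t_expr$t + s * t_meth$t, kind = "combined",
                 components = list(a = list(expr = t_expr$components$a,
                                            meth = t_meth$components$a),
                                   lambda = la, sign_multiplier = s)),
            class = "PromiseStat")
}

#' @export
print.PromiseStat <- function(x, ...) {
  cat(sprintf("PromiseStat (%s): t = %.4f\n", x$kind, x$t))
  invisible(x)
}
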