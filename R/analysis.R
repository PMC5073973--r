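# Per-gene orchestration: complete CC-PROMISE (CCPR), feature-level
# expression/methylation PROMISE, and the unadjusted / Bonferroni / overlap
# gene summaries. All p-values for one dataset come from one shared
# permutation stream.
#
# Under endpoint permutation the molecular data are untouched, so the
# canonical weights and scores -- functions of the molecular data only --
# are permutation-invariant: the CCA is fitted once and only the
# endpoint-to-sample assignment moves.

# centered ranks scaled to unit norm, so crossprod() of two such vectors
# is their Spearman correlation
unit_ranks <- function(v) {
  r <- rank(v, ties.method = "average")
  z <- r - mean(r)
  s <- sqrt(sum(z^2))
  if (s == 0) stop("undefined statistic: constant vector")
  z / s
}

# endpoint evidence matrix for the batched path: column k is the
# unit-norm centered rank vector of endpoint k's evidence score times its
# direction sign. Requires complete endpoint data.
endpoint_rank_matrix <- function(endpoints) {
  cols <- lapply(seq_along(endpoints$endpoints), function(k) {
    sp <- endpoints$endpoints[[k]]
    z <- endpoint_score(sp, endpoints$values[[k]])
    unit_ranks(z) * sp$direction_sign
  })
  do.call(cbind, cols)
}

endpoints_complete <- function(endpoints) {
  !anyNA(unlist(endpoints$values, use.names = FALSE))
}

# Fast shared-stream adaptive p-values for the statistics defined by the
# columns of Z (n x S unit-rank molecular vectors). Optionally appends a
# combined statistic t[i] + sign * t[j].
promise_perm_fast <- function(Z, Yz, lambdas, cfg, stream,
                              combine = NULL) {
  t0 <- drop(crossprod(Z, Yz) %*% lambdas)
  if (!is.null(combine))
    t0 <- c(t0, t0[combine$i] + combine$sign * t0[combine$j])
  n <- nrow(Z)
  batch_fun <- function(P, idx) {
    B <- ncol(P)
    Tt <- matrix(0, ncol(Z), B)
    for (k in seq_along(lambdas)) {
      Yp <- Yz[, k][P]
      dim(Yp) <- c(n, B)
      Tt <- Tt + lambdas[k] * crossprod(Z, Yp)
    }
    if (!is.null(combine))
      Tt <- rbind(Tt, Tt[combine$i, ] + combine$sign * Tt[combine$j, ])
    Tt
  }
  list(t0 = t0,
       results = adaptive_pvalues_multi(t0, batch_fun, cfg, stream))
}

# General path tolerating missing endpoint or molecular values: each
# permuted statistic is recomputed through endpoint_assoc_vector with
# pairwise-complete cases. Much slower; used only when data are
# incomplete.
promise_perm_slow <- function(feats, endpoints, lambda, cfg, stream,
                              combine = NULL) {
  stat_vec <- function(ep) {
    vapply(feats, function(f) {
      a <- suppressWarnings(endpoint_assoc_vector(f, ep)$value)
      a[is.na(a)] <- 0
      sum(lambda$lambdas * a)
    }, numeric(1))
  }
  t0 <- stat_vec(endpoints)
  if (!is.null(combine))
    t0 <- c(t0, t0[combine$i] + combine$sign * t0[combine$j])
  batch_fun <- function(P, idx) {
    Tt <- vapply(seq_len(ncol(P)), function(j)
      stat_vec(subset_endpoints(endpoints, P[, j])),
      numeric(length(feats)))
    Tt <- matrix(Tt, nrow = length(feats))
    if (!is.null(combine))
      Tt <- rbind(Tt, Tt[combine$i, ] + combine$sign * Tt[combine$j, ])
    Tt
  }
  list(t0 = t0,
       results = adaptive_pvalues_multi(t0, batch_fun, cfg, stream))
}

#' Complete CC-PROMISE analysis for one gene
#'
#' Fits and orients the canonical correlation of the gene's expression and
#' methylation blocks, projects the endpoint associations of the two
#' canonical score vectors onto the evidence direction, combines them with
#' the post-orientation sign (+1), and computes the three adaptive
#' permutation p-values from one shared stream. Scores are functions of
#' the molecular data only, so the CCA is not refitted under endpoint
#' permutation.
#'
#' @param X Numeric matrix, n samples x F expression features.
#' @param M Numeric matrix, n samples x L methylation markers.
#' @param endpoints An [endpoint_table()] aligned to the rows of `X`.
#' @param lambda An [build_evidence_vector()] direction.
#' @param perm_cfg A [permutation_config()].
#' @param stream Optional shared [permutation_stream()].
#' @return List with `t_expr`, `p_expr`, `t_meth`, `p_meth`,
#'   `t_combined`, `p_combined`, `cca` (the oriented `CCAResult`), and
#'   `perm` (the three `PermutationResult`s).
#' @export
ccpr_gene <- function(X, M, endpoints, lambda, perm_cfg, stream = NULL) {
  fit <- orient_scores(fit_cca(X, M), X)
  if (is.null(stream))
    stream <- permutation_stream(perm_cfg$seed, nrow(as.matrix(X)),
                                 perm_cfg$B1)
  s_comb <- sign(fit$r_cc)  # post-orientation score correlation >= 0
  if (endpoints_complete(endpoints)) {
    Z <- cbind(unit_ranks(fit$expr_scores), unit_ranks(fit$meth_scores))
    Yz <- endpoint_rank_matrix(endpoints)
    pe <- promise_perm_fast(Z, Yz, lambda$lambdas, perm_cfg, stream,
                            combine = list(i = 1L, j = 2L, sign = s_comb))
  } else {
    pe <- promise_perm_slow(list(fit$expr_scores, fit$meth_scores),
                            endpoints, lambda, perm_cfg, stream,
                            combine = list(i = 1L, j = 2L, sign = s_comb))
  }
  list(t_expr = pe$t0[1L], p_expr = pe$results[[1L]]$p,
       t_meth = pe$t0[2L], p_meth = pe$results[[2L]]$p,
       t_combined = pe$t0[3L], p_combined = pe$results[[3L]]$p,
       cca = fit, perm = pe$results)
}

#' Feature- or marker-level PROMISE analysis
#'
#' Projects each feature's endpoint association vector onto the evidence
#' direction and computes per-feature adaptive permutation p-values from
#' the shared stream.
#'
#' @param features Numeric matrix, n samples x J features.
#' @param endpoints An [endpoint_table()].
#' @param lambda An [build_evidence_vector()] direction.
#' @param perm_cfg A [permutation_config()].
#' @param stream Optional shared [permutation_stream()].
#' @return Data frame with one row per feature: `feature`, `t`, `p`,
#'   `exceed_count`, `performed`.
#' @export
feature_promise <- function(features, endpoints, lambda, perm_cfg,
                            stream = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("at least one feature is required")
  if (is.null(stream))
    stream <- permutation_stream(perm_cfg$seed, nrow(features),
                                 perm_cfg$B1)
  if (endpoints_complete(endpoints) && !anyNA(features)) {
    Z <- apply(features, 2L, unit_ranks)
    pe <- promise_perm_fast(Z, endpoint_rank_matrix(endpoints),
                            lambda$lambdas, perm_cfg, stream)
  } else {
    pe <- promise_perm_slow(lapply(seq_len(ncol(features)), function(j)
      features[, j]), endpoints, lambda, perm_cfg, stream)
  }
  data.frame(
    feature = colnames(features) %||% paste0("f", seq_len(ncol(features))),
    t = pe$t0,
    p = vapply(pe$results, `[[`, numeric(1), "p"),
    exceed_count = vapply(pe$results, `[[`, numeric(1), "exceed_count"),
    performed = vapply(pe$results, `[[`, numeric(1), "performed"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene summaries of feature-level p-values
#'
#' `summarize_unadjusted()` is the minimum p-value over a gene's features;
#' `summarize_bonferroni()` is the minimum Bonferroni-adjusted p-value,
#' `min_j min(1, J p_j)`; `overlap_p()` is the overlap rule, the maximum
#' of the two single-source gene summaries.
#'
#' @param p_values Non-empty numeric vector of p-values.
#' @return A single p-value.
#' @export
summarize_unadjusted <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  min(p_values)
}

#' @rdname summarize_unadjusted
#' @export
summarize_bonferroni <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  min(pmin(1, length(p_values) * p_values))
}

#' @rdname summarize_unadjusted
#' @param p_a,p_b The two single-source gene summary p-values.
#' @export
overlap_p <- function(p_a, p_b) {
  stopifnot(p_a > 0, p_a <= 1, p_b > 0, p_b <= 1)
  max(p_a, p_b)
}

#' Run the full per-gene analysis over a dataset
#'
#' For every mapped gene: complete CC-PROMISE (canonical scores + combined
#' projection statistic), feature-level expression and methylation PROMISE
#' with unadjusted (min p) and Bonferroni-adjusted gene summaries, and the
#' two overlap rules. Features with any missing value are dropped from a
#' gene's CCA (complete case per gene); genes whose CCA is degenerate are
#' reported as skipped, never dropped silently. One permutation stream,
#' seeded from `perm_cfg$seed`, is shared by every statistic of every
#' gene.
#'
#' @param dataset An `AlignedDataset` from [align_dataset()].
#' @param gene_maps A list of [gene_feature_map()]s (or a single one).
#' @param lambda An [build_evidence_vector()] direction.
#' @param perm_cfg A [permutation_config()].
#' @return Data frame with one row per analysed gene (`gene_id`, counts,
#'   `r_cc`, `p_cc`, the three CC-PROMISE statistics and p-values, and the
#'   `uxpr`/`axpr`/`umpr`/`ampr`/`uov`/`aov` summaries). Attributes:
#'   `skipped` (data frame of skipped genes with reasons) and
#'   `feature_tables` (per-gene feature-level results).
#' @export
run_study <- function(dataset, gene_maps, lambda, perm_cfg) {
  stopifnot(inherits(dataset, "AlignedDataset"))
  val <- validate_gene_map(gene_maps, dataset$meth, dataset$expr)
  skipped <- val$skipped
  n <- length(dataset$meth$sample_ids)
  stream <- permutation_stream(perm_cfg$seed, n, perm_cfg$B1)
  rows <- list(); ftabs <- list()
  for (gm in val$maps) {
    Xg <- t(dataset$expr$values[gm$expr_feature_ids, , drop = FALSE])
    Mg <- t(dataset$meth$values[gm$meth_feature_ids, , drop = FALSE])
    Xg <- Xg[, colSums(is.na(Xg)) == 0L, drop = FALSE]
    Mg <- Mg[, colSums(is.na(Mg)) == 0L, drop = FALSE]
    if (ncol(Xg) == 0L || ncol(Mg) == 0L) {
      skipped <- rbind(skipped, data.frame(
        gene_id = gm$gene_id, reason = "no complete features",
        stringsAsFactors = FALSE))
      next
    }
    res <- tryCatch({
      cc <- ccpr_gene(Xg, Mg, dataset$endpoints, lambda, perm_cfg,
                      stream)
      fx <- feature_promise(Xg, dataset$endpoints, lambda, perm_cfg,
                            stream)
      fm <- feature_promise(Mg, dataset$endpoints, lambda, perm_cfg,
                            stream)
      uxpr <- summarize_unadjusted(fx$p)
      axpr <- summarize_bonferroni(fx$p)
      umpr <- summarize_unadjusted(fm$p)
      ampr <- summarize_bonferroni(fm$p)
      list(row = data.frame(
        gene_id = gm$gene_id, n_expr = ncol(Xg), n_meth = ncol(Mg),
        r_cc = cc$cca$r_cc, p_cc = cc$cca$p_cc,
        t_expr = cc$t_expr, p_expr = cc$p_expr,
        t_meth = cc$t_meth, p_meth = cc$p_meth,
        t_combined = cc$t_combined, p_combined = cc$p_combined,
        uxpr = uxpr, axpr = axpr, umpr = umpr, ampr = ampr,
        uov = overlap_p(uxpr, umpr), aov = overlap_p(axpr, ampr),
        stringsAsFactors = FALSE),
        ftab = list(expression = fx, methylation = fm))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- rbind(skipped, data.frame(
        gene_id = gm$gene_id, reason = res, stringsAsFactors = FALSE))
    } else {
      rows[[gm$gene_id]] <- res$row
      ftabs[[gm$gene_id]] <- res$ftab
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "feature_tables") <- ftabs
  out
}
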