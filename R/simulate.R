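# Simulation framework: single-gene two-omics data generator, the seven
# analysis strategies (CCPR, UXPR, AXPR, UMPR, AMPR, UOV, AOV), and
# rejection-rate estimation over replicated settings.

SIM_METHODS <- c("CCPR", "UXPR", "AXPR", "UMPR", "AMPR", "UOV", "AOV")

#' Define one simulation setting
#'
#' One gene with `n_markers` methylation markers and `n_expr` expression
#' features, and two quantitative endpoints. Methylation follows a
#' first-order autoregression along the markers (`beta_m`), the
#' expression features load on the first two markers (`beta_x`), and each
#' endpoint loads on one expression feature (`beta_y`); all innovations
#' are independent standard normal. `beta_y = 0` is the null of no
#' molecular-endpoint association.
#'
#' @param beta_m,beta_x,beta_y Regression coefficients (the study grid
#'   uses values in \{-0.5, -0.3, 0, 0.3, 0.5\}).
#' @param n Sample size (grid: 30, 50, 100, 500).
#' @param n_markers,n_expr Numbers of methylation markers (10) and
#'   expression features (2).
#' @return An object of class `SimulationSetting`.
#' @export
simulation_setting <- function(beta_m, beta_x, beta_y, n,
                               n_markers = 10L, n_expr = 2L) {
  stopifnot(n >= 4, n_markers >= n_expr, n_expr >= 1)
  structure(list(beta_m = beta_m, beta_x = beta_x, beta_y = beta_y,
                 n = as.integer(n), n_markers = as.integer(n_markers),
                 n_expr = as.integer(n_expr), K = 2L),
            class = "SimulationSetting")
}

#' The full simulation grid
#'
#' All combinations of the three coefficients over
#' \{-0.5, -0.3, 0, 0.3, 0.5\} and sample sizes \{30, 50, 100, 500\}:
#' 500 settings, of which the 100 with `beta_y = 0` are null settings.
#'
#' @param betas Coefficient grid values.
#' @param ns Sample size grid values.
#' @return List of [simulation_setting()]s.
#' @export
default_grid <- function(betas = c(-0.5, -0.3, 0, 0.3, 0.5),
                         ns = c(30L, 50L, 100L, 500L)) {
  g <- expand.grid(beta_m = betas, beta_x = betas, beta_y = betas,
                   n = ns)
  lapply(seq_len(nrow(g)), function(i)
    simulation_setting(g$beta_m[i], g$beta_x[i], g$beta_y[i], g$n[i]))
}

#' Generate one single-gene two-omics dataset
#'
#' Per subject: `m_1 ~ N(0, 1)`; `m_l = beta_m m_(l-1) + e` for
#' `l = 2, ..., n_markers`; `x_j = beta_x m_j + e` for
#' `j = 1, ..., n_expr`; `y_j = beta_y x_j + e`; all `e` independent
#' standard normal. Note the chain is not variance-stationary: marker
#' variances propagate as `var(m_l) = 1 + beta_m^2 var(m_(l-1))` from
#' `var(m_1) = 1`. Endpoints are quantitative with direction sign +1.
#'
#' @param setting A [simulation_setting()].
#' @param seed Integer seed.
#' @return An `AlignedDataset` (methylation, expression, endpoints) with
#'   attribute `gene_map`, a [gene_feature_map()] covering the single
#'   simulated gene.
#' @export
generate_dataset <- function(setting, seed) {
  stopifnot(inherits(setting, "SimulationSetting"))
  set.seed(as.integer(seed))
  n <- setting$n; L <- setting$n_markers; Fx <- setting$n_expr
  M <- matrix(0, n, L)
  M[, 1L] <- stats::rnorm(n)
  for (l in seq_len(L - 1L) + 1L)
    M[, l] <- setting$beta_m * M[, l - 1L] + stats::rnorm(n)
  X <- setting$beta_x * M[, seq_len(Fx), drop = FALSE] +
    matrix(stats::rnorm(n * Fx), n, Fx)
  Y <- setting$beta_y * X + matrix(stats::rnorm(n * Fx), n, Fx)
  sid <- paste0("s", seq_len(n))
  meth <- omics_matrix(t(M), paste0("meth_", seq_len(L)), sid)
  expr <- omics_matrix(t(X), paste0("expr_", seq_len(Fx)), sid)
  eps <- lapply(seq_len(setting$K), function(k)
    endpoint_spec(paste0("y", k), "quantitative", 1))
  vals <- lapply(seq_len(setting$K), function(k) Y[, k])
  names(vals) <- paste0("y", seq_len(setting$K))
  ds <- align_dataset(meth, expr,
                      endpoint_table(sid, eps, vals))
  attr(ds, "gene_map") <- gene_feature_map("sim_gene",
                                           meth$feature_ids,
                                           expr$feature_ids)
  ds
}

rep_seed <- function(seed, r, what) {
  as.integer((abs(as.numeric(seed)) * 1009 + r * 7919 + what * 104729) %%
               2147483647)
}

# all seven method p-values for one simulated dataset, sharing one stream
analyze_sim_dataset <- function(ds, lambda, perm_cfg, perm_seed,
                                methods = SIM_METHODS) {
  X <- t(ds$expr$values); M <- t(ds$meth$values)
  n <- nrow(X)
  stream <- permutation_stream(perm_seed, n, perm_cfg$B1)
  Yz <- endpoint_rank_matrix(ds$endpoints)
  need_gene <- "CCPR" %in% methods
  need_x <- any(c("UXPR", "AXPR", "UOV", "AOV") %in% methods)
  need_m <- any(c("UMPR", "AMPR", "UOV", "AOV") %in% methods)
  cols <- list(); combine <- NULL
  if (need_gene) {
    fit <- orient_scores(fit_cca(X, M), X)
    cols$gene <- cbind(unit_ranks(fit$expr_scores),
                       unit_ranks(fit$meth_scores))
    combine <- list(i = 1L, j = 2L, sign = sign(fit$r_cc))
  }
  if (need_x) cols$x <- apply(X, 2L, unit_ranks)
  if (need_m) cols$m <- apply(M, 2L, unit_ranks)
  Z <- do.call(cbind, cols)
  pe <- promise_perm_fast(Z, Yz, lambda$lambdas, perm_cfg, stream,
                          combine = combine)
  p <- vapply(pe$results, `[[`, numeric(1), "p")
  off <- if (need_gene) 2L else 0L
  px <- if (need_x) p[off + seq_len(ncol(cols$x))] else NULL
  pm <- if (need_m) p[off + (if (need_x) ncol(cols$x) else 0L) +
                        seq_len(ncol(cols$m))] else NULL
  out <- c(
    CCPR = if (need_gene) p[length(p)] else NA_real_,
    UXPR = if (need_x) summarize_unadjusted(px) else NA_real_,
    AXPR = if (need_x) summarize_bonferroni(px) else NA_real_,
    UMPR = if (need_m) summarize_unadjusted(pm) else NA_real_,
    AMPR = if (need_m) summarize_bonferroni(pm) else NA_real_)
  out <- c(out,
           UOV = if (need_x && need_m) overlap_p(out[["UXPR"]],
                                                 out[["UMPR"]])
                 else NA_real_,
           AOV = if (need_x && need_m) overlap_p(out[["AXPR"]],
                                                 out[["AMPR"]])
                 else NA_real_)
  out[methods]
}

#' Estimate rejection rates for one simulation setting
#'
#' Generates `reps` independent datasets from the setting and applies the
#' requested methods; a method rejects when its summary p-value is at most
#' `alpha`. Per-replicate seeds derive from `(seed, replicate)`, so any
#' single replicate is reproducible in isolation; within a replicate all
#' methods share one permutation stream. With `beta_y = 0` the rejection
#' rate estimates type I error, otherwise power.
#'
#' @param setting A [simulation_setting()].
#' @param reps Number of replicate datasets.
#' @param alpha Significance threshold (default 0.01).
#' @param methods Subset of `c("CCPR","UXPR","AXPR","UMPR","AMPR","UOV",
#'   "AOV")`.
#' @param perm_cfg A [permutation_config()] (its seed is unused; see
#'   `seed`).
#' @param seed Master seed for the setting.
#' @return Data frame, one row per method: `method`, `rejections`,
#'   `reps`, `rate`, `mcse` (binomial Monte-Carlo standard error),
#'   `alpha`, and the setting parameters.
#' @export
run_setting <- function(setting, reps, alpha = 0.01,
                        methods = SIM_METHODS,
                        perm_cfg = permutation_config(),
                        seed = 1L) {
  stopifnot(reps >= 1L)
  methods <- match.arg(methods, SIM_METHODS, several.ok = TRUE)
  lambda <- NULL
  rej <- matrix(0L, reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    ds <- generate_dataset(setting, rep_seed(seed, r, 1L))
    if (is.null(lambda))
      lambda <- build_evidence_vector(ds$endpoints, normalized = TRUE)
    p <- analyze_sim_dataset(ds, lambda, perm_cfg,
                             rep_seed(seed, r, 2L), methods)
    rej[r, ] <- as.integer(p <= alpha)
  }
  rate <- colMeans(rej)
  data.frame(method = methods,
             rejections = colSums(rej), reps = reps, rate = rate,
             mcse = sqrt(rate * (1 - rate) / reps),
             alpha = alpha,
             beta_m = setting$beta_m, beta_x = setting$beta_x,
             beta_y = setting$beta_y, n = setting$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a list of simulation settings with per-setting checkpointing
#'
#' Iterates the settings, appending each finished setting's rows to
#' `out_path` (TSV) when given, and skipping settings already present
#' there, so an interrupted grid run resumes where it stopped.
#' Per-setting seeds derive from the master seed and the setting's
#' parameters, so results do not depend on the iteration order.
#'
#' @param settings List of [simulation_setting()]s (e.g.
#'   [default_grid()]); may be empty.
#' @param reps Replicates per setting.
#' @param alpha Significance threshold.
#' @param out_path Optional TSV checkpoint/output path.
#' @param methods Methods to run (see [run_setting()]).
#' @param perm_cfg A [permutation_config()].
#' @param seed Master seed.
#' @return Data frame of all settings' results (one row per setting x
#'   method), with attribute `partition` giving the null (`beta_y = 0`)
#'   and non-null setting counts.
#' @export
run_grid <- function(settings, reps, alpha = 0.01, out_path = NULL,
                     methods = SIM_METHODS,
                     perm_cfg = permutation_config(), seed = 1L) {
  done <- NULL
  if (!is.null(out_path) && file.exists(out_path))
    done <- utils::read.delim(out_path, stringsAsFactors = FALSE)
  key <- function(bm, bx, by, n)
    paste(sprintf("%g", bm), sprintf("%g", bx), sprintf("%g", by), n,
          sep = "|")
  done_keys <- if (!is.null(done) && nrow(done))
    unique(key(done$beta_m, done$beta_x, done$beta_y, done$n))
  else character(0)
  out <- if (!is.null(done)) list(done) else list()
  for (st in settings) {
    k <- key(st$beta_m, st$beta_x, st$beta_y, st$n)
    if (k %in% done_keys) next
    sseed <- as.integer((abs(as.numeric(seed)) * 33331 +
                           sum(c(st$beta_m, st$beta_x, st$beta_y) *
                                 c(101, 103, 107) * 10) + st$n) %%
                          2147483647)
    res <- run_setting(st, reps, alpha, methods, perm_cfg, sseed)
    out[[length(out) + 1L]] <- res
    if (!is.null(out_path))
      utils::write.table(res, out_path, sep = "\t", row.names = FALSE,
                         col.names = !file.exists(out_path),
                         append = file.exists(out_path), quote = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(method = character(0))
  rownames(res) <- NULL
  if (nrow(res)) {
    kk <- unique(key(res$beta_m, res$beta_x, res$beta_y, res$n))
    null_k <- unique(key(res$beta_m, res$beta_x, res$beta_y,
                         res$n)[res$beta_y == 0])
    attr(res, "partition") <- c(null = length(null_k),
                                non_null = length(kk) - length(null_k))
  }
  res
}

#' Large-sample moments implied by the data generator
#'
#' Closed forms used to check the generator: with `var(m_1) = 1` the
#' lag-one marker correlation at the chain start is
#' `beta_m / sqrt(1 + beta_m^2)`, and the endpoint-expression correlation
#' is `beta_y sqrt(1 + beta_x^2) / sqrt(1 + beta_y^2 (1 + beta_x^2))`.
#'
#' @param setting A [simulation_setting()].
#' @return Named numeric vector `c(cor_m1_m2, cor_y1_x1)`.
#' @export
theoretical_moments <- function(setting) {
  bm <- setting$beta_m; bx <- setting$beta_x; by <- setting$beta_y
  vx <- 1 + bx^2
  c(cor_m1_m2 = bm / sqrt(1 + bm^2),
    cor_y1_x1 = by * sqrt(vx) / sqrt(1 + by^2 * vx))
}
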