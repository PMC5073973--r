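test_that("gene summaries follow the min / Bonferroni / max rules", {
  expect_equal(summarize_unadjusted(c(0.004, 0.2)), 0.004)
  expect_equal(summarize_unadjusted(0.03), 0.03)
  expect_equal(summarize_unadjusted(c(1, 1)), 1)
  expect_equal(summarize_bonferroni(c(0.004, 0.2)), 0.008)
  expect_equal(summarize_bonferroni(c(0.6, 0.7)), 1) # capped
  expect_equal(summarize_bonferroni(0.03), 0.03)
  expect_equal(overlap_p(0.008, 0.03), 0.03)
  expect_equal(overlap_p(0.5, 0.5), 0.5)
  expect_equal(overlap_p(1e-4, 1), 1)
  expect_error(summarize_unadjusted(numeric(0)), "empty")
})

test_that("a perfectly associated gene attains the evidence bound", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  M <- 0.7 * X[, c(1, 2, 1)] + matrix(rnorm(n * 3), n, 3) * 0.3
  fit <- orient_scores(fit_cca(X, M), X)
  sid <- paste0("s", 1:n)
  eps <- list(endpoint_spec("y1", "quantitative", 1),
              endpoint_spec("y2", "quantitative", 1))
  et <- endpoint_table(sid, eps, list(y1 = fit$expr_scores,
                                      y2 = fit$expr_scores))
  lam <- build_evidence_vector(et)
  res <- ccpr_gene(X, M, et, lam, permutation_config(100, 10000, 3))
  expect_equal(res$t_expr, 1, tolerance = 1e-10)
  expect_lte(res$p_expr, 0.01)
  expect_lte(res$p_combined, 0.01)
})

test_that("a duplicated endpoint doubles the unnormalized statistic", {
  set.seed(23)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  M <- matrix(rnorm(n * 3), n, 3)
  y1 <- rnorm(n)
  sid <- paste0("s", 1:n)
  eps <- list(endpoint_spec("y1", "quantitative", 1),
              endpoint_spec("y2", "quantitative", 1))
  et <- endpoint_table(sid, eps, list(y1 = y1, y2 = y1))
  lam <- build_evidence_vector(et, normalized = FALSE)
  res <- ccpr_gene(X, M, et, lam, permutation_config(100, 500, 3))
  fit <- orient_scores(fit_cca(X, M), X)
  a1 <- spearman_assoc(fit$expr_scores, y1)$value
  expect_equal(res$t_expr, 2 * a1, tolerance = 1e-10)
})

test_that("feature-level analysis shares the stream deterministically", {
  ds <- toy_dataset(n = 25, seed = 3)
  lam <- toy_lambda()
  cfg <- permutation_config(50, 1000, 11)
  X <- t(ds$expr$values)
  # two identical features get identical (t, p)
  f2 <- cbind(a = X[, 1], b = X[, 1])
  res <- feature_promise(f2, ds$endpoints, lam, cfg)
  expect_equal(res$t[1], res$t[2])
  expect_equal(res$p[1], res$p[2])
  # single feature equal to a single endpoint gives t = lambda_1
  sid <- ds$endpoints$sample_ids
  et1 <- endpoint_table(sid, list(endpoint_spec("y", "quantitative", 1)),
                        list(y = X[, 1]))
  lam1 <- build_evidence_vector(et1, normalized = FALSE)
  r1 <- feature_promise(X[, 1, drop = FALSE], et1, lam1, cfg)
  expect_equal(r1$t, lam1$lambdas[1])
})

test_that("feature-level adaptive p equals exact enumeration on a small toy", {
  set.seed(29)
  n <- 6
  f <- rnorm(n)
  sid <- paste0("s", 1:n)
  eps <- list(endpoint_spec("y1", "quantitative", 1),
              endpoint_spec("y2", "quantitative", -1))
  et <- endpoint_table(sid, eps, list(y1 = rnorm(n), y2 = rnorm(n)))
  lam <- build_evidence_vector(et)
  nf <- factorial(n)
  res <- feature_promise(cbind(f), et, lam,
                         permutation_config(nf, nf, 1),
                         stream = enumeration_stream(n))
  stat <- function(p) {
    a <- endpoint_assoc_vector(f, ccpromise:::subset_endpoints(et, p))$value
    sum(lam$lambdas * a)
  }
  expect_equal(res$p, exact_reference_pvalue(stat(1:n), stat, n))
})

test_that("the slow (missing-tolerant) path agrees with the batched path", {
  ds <- toy_dataset(n = 18, seed = 9)
  lam <- toy_lambda()
  cfg <- permutation_config(30, 300, 5)
  feats <- list(t(ds$expr$values)[, 1], t(ds$meth$values)[, 2])
  stream1 <- permutation_stream(cfg$seed, 18, cfg$B1)
  stream2 <- permutation_stream(cfg$seed, 18, cfg$B1)
  Z <- cbind(ccpromise:::unit_ranks(feats[[1]]),
             ccpromise:::unit_ranks(feats[[2]]))
  fast <- ccpromise:::promise_perm_fast(
    Z, ccpromise:::endpoint_rank_matrix(ds$endpoints), lam$lambdas,
    cfg, stream1)
  slow <- ccpromise:::promise_perm_slow(feats, ds$endpoints, lam, cfg,
                                        stream2)
  expect_equal(fast$t0, slow$t0, tolerance = 1e-12)
  expect_equal(lapply(fast$results, `[[`, "p"),
               lapply(slow$results, `[[`, "p"))
})

test_that("missing endpoint values are excluded pairwise, not fatally", {
  ds <- toy_dataset(n = 24, seed = 15)
  vals <- ds$endpoints$values
  vals$y1[c(2, 7)] <- NA
  et <- endpoint_table(ds$endpoints$sample_ids, ds$endpoints$endpoints,
                       vals)
  lam <- toy_lambda()
  cfg <- permutation_config(20, 200, 5)
  res <- ccpr_gene(t(ds$expr$values), t(ds$meth$values), et, lam, cfg)
  expect_true(res$p_combined > 0 && res$p_combined <= 1)
  res2 <- ccpr_gene(t(ds$expr$values), t(ds$meth$values), et, lam, cfg)
  expect_identical(res$p_combined, res2$p_combined)
})

test_that("the study loop reports results, skips, and is reproducible", {
  ds <- toy_dataset(n = 22, seed = 33)
  # make a degenerate gene: constant methylation marker
  ds$meth$values["m3", ] <- 1
  maps <- list(gene_feature_map("gA", c("m1", "m2"), c("x1", "x2")),
               gene_feature_map("gB", "m1", "x2"),
               gene_feature_map("gDeg", "m3", "x1"))
  lam <- toy_lambda()
  cfg <- permutation_config(30, 300, 17)
  res <- run_study(ds, maps, lam, cfg)
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "skipped")$gene_id, "gDeg")
  # unadjusted summaries never exceed adjusted ones
  expect_true(all(res$uxpr <= res$axpr))
  expect_true(all(res$umpr <= res$ampr))
  expect_equal(res$uov, pmax(res$uxpr, res$umpr))
  expect_equal(res$aov, pmax(res$axpr, res$ampr))
  # bit-identical rerun under the same seed
  res2 <- run_study(ds, maps, lam, cfg)
  attributes(res) <- attributes(res2) <- NULL
  expect_identical(res, res2)
})
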