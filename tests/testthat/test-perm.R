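test_that("the permutation stream is deterministic and seed-sensitive", {
  s1 <- permutation_stream(5, 12)
  s2 <- permutation_stream(5, 12)
  expect_identical(s1$get(1, 700), s2$get(1, 700))
  # addressable: asking for a window equals slicing the full range
  expect_identical(s1$get(601, 650), s2$get(1, 700)[, 601:650])
  s3 <- permutation_stream(6, 12)
  expect_false(identical(s1$get(1, 100), s3$get(1, 100)))
  # every column is a permutation
  P <- s1$get(1, 200)
  expect_true(all(apply(P, 2, sort) == 1:12))
})

test_that("n = 2 permutations are identity or swap only", {
  P <- permutation_stream(9, 2)$get(1, 50)
  expect_true(all(apply(P, 2, function(p)
    identical(p, 1:2) || identical(p, 2:1))))
})

test_that("early stopping reports exceedances over performed permutations", {
  cfg <- permutation_config(100, 10000, 1)
  # exactly the even-indexed permutations exceed: the 100th exceedance
  # lands on permutation 200
  r <- adaptive_pvalue(1, function(P, idx) ifelse(idx %% 2 == 0, 2, 0),
                       cfg, n = 10)
  expect_equal(r$p, 0.50)
  expect_equal(r$exceed_count, 100L)
  expect_equal(r$performed, 200L)
  expect_true(r$stopped_early)
  # t0 = 0: every permutation exceeds, stop at B0 with p = 1
  r0 <- adaptive_pvalue(0, function(P, idx) rnorm(ncol(P)), cfg, n = 10)
  expect_equal(r0$p, 1)
  expect_equal(r0$performed, 100L)
  # 25 exceedances in all B1 = 10000
  r25 <- adaptive_pvalue(1, function(P, idx)
    ifelse(idx %% 400 == 0, 2, 0), cfg, n = 10)
  expect_equal(r25$p, 0.0025)
  expect_false(r25$stopped_early)
  # p never drops below 1/B1
  rnone <- adaptive_pvalue(5, function(P, idx) rep(0, ncol(P)),
                           permutation_config(10, 500, 1), n = 10)
  expect_equal(rnone$p, 1 / 500)
})

test_that("adaptive p-values are bit-reproducible under a fixed seed", {
  set.seed(99)
  x <- rnorm(30); y <- rnorm(30)
  cfg <- permutation_config(50, 2000, 123)
  sf <- function(P, idx) apply(P, 2, function(p) cor(x, y[p]))
  r1 <- adaptive_pvalue(cor(x, y), sf, cfg, n = 30)
  r2 <- adaptive_pvalue(cor(x, y), sf, cfg, n = 30)
  expect_identical(r1, r2)
})

test_that("adaptive with an enumerating stream equals exact enumeration", {
  set.seed(17)
  for (n in c(5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    t0 <- cor(x, y)
    exact <- exact_reference_pvalue(t0, function(p) cor(x, y[p]), n)
    ad <- adaptive_pvalue(
      t0, function(P, idx) apply(P, 2, function(p) cor(x, y[p])),
      permutation_config(factorial(n), factorial(n), 1),
      stream = enumeration_stream(n))
    expect_equal(ad$p, exact)
    expect_equal(ad$performed, factorial(n))
  }
})

test_that("exact enumeration handles symmetric and extremal statistics", {
  # statistic symmetric under label swap at n = 2: both permutations tie
  expect_equal(exact_reference_pvalue(
    1, function(p) 1, 2), 1)
  # n = 3, statistic uniquely maximised at the identity; compare against
  # a direct brute-force over the 6 permutations rather than assuming 1/6
  x <- c(1, 2, 4); y <- c(1, 2, 4)
  tb <- apply(ccpromise:::all_permutations(3), 1,
              function(p) cor(x, y[p]))
  expect_equal(exact_reference_pvalue(cor(x, y),
                                      function(p) cor(x, y[p]), 3),
               mean(abs(tb) >= abs(cor(x, y)) - 1e-12))
  expect_error(exact_reference_pvalue(1, identity, 9), "n > 8")
})

test_that("joint multi-statistic stopping matches per-statistic runs", {
  set.seed(31)
  n <- 15
  x1 <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n)
  cfg <- permutation_config(20, 1000, 77)
  stream <- permutation_stream(cfg$seed, n, cfg$B1)
  t0s <- c(cor(x1, y), cor(x2, y))
  joint <- ccpromise:::adaptive_pvalues_multi(
    t0s,
    function(P, idx) rbind(apply(P, 2, function(p) cor(x1, y[p])),
                           apply(P, 2, function(p) cor(x2, y[p]))),
    cfg, stream)
  for (s in 1:2) {
    xs <- list(x1, x2)[[s]]
    solo <- adaptive_pvalue(t0s[s],
                            function(P, idx)
                              apply(P, 2, function(p) cor(xs, y[p])),
                            cfg, stream = permutation_stream(cfg$seed, n,
                                                             cfg$B1))
    expect_identical(joint[[s]], solo)
  }
})
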