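test_that("spearman association reproduces hand-computed rank values", {
  expect_equal(spearman_assoc(1:3, c(10, 20, 30))$value, 1)
  expect_equal(spearman_assoc(1:3, c(3, 2, 1))$value, -1)
  # ranks (1,2,3) vs (3,1,2): centered products sum to -1, sds 1 -> -0.5
  expect_equal(spearman_assoc(1:3, c(3, 1, 2))$value, -0.5)
  expect_error(spearman_assoc(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_assoc(c(1, 2, NA), c(1, NA, 3)), "insufficient")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    v <- spearman_assoc(x, y)$value
    expect_equal(spearman_assoc(exp(x), y)$value, v)
    expect_equal(spearman_assoc(x, y^3 + 2 * y)$value, v)
  }
})

test_that("binary association is the rank-biserial Spearman form", {
  # ranks (1,2,3,4) with (0,0,1,1): 2/sqrt(5)
  expect_equal(binary_assoc(1:4, c(0, 0, 1, 1))$value, 2 / sqrt(5))
  expect_error(binary_assoc(1:4, c(1, 1, 1, 1)), "one group")
  expect_error(binary_assoc(rep(2, 4), c(0, 0, 1, 1)), "constant")
  expect_error(binary_assoc(1:4, c(0, 0, 1, 2)), "0/1")
})

test_that("survival association matches a hand Nelson-Aalen oracle", {
  # all events, no ties: H = cumsum(1/(n - i + 1)) at ordered times
  time <- 1:5; event <- rep(1, 5)
  H <- cumsum(1 / (5:1))
  oracle_resid <- event - H
  x <- c(5, 4, 3, 2, 1)
  oracle <- -cor(rank(x), rank(oracle_resid))
  got <- survival_assoc(x, time, event)
  expect_equal(got$value, oracle)
  expect_equal(got$value, -1) # perfectly anti-concordant with survival
  # larger x with later event times -> positive
  expect_gt(survival_assoc(1:5, time, event)$value, 0)
  expect_warning(v0 <- survival_assoc(1:5, time, rep(0, 5)), "no events")
  expect_equal(v0$value, 0)
})

test_that("pair correlation gives Pearson r with t-based p", {
  expect_equal(pair_correlation(c(0, 1, 2), c(1, 3, 5))$r, 1)
  expect_equal(pair_correlation(1:3, c(3, 2, 1))$r, -1)
  expect_equal(pair_correlation(1:3, c(1, 3, 2))$r, 0.5)
  pc <- pair_correlation(rnorm(10), rnorm(10))
  expect_true(pc$p > 0 && pc$p <= 1)
  expect_error(pair_correlation(rep(1, 5), 1:5), "constant")
})

test_that("pair correlation p-values are uniform under independence", {
  set.seed(7)
  p <- replicate(2000, pair_correlation(rnorm(10), rnorm(10))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("all association statistics stay within [-1, 1]", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    expect_lte(abs(spearman_assoc(x, rnorm(n))$value), 1)
    expect_lte(abs(binary_assoc(x, rbinom(n, 1, 0.5) * 0 +
                                  c(0, 1, rbinom(n - 2, 1, 0.5)))$value), 1)
    v <- survival_assoc(x, rexp(n), c(1, rbinom(n - 1, 1, 0.7)))$value
    expect_lte(abs(v), 1)
  }
})

test_that("endpoint association vectors dispatch and apply direction signs", {
  n <- 30; set.seed(5)
  sid <- paste0("s", 1:n)
  f <- rnorm(n)
  eps <- list(endpoint_spec("same", "quantitative", 1),
              endpoint_spec("flip", "quantitative", -1))
  et <- endpoint_table(sid, eps, list(same = f, flip = f))
  av <- endpoint_assoc_vector(f, et)
  expect_equal(av$value, c(1, -1)) # sign flip contract
  # mixed kinds: binary + survival dispatch
  eps2 <- list(endpoint_spec("b", "binary", 1),
               endpoint_spec("s", "survival", 1))
  et2 <- endpoint_table(sid, eps2,
                        list(b = rbinom(n, 1, 0.5),
                             s = list(time = rexp(n),
                                      event = rbinom(n, 1, 0.7))))
  av2 <- endpoint_assoc_vector(f, et2)
  expect_true(all(abs(av2$value) <= 1))
  # per-endpoint failure becomes NA with warning, not an error
  et3 <- endpoint_table(sid, eps,
                        list(same = rep(1, n), flip = f))
  expect_warning(av3 <- endpoint_assoc_vector(f, et3), "constant")
  expect_true(is.na(av3$value[1]) && !is.na(av3$value[2]))
})

test_that("independent endpoints give near-zero association", {
  set.seed(13)
  n <- 2000
  a <- spearman_assoc(rnorm(n), rnorm(n))$value
  expect_lt(abs(a), 3 / sqrt(n))
})
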