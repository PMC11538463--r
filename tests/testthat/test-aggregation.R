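test_that("priority weights follow the multiplicative discounting rule", {
  pw <- priorityWeights(c(0.4, 0.5, 0.2))
  expect_equal(pw$T, c(1, 0.4, 0.2))
  expect_equal(pw$w, c(0.625, 0.25, 0.125))
  expect_equal(priorityWeights(rep(1, 4))$w, rep(0.25, 4))
  expect_equal(priorityWeights(0.3)$w, 1)
  expect_error(priorityWeights(numeric()), "non-empty")
  expect_error(priorityWeights(c(0.5, 1.2)), "\\[0, 1\\]")
  # degrees never increase along the priority order
  set.seed(71)
  for (rep in 1:50) {
    Tdeg <- priorityWeights(runif(6))$T
    expect_true(all(diff(Tdeg) <= 0))
    expect_equal(Tdeg[1], 1)
  }
})

test_that("crisp MSM and DMSM match subset enumeration by hand", {
  expect_equal(crispMSM(c(1, 2, 3), 2), sqrt((2 + 3 + 6) / 3))
  expect_equal(crispDMSM(c(1, 2, 3), 2), (3 * 4 * 5)^(1 / 3) / 2)
  # idempotency of the plain means
  expect_equal(crispMSM(rep(2.5, 5), 3), 2.5)
  expect_equal(crispDMSM(rep(2.5, 5), 3), 2.5)
  expect_error(crispMSM(1:3, 4), "k")
  # MSM is monotone in each argument
  expect_lt(crispMSM(c(1, 2, 3), 2), crispMSM(c(1, 2.5, 3), 2))
})

test_that("a single argument passes through both operators unchanged", {
  set.seed(81)
  x <- rand_qrf2ln(1)
  expect_same_qrf2ln(qrf2lPMSM(x, 1, k = 1), x)
  expect_same_qrf2ln(qrf2lPDMSM(x, 1, k = 1), x)
})

test_that("closed forms equal stepwise evaluation through the laws", {
  set.seed(91)
  for (rep in 1:120) {
    n <- sample(2:4, 1)
    k <- sample.int(n, 1)
    x <- rand_qrf2ln(n)
    w <- rand_weights(n)
    expect_same_qrf2ln(qrf2lPMSM(x, w, k), pmsm_oracle(x, w, k))
    expect_same_qrf2ln(qrf2lPDMSM(x, w, k), pdmsm_oracle(x, w, k))
  }
})

test_that("reduced special cases agree with the general operator", {
  set.seed(101)
  for (rep in 1:40) {
    n <- 4
    x <- rand_qrf2ln(n)
    w <- rand_weights(n)
    for (dual in c(FALSE, TRUE)) {
      agg <- if (dual) qrf2lPDMSM else qrf2lPMSM
      expect_same_qrf2ln(qrf2lSpecialCase(x, w, "k1", dual), agg(x, w, 1))
      expect_same_qrf2ln(qrf2lSpecialCase(x, w, "k2", dual), agg(x, w, 2))
      expect_same_qrf2ln(qrf2lSpecialCase(x, w, "k3", dual), agg(x, w, 3))
      expect_same_qrf2ln(qrf2lSpecialCase(x, w, "kn", dual), agg(x, w, n))
    }
  }
})

test_that("aggregates are monotone and bounded by the envelopes", {
  set.seed(111)
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    k <- sample.int(n, 1)
    pr <- rand_ordered_pair(n)
    w <- rand_weights(n)
    for (agg in list(qrf2lPMSM, qrf2lPDMSM)) {
      lo <- agg(pr$small, w, k)
      hi <- agg(pr$large, w, k)
      expect_lte(score(lo), score(hi) + 1e-9)
      # componentwise bounding, which implies the score bound used above
      expect_lte(lo$index + lo$delta, hi$index + hi$delta + 1e-9)
      expect_lte(lo$mu, hi$mu + 1e-9)
      expect_gte(lo$nu, hi$nu - 1e-9)
      # min/max envelopes of a mixed panel bound its aggregate
      mix <- c(pr$small[seq_len(ceiling(n / 2))],
               pr$large[seq(ceiling(n / 2) + 1, n)])
      S <- attr(mix, "lts")
      vmin <- min(mix$index + mix$delta); vmax <- max(mix$index + mix$delta)
      ttmin <- toTwoTuple(rep(vmin, n), S); ttmax <- toTwoTuple(rep(vmax, n), S)
      env_lo <- qrf2ln(ttmin$index, ttmin$delta, min(mix$mu), max(mix$nu))
      env_hi <- qrf2ln(ttmax$index, ttmax$delta, max(mix$mu), min(mix$nu))
      expect_lte(score(agg(env_lo, w, k)), score(agg(mix, w, k)) + 1e-9)
      expect_gte(score(agg(env_hi, w, k)), score(agg(mix, w, k)) - 1e-9)
    }
  }
})

test_that("prioritized operators are deliberately not idempotent", {
  x <- qrf2ln(c(3, 3, 3), 0, 0.6, 0.3)
  w <- c(0.7, 0.2, 0.1)  # non-uniform priority weights
  agg <- qrf2lPMSM(x, w, k = 2)
  expect_gt(abs(score(agg) - score(x[1])), 1e-3)
  aggd <- qrf2lPDMSM(x, w, k = 2)
  expect_gt(abs(score(aggd) - score(x[1])), 1e-3)
})

test_that("the Muirhead mean is symmetric and handles degenerate P", {
  set.seed(121)
  x <- rand_qrf2ln(4)
  P <- c(1, 1, 2, 1)
  r1 <- qrf2lMuirhead(x, P)
  shuffle <- sample(4)
  r2 <- qrf2lMuirhead(x[shuffle], P)
  expect_same_qrf2ln(r1, r2)
  # P = (1, 0, 0, 0) on identical inputs returns the common input
  y <- qrf2ln(rep(2L, 4), 0, 0.6, 0.3)
  expect_same_qrf2ln(qrf2lMuirhead(y, c(1, 0, 0, 0)), y[1])
  expect_error(qrf2lMuirhead(rand_qrf2ln(9), rep(1, 9)), "n <= 8")
  expect_error(qrf2lMuirhead(x, c(0, 0, 0, 0)), "positive")
})

test_that("the orthopair MSM is idempotent and matches the law oracle", {
  r <- qrofMSM(rep(0.7, 4), rep(0.4, 4), k = 2, q = 3)
  expect_equal(r$mu, 0.7, tolerance = 1e-12)
  expect_equal(r$nu, 0.4, tolerance = 1e-12)
  set.seed(131)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    k <- sample.int(n, 1)
    pr <- rand_pair(n, 3)
    got <- qrofMSM(pr$mu, pr$nu, k = k, q = 3)
    ref <- qrofmsm_oracle(pr$mu, pr$nu, k, 3)
    expect_equal(got$mu, ref$mu, tolerance = 1e-9)
    expect_equal(got$nu, ref$nu, tolerance = 1e-9)
  }
  expect_error(qrofMSM(c(0.8, 0.9), c(0.9, 0.8), k = 1, q = 2), "invalid")
})
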