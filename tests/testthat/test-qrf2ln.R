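test_that("construction enforces the rung constraint and field ranges", {
  expect_silent(qrf2ln(2, 0, 0.6, 0.3))
  expect_error(qrf2ln(2, 0, 0.8, 0.9, q = 2), "rung constraint")
  expect_error(qrf2ln(2, 0, 0.8, 0.9, q = 3), "rung constraint")
  expect_silent(qrf2ln(2, 0, 0.8, 0.9, q = 5))
  expect_error(qrf2ln(7, 0, 0.5, 0.5), "outside")
  expect_error(qrf2ln(2, 0.5, 0.5, 0.5), "outside")
  expect_error(qrf2ln(2, 0, 1.2, 0.1), "\\[0, 1\\]")
})

test_that("score and accuracy match hand evaluation and their ranges", {
  a <- qrf2ln(2, 0, 0.6, 0.3)
  expect_equal(score(a), 2 * (1 + 0.6^3 - 0.3^3) / 14)
  expect_equal(accuracy(a), 2 * (0.6^3 + 0.3^3))
  # degenerate linguistic part nullifies both
  expect_equal(score(qrf2ln(0, 0, 0.9, 0.2)), 0)
  expect_equal(accuracy(qrf2ln(3, 0, 0, 0)), 0)
  # the maximal element attains the top of the score range, (g-1)/g
  expect_equal(score(qrf2ln(6, 0, 1, 0)), 6 / 7)
  set.seed(21)
  x <- rand_qrf2ln(500)
  expect_true(all(score(x) >= 0 & score(x) <= 1))
})

test_that("comparison orders by score with an accuracy tie-break", {
  a <- qrf2ln(3, 0, 0.7, 0.2)
  b <- qrf2ln(2, 0, 0.5, 0.4)
  expect_identical(compareQ(a, b), 1L)
  expect_identical(compareQ(b, a), -1L)
  expect_identical(compareQ(a, a), 0L)
  # equal scores (mu = nu cancels in the score), different accuracy
  x <- qrf2ln(2, 0, 0.5, 0.5)
  y <- qrf2ln(2, 0, 0.7, 0.7)
  expect_equal(score(x), score(y))
  expect_gt(accuracy(y), accuracy(x))
  expect_identical(compareQ(y, x), 1L)
  expect_identical(compareQ(y, x, accuracyHigherWins = FALSE), -1L)
  # incompatible operands
  expect_error(compareQ(a, qrf2ln(2, 0, 0.5, 0.4, q = 4)), "rungs")
  expect_error(compareQ(a, qrf2ln(2, 0, 0.5, 0.4, lts = lts(5))),
               "cardinality")
})

test_that("operational laws reproduce hand-derived cases", {
  a <- qrf2ln(2, 0, 0.6, 0.3)
  b <- qrf2ln(3, 0, 0.4, 0.5)
  s <- qAdd(a, b)
  expect_equal(s$index + s$delta, 5)
  expect_equal(s$mu, (0.216 + 0.064 - 0.216 * 0.064)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(s$nu, 0.15)
  d <- qScale(2, a)
  expect_equal(d$index + d$delta, 4)
  expect_equal(d$mu, (1 - (1 - 0.216)^2)^(1 / 3), tolerance = 1e-12)
  expect_equal(d$nu, 0.09)
  # neutral element of the sum
  zero <- qrf2ln(0, 0, 0, 1)
  expect_same_qrf2ln(qAdd(a, zero), a)
  # complement is an involution
  expect_same_qrf2ln(qComplement(qComplement(a)), a)
  expect_error(qScale(-1, a), "positive")
  expect_error(qPower(a, 0), "positive")
})

test_that("linguistic overflow is clamped with a warning", {
  a <- qrf2ln(4, 0, 0.6, 0.3)
  b <- qrf2ln(5, 0, 0.5, 0.4)
  expect_warning(p <- qMultiply(a, b), "clamped")
  expect_equal(p$index + p$delta, 6)
  expect_warning(qAdd(a, b), "clamped")
  expect_silent(qMultiply(a, b, clamp = FALSE))
})

test_that("the Hamming distance is a normalized score-numerator difference", {
  a <- qrf2ln(2, 0, 0.6, 0.3)
  b <- qrf2ln(3, 0, 0.4, 0.5)
  expect_equal(hammingDistance(a, b),
               abs(2 * (1 + 0.216 - 0.027) - 3 * (1 + 0.064 - 0.125)) / 14)
  expect_equal(hammingDistance(a, a), 0)
  set.seed(31)
  x <- rand_qrf2ln(200); y <- rand_qrf2ln(200)
  expect_equal(hammingDistance(x, y), hammingDistance(y, x))
  expect_true(all(hammingDistance(x, y) >= 0))
})

test_that("random operation chains stay inside the constraint set", {
  set.seed(41)
  q <- 3
  ops <- list(
    function(a, b) qAdd(a, b, clamp = FALSE),
    function(a, b) qMultiply(a, b, clamp = FALSE),
    function(a, b) qScale(runif(1, 0.1, 3), a, clamp = FALSE),
    function(a, b) qPower(a, runif(1, 0.1, 3), clamp = FALSE),
    function(a, b) qComplement(a)
  )
  n <- 2500  # 4 ops per chain -> 1e4 law applications
  x <- rand_qrf2ln(n)
  for (step in 1:4) {
    y <- rand_qrf2ln(n)
    f <- ops[[sample.int(length(ops), 1)]]
    x <- f(x, y)
    expect_true(all(x$mu >= 0 & x$mu <= 1))
    expect_true(all(x$nu >= 0 & x$nu <= 1))
    expect_true(all(x$mu^q + x$nu^q <= 1 + 1e-9))
    expect_true(all(x$delta >= -0.5 & x$delta < 0.5))
  }
})

test_that("scalar multiplication distributes over the fuzzy sum", {
  set.seed(51)
  for (rep in 1:20) {
    a <- rand_qrf2ln(1); b <- rand_qrf2ln(1)
    alpha <- runif(1, 0.2, 2.5)
    lhs <- qScale(alpha, qAdd(a, b, clamp = FALSE), clamp = FALSE)
    rhs <- qAdd(qScale(alpha, a, clamp = FALSE),
                qScale(alpha, b, clamp = FALSE), clamp = FALSE)
    expect_same_qrf2ln(lhs, rhs, tol = 1e-9)
  }
})

test_that("the canonical text form round-trips and validates", {
  x <- parseCell("s2:0.0|0.6,0.3")
  expect_equal(x$index, 2L)
  expect_equal(x$mu, 0.6)
  # delta defaults to zero when omitted
  expect_equal(parseCell("s2|0.6,0.3")$delta, 0)
  expect_error(parseCell("s2:0.0|0.8,0.9", q = 2), "rung constraint")
  expect_error(parseCell("s2:0.0|0.8,0.9", q = 3), "rung constraint")
  expect_silent(parseCell("s2:0.0|0.8,0.9", q = 5))
  expect_error(parseCell("2|0.6,0.3"), "malformed")
  set.seed(61)
  y <- rand_qrf2ln(50)
  z <- parseCell(formatCell(y))
  expect_same_qrf2ln(y, z, tol = 1e-12)
})
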