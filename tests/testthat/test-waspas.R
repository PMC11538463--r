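test_that("normalization complements cost columns and is an involution", {
  pan <- generatePanel(m = 3, s = 3, p = 2, seed = 141)
  # all-benefit panels pass through unchanged
  expect_identical(normalizePanel(pan), pan)
  pan$criteriaTypes <- c("benefit", "cost", "cost")
  norm <- normalizePanel(pan)
  expect_equal(norm$matrices[[1]]$mu[, 2], pan$matrices[[1]]$nu[, 2])
  expect_equal(norm$matrices[[1]]$nu[, 3], pan$matrices[[1]]$mu[, 3])
  expect_equal(norm$matrices[[1]]$mu[, 1], pan$matrices[[1]]$mu[, 1])
  expect_identical(normalizePanel(norm), pan)
})

test_that("expert priority degrees start at one and never increase", {
  pan <- examplePanel()
  pw <- expertPriorityWeights(pan, digits = NULL)
  expect_true(all(pw$T[, , 1] == 1))
  expect_true(all(pw$T[, , 2] >= pw$T[, , 3]))
  # the first degree after the leader is the leader's score
  e1 <- pan$matrices[[1]]
  expect_equal(pw$T[1, 1, 2], score(qrf2ln(e1$index[1, 1], e1$delta[1, 1],
                                           e1$mu[1, 1], e1$nu[1, 1])))
  # weights normalize per cell
  expect_equal(apply(pw$w, c(1, 2), sum), matrix(1, 5, 4), ignore_attr = TRUE)
})

test_that("a single-expert panel aggregates to its own matrix at k = 1", {
  pan <- generatePanel(m = 4, s = 3, p = 1, seed = 151)
  col <- aggregateExperts(pan, k = 1)
  m <- pan$matrices[[1]]
  expect_equal(col$index + col$delta, m$index + m$delta, tolerance = 1e-9)
  expect_equal(col$mu, m$mu, tolerance = 1e-9)
  expect_equal(col$nu, m$nu, tolerance = 1e-9)
})

test_that("the combined measure is affine in theta with model endpoints", {
  pan <- generatePanel(seed = 161)
  r0 <- waspas(pan, theta = 0)
  r1 <- waspas(pan, theta = 1)
  expect_equal(r0$combined, r0$ppm)
  expect_equal(r1$combined, r1$psm)
  for (th in c(0.25, 0.5, 0.8)) {
    r <- waspas(pan, theta = th)
    expect_equal(r$combined, th * r1$combined + (1 - th) * r0$combined,
                 tolerance = 1e-12)
  }
  expect_error(waspas(pan, theta = 1.2), "theta")
})

test_that("the pipeline is deterministic and ranking is a permutation", {
  pan <- generatePanel(seed = 171)
  a <- waspas(pan)
  b <- waspas(pan)
  expect_identical(a, b)
  expect_setequal(a$ranking, seq_along(a$combined))
  expect_true(all(diff(a$combined[a$ranking]) <= 0))
})

test_that("sensitivity scans cover the grid and stay affine in theta", {
  pan <- examplePanel()
  scan <- sensitivityScan(pan, thetaGrid = c(0, 0.5, 1), qGrid = c(3, 5))
  expect_equal(nrow(scan), 6)
  alts <- pan$alternatives
  for (qq in c(3, 5)) {
    sub <- scan[scan$q == qq, ]
    mid <- 0.5 * (unlist(sub[sub$theta == 0, alts]) +
                  unlist(sub[sub$theta == 1, alts]))
    expect_equal(unlist(sub[sub$theta == 0.5, alts]), mid,
                 tolerance = 1e-12)
  }
  # combined measure rises with theta whenever the sum model dominates
  r <- waspas(pan, theta = 0.5)
  stopifnot(all(r$psm >= r$ppm))
  s3 <- scan[scan$q == 3, ]
  expect_true(all(unlist(s3[s3$theta == 1, alts]) >=
                  unlist(s3[s3$theta == 0, alts])))
})

test_that("changing q revalidates every cell against the new rung", {
  S <- lts()
  mk <- function(mu, nu) {
    qrf2lMatrix(matrix(2L, 1, 1), matrix(0, 1, 1), matrix(mu, 1, 1),
                matrix(nu, 1, 1), q = 3, lts = S)
  }
  pan <- decisionPanel(list(mk(0.8, 0.75)))  # valid at q = 3 only
  expect_silent(waspas(pan, k = 1))
  expect_error(sensitivityScan(pan, thetaGrid = 0.5, qGrid = 2, k = 1),
               "rung constraint")
})
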