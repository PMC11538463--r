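# stepwise oracles: evaluate the aggregation definitions with nothing but the
# exported operational laws (clamp = FALSE keeps intermediate linguistic
# aggregation values in the unbounded symbolic domain, as the closed forms do)

pmsm_oracle <- function(values, w, k) {
  n <- length(values)
  sub <- utils::combn(n, k)
  acc <- NULL
  for (s in seq_len(ncol(sub))) {
    term <- NULL
    for (j in sub[, s]) {
      t1 <- qPower(values[j], w[j], clamp = FALSE)
      term <- if (is.null(term)) t1 else qMultiply(term, t1, clamp = FALSE)
    }
    acc <- if (is.null(acc)) term else qAdd(acc, term, clamp = FALSE)
  }
  qPower(qScale(1 / ncol(sub), acc, clamp = FALSE), 1 / k, clamp = FALSE)
}

pdmsm_oracle <- function(values, w, k) {
  n <- length(values)
  sub <- utils::combn(n, k)
  acc <- NULL
  for (s in seq_len(ncol(sub))) {
    term <- NULL
    for (j in sub[, s]) {
      t1 <- qScale(w[j], values[j], clamp = FALSE)
      term <- if (is.null(term)) t1 else qAdd(term, t1, clamp = FALSE)
    }
    acc <- if (is.null(acc)) term else qMultiply(acc, term, clamp = FALSE)
  }
  qScale(1 / k, qPower(acc, 1 / ncol(sub), clamp = FALSE), clamp = FALSE)
}

# q-ROF pairs as degenerate q-RF2L numbers with a fixed linguistic part, so
# the same laws drive the orthopair arithmetic
qrofmsm_oracle <- function(mu, nu, k, q) {
  S <- lts()
  vals <- qrf2ln(1, 0, mu, nu, q = q, lts = S)
  n <- length(mu)
  sub <- utils::combn(n, k)
  acc <- NULL
  for (s in seq_len(ncol(sub))) {
    term <- NULL
    for (j in sub[, s]) {
      term <- if (is.null(term)) vals[j] else
        qMultiply(term, vals[j], clamp = FALSE)
    }
    acc <- if (is.null(acc)) term else qAdd(acc, term, clamp = FALSE)
  }
  out <- qPower(qScale(1 / ncol(sub), acc, clamp = FALSE), 1 / k,
                clamp = FALSE)
  list(mu = out$mu, nu = out$nu)
}

expect_same_qrf2ln <- function(a, b, tol = 1e-9) {
  expect_equal(a$index + a$delta, b$index + b$delta, tolerance = tol)
  expect_equal(a$mu, b$mu, tolerance = tol)
  expect_equal(a$nu, b$nu, tolerance = tol)
}
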