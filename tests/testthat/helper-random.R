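# random generators used across the property-style tests

# one valid orthopair (mu, nu) under mu^q + nu^q <= 1, by rejection
rand_pair <- function(n, q) {
  mu <- nu <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    a <- runif(length(need)); b <- runif(length(need))
    ok <- a^q + b^q <= 1
    mu[need[ok]] <- a[ok]; nu[need[ok]] <- b[ok]
    need <- need[!ok]
  }
  list(mu = mu, nu = nu)
}

# a random qrf2ln vector of length n (continuous linguistic values)
rand_qrf2ln <- function(n, q = 3, S = lts()) {
  pr <- rand_pair(n, q)
  v <- runif(n, 0, S$maxIndex)
  tt <- toTwoTuple(v, S)
  qrf2ln(tt$index, tt$delta, pr$mu, pr$nu, q = q, lts = S)
}

# componentwise ordered pair of qrf2ln vectors (small <= large)
rand_ordered_pair <- function(n, q = 3, S = lts()) {
  big <- rand_qrf2ln(n, q, S)
  u <- runif(n); v <- runif(n); w <- runif(n)
  vSmall <- (big$index + big$delta) * u
  muSmall <- big$mu * v
  headroom <- pmax(0, (1 - muSmall^q))^(1 / q) - big$nu
  nuSmall <- big$nu + w * pmax(0, headroom)
  tt <- toTwoTuple(vSmall, S)
  small <- qrf2ln(tt$index, tt$delta, muSmall, nuSmall, q = q, lts = S)
  list(small = small, large = big)
}

rand_weights <- function(n) {
  w <- runif(n)
  w / sum(w)
}
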