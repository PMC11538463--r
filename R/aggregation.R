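#' Prioritized averaging weights
#'
#' Priority-degree weights in the sense of the prioritized averaging (PA)
#' operator: for items given in priority order with satisfaction scores
#' \eqn{s_1, s_2, \dots \in [0, 1]}, the degrees are \eqn{T_1 = 1} and
#' \eqn{T_i = \prod_{t < i} s_t}, and the weights are \eqn{w = T / \sum T}.
#' An item is thus discounted by how poorly all strictly higher-priority
#' items score.
#'
#' @param scores numeric vector of scores in \eqn{[0, 1]} in priority order
#'   (highest priority first).
#' @param digits optional; round the normalized weights to this many decimal
#'   places. Aggregations published in tabular workflows often consume the
#'   weights at their tabulated precision, and rounding here reproduces that.
#' @return A list of class \code{priorityWeights} with components \code{T}
#'   (priority degrees) and \code{w} (normalized weights).
#' @examples
#' priorityWeights(c(0.4, 0.5, 0.2))  # T = (1, 0.4, 0.2)
#' @export
priorityWeights <- function(scores, digits = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop("`scores` must be non-empty", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("`scores` must lie in [0, 1]", call. = FALSE)
  }
  n <- length(scores)
  Tdeg <- c(1, cumprod(scores[-n]))
  w <- Tdeg / sum(Tdeg)
  if (!is.null(digits)) w <- round(w, digits)
  structure(list(T = Tdeg, w = w), class = "priorityWeights")
}

#' @export
print.priorityWeights <- function(x, ...) {
  cat("Priority degrees T:", formatC(x$T, format = "g"), "\n")
  cat("Weights w:         ", formatC(x$w, format = "g"), "\n")
  invisible(x)
}

weights_vector <- function(weights, n) {
  w <- if (inherits(weights, "priorityWeights")) weights$w else
    as.numeric(weights)
  if (length(w) != n) {
    stop("got ", length(w), " weights for ", n, " values", call. = FALSE)
  }
  w
}

#' Crisp Maclaurin symmetric means
#'
#' The Maclaurin symmetric mean of order k of non-negative numbers,
#' \eqn{\mathrm{MSM}^{(k)}(x) = (\binom{n}{k}^{-1} \sum_{i_1 < \dots < i_k}
#' \prod_j x_{i_j})^{1/k}}, and its dual
#' \eqn{\mathrm{DMSM}^{(k)}(x) = \frac{1}{k} (\prod_{i_1 < \dots < i_k}
#' \sum_j x_{i_j})^{1 / \binom{n}{k}}}, both by direct enumeration of the
#' k-subsets. They interpolate between the arithmetic/geometric means
#' (k = 1) and the geometric/arithmetic means (k = n), capturing
#' interrelations among any k inputs. These serve as the scalar backbone
#' (and test oracles) of the fuzzy operators.
#'
#' @param x numeric vector of non-negative values.
#' @param k order of the mean, \eqn{1 \le k \le length(x)}.
#' @return A single numeric value.
#' @examples
#' crispMSM(c(1, 2, 3), 2)   # ((2 + 3 + 6) / 3)^(1/2)
#' crispDMSM(c(1, 2, 3), 2)  # (1/2) * (3 * 4 * 5)^(1/3)
#' @export
crispMSM <- function(x, k) {
  n <- length(x)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= ", n, call. = FALSE)
  sub <- utils::combn(n, k)
  mean(apply(sub, 2L, function(i) prod(x[i])))^(1 / k)
}

#' @rdname crispMSM
#' @export
crispDMSM <- function(x, k) {
  n <- length(x)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= ", n, call. = FALSE)
  sub <- utils::combn(n, k)
  prod(apply(sub, 2L, function(i) sum(x[i])))^(1 / ncol(sub)) / k
}

# extract (v, mu, nu, q, lts) arrays from a qrf2ln vector, with checks
agg_prep <- function(values, weights, k) {
  if (!inherits(values, "qrf2ln")) {
    stop("`values` must be a qrf2ln vector", call. = FALSE)
  }
  n <- length(values)
  if (n == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= ", n, call. = FALSE)
  list(v = lvalue(values), mu = values$mu, nu = values$nu,
       q = attr(values, "q"), lts = attr(values, "lts"),
       w = weights_vector(weights, n), n = n,
       sub = utils::combn(n, as.integer(k)))
}

#' Prioritized Maclaurin symmetric mean of q-RF2L numbers
#'
#' \code{qrf2lPMSM} aggregates q-RF2L numbers given in priority order with
#' priority weights \eqn{w}: each argument is first attenuated by its weight
#' through the power law \eqn{\partial_i^{w_i}}, then the order-k Maclaurin
#' symmetric mean is taken under the operational laws,
#' \deqn{\Big(\tbinom{n}{k}^{-1} \bigoplus_{i_1 < \dots < i_k}
#'   \bigotimes_{j = 1}^{k} \partial_{i_j}^{w_{i_j}}\Big)^{1/k}.}
#' \code{qrf2lPDMSM} is the dual: weights enter through scalar
#' multiplication and the sum/product roles swap,
#' \deqn{\frac{1}{k}\Big(\bigotimes_{i_1 < \dots < i_k}
#'   \bigoplus_{j = 1}^{k} (w_{i_j} \partial_{i_j})\Big)^{1/\binom{n}{k}}.}
#' Both are evaluated through closed-form expressions equivalent to the
#' stepwise law evaluation; the linguistic component is computed in the
#' aggregation-value domain, where the result is always within the label
#' range. The operators are monotone and bounded by the min/max envelopes,
#' but deliberately not idempotent: prioritization trades idempotency for
#' discounting by the priority weights.
#'
#' @param values a \code{qrf2ln} vector in priority order.
#' @param weights a \code{priorityWeights} object or a numeric weight vector
#'   of the same length.
#' @param k order of the symmetric mean; the default 2 is the smallest order
#'   that captures pairwise interrelation.
#' @return A \code{qrf2ln} vector of length 1.
#' @examples
#' # three experts' views on one cell, highest priority first
#' x <- qrf2ln(c(2, 5, 1), 0, c(0.6, 0.6, 0.5), c(0.3, 0.5, 0.4))
#' w <- priorityWeights(score(x))
#' qrf2lPMSM(x, w, k = 2)
#' qrf2lPDMSM(x, w, k = 2)
#' @export
qrf2lPMSM <- function(values, weights, k = 2) {
  p <- agg_prep(values, weights, k)
  C <- ncol(p$sub); q <- p$q
  # weighted arguments: v^w, mu^(q w) (as q-th powers), (1-nu^q)^w
  vW <- p$v^p$w
  muQW <- p$mu^(q * p$w)
  nuC <- (1 - p$nu^q)^p$w          # complement-space non-membership
  vAcc <- 0; muProd <- 1; nuProd <- 1
  for (s in seq_len(C)) {
    i <- p$sub[, s]
    vAcc <- vAcc + prod(vW[i])
    muProd <- muProd * (1 - prod(muQW[i]))^(1 / C)
    nuProd <- nuProd * (1 - prod(nuC[i]))^(1 / C)
  }
  v <- (vAcc / C)^(1 / k)
  mu <- (1 - muProd)^(1 / (q * k))
  nu <- (1 - (1 - nuProd)^(1 / k))^(1 / q)
  new_qrf2ln(v, mu, nu, q, p$lts, validate = FALSE)
}

#' @rdname qrf2lPMSM
#' @export
qrf2lPDMSM <- function(values, weights, k = 2) {
  p <- agg_prep(values, weights, k)
  C <- ncol(p$sub); q <- p$q
  vW <- p$w * p$v
  muC <- (1 - p$mu^q)^p$w          # complement-space membership
  nuQW <- p$nu^(q * p$w)
  vProd <- 1; muProd <- 1; nuProd <- 1
  for (s in seq_len(C)) {
    i <- p$sub[, s]
    vProd <- vProd * sum(vW[i])
    muProd <- muProd * (1 - prod(muC[i]))      # subset-sum membership^q
    nuProd <- nuProd * (1 - prod(nuQW[i]))^(1 / C)
  }
  v <- vProd^(1 / C) / k
  mu <- (1 - (1 - muProd^(1 / C))^(1 / k))^(1 / q)
  nu <- (1 - nuProd)^(1 / (q * k))
  new_qrf2ln(v, mu, nu, q, p$lts, validate = FALSE)
}

#' Reduced special cases of the prioritized symmetric means
#'
#' At k = 1, 2, 3 and k = n the general operators reduce to prioritized
#' averaging, Bonferroni-type and geometric forms. These reduced closed
#' forms are implemented independently of the general formula (as separate
#' algebraic simplifications) and agree with \code{qrf2lPMSM} /
#' \code{qrf2lPDMSM} at the matching k.
#'
#' @inheritParams qrf2lPMSM
#' @param case one of \code{"k1"}, \code{"k2"}, \code{"k3"}, \code{"kn"}.
#' @param dual logical; reduce the dual operator instead.
#' @return A \code{qrf2ln} vector of length 1.
#' @export
qrf2lSpecialCase <- function(values, weights,
                             case = c("k1", "k2", "k3", "kn"),
                             dual = FALSE) {
  case <- match.arg(case)
  n <- length(values)
  k <- switch(case, k1 = 1L, k2 = 2L, k3 = 3L, kn = n)
  p <- agg_prep(values, weights, k)
  q <- p$q
  if (!dual) {
    vW <- p$v^p$w; muQW <- p$mu^(q * p$w); nuC <- (1 - p$nu^q)^p$w
    if (case == "k1") {
      # prioritized-averaging form: arithmetic mean of weighted arguments
      v <- mean(vW)
      mu <- (1 - prod((1 - muQW)^(1 / n)))^(1 / q)
      nu <- prod((1 - nuC)^(1 / (q * n)))
    } else if (case == "kn") {
      # single n-subset: prioritized geometric form
      v <- prod(vW)^(1 / n)
      mu <- prod(muQW^(1 / (q * n)))
      nu <- (1 - prod(nuC)^(1 / n))^(1 / q)
    } else {
      # Bonferroni-type forms: explicit sums over pairs/triples
      idx <- utils::combn(n, k)
      C <- ncol(idx)
      v <- (sum(apply(idx, 2L, function(i) prod(vW[i]))) / C)^(1 / k)
      mu <- (1 - prod(apply(idx, 2L, function(i)
        (1 - prod(muQW[i]))^(1 / C))))^(1 / (q * k))
      nu <- (1 - (1 - prod(apply(idx, 2L, function(i)
        (1 - prod(nuC[i]))^(1 / C))))^(1 / k))^(1 / q)
    }
  } else {
    vW <- p$w * p$v; muC <- (1 - p$mu^q)^p$w; nuQW <- p$nu^(q * p$w)
    if (case == "k1") {
      # prioritized geometric-mean form
      v <- prod(vW)^(1 / n)
      mu <- prod((1 - muC)^(1 / (q * n)))
      nu <- (1 - prod((1 - nuQW)^(1 / n)))^(1 / q)
    } else if (case == "kn") {
      # single n-subset: prioritized arithmetic form
      v <- sum(vW) / n
      mu <- (1 - prod(muC)^(1 / n))^(1 / q)
      nu <- prod(nuQW^(1 / (q * n)))
    } else {
      idx <- utils::combn(n, k)
      C <- ncol(idx)
      v <- prod(apply(idx, 2L, function(i) sum(vW[i])))^(1 / C) / k
      mu <- (1 - (1 - prod(apply(idx, 2L, function(i)
        1 - prod(muC[i])))^(1 / C))^(1 / k))^(1 / q)
      nu <- (1 - prod(apply(idx, 2L, function(i)
        (1 - prod(nuQW[i]))^(1 / C))))^(1 / (q * k))
    }
  }
  new_qrf2ln(v, mu, nu, q, p$lts, validate = FALSE)
}

#' q-RF2L Muirhead mean
#'
#' The Muirhead mean with parameter vector \eqn{P}: a symmetric mean over all
#' permutations,
#' \deqn{\Big(\frac{1}{n!} \bigoplus_{\sigma \in S_n} \bigotimes_{j = 1}^{n}
#'   \partial_{\sigma(j)}^{P_j}\Big)^{1 / \sum_j P_j},}
#' evaluated by full permutation enumeration (guarded at \eqn{n \le 8}).
#' With \eqn{P = (1, 0, \dots, 0)} it reduces to the arithmetic mean under
#' the laws; repeated entries in \eqn{P} emphasize interactions of that many
#' arguments. Used as a published comparison method for the pipeline.
#'
#' @param values a \code{qrf2ln} vector.
#' @param P numeric vector of non-negative parameters, one per value, not
#'   all zero.
#' @return A \code{qrf2ln} vector of length 1.
#' @export
qrf2lMuirhead <- function(values, P) {
  if (!inherits(values, "qrf2ln")) {
    stop("`values` must be a qrf2ln vector", call. = FALSE)
  }
  n <- length(values)
  if (n > 8L) {
    stop("permutation enumeration is limited to n <= 8 arguments, got ", n,
         call. = FALSE)
  }
  P <- as.numeric(P)
  if (length(P) != n) stop("`P` must have one entry per value", call. = FALSE)
  if (any(P < 0) || all(P == 0)) {
    stop("`P` must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  q <- attr(values, "q"); ltsx <- attr(values, "lts")
  v <- lvalue(values); mu <- values$mu; nu <- values$nu
  perms <- permutations_of(n)
  np <- nrow(perms)
  vAcc <- 0; muProd <- 1; nuProd <- 1
  for (r in seq_len(np)) {
    sg <- perms[r, ]
    vAcc <- vAcc + prod(v[sg]^P)
    muProd <- muProd * (1 - prod(mu[sg]^(q * P)))^(1 / np)
    nuProd <- nuProd * (1 - prod((1 - nu[sg]^q)^P))^(1 / np)
  }
  sP <- sum(P)
  vOut <- (vAcc / np)^(1 / sP)
  muOut <- (1 - muProd)^(1 / (q * sP))
  nuOut <- (1 - (1 - nuProd)^(1 / sP))^(1 / q)
  new_qrf2ln(vOut, muOut, nuOut, q, ltsx, validate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- sub[r, ] + (sub[r, ] >= i)
      out[row, ] <- c(i, rest)
      row <- row + 1L
    }
  }
  out
}

#' q-rung orthopair fuzzy Maclaurin symmetric mean
#'
#' The linguistic-free MSM on plain q-ROF pairs \eqn{\langle m, n \rangle}:
#' the order-k Maclaurin symmetric mean under the q-ROF algebraic laws. This
#' is the comparison method that discards the linguistic terms, retained here
#' to reproduce the validation study.
#'
#' @param mu,nu numeric vectors of membership and non-membership grades with
#'   \eqn{m^q + n^q \le 1}.
#' @param k order of the mean.
#' @param q the rung.
#' @return A list with elements \code{mu}, \code{nu} and \code{score}, where
#'   the score is the q-ROF score \eqn{(1 + m^q - n^q) / 2}.
#' @export
qrofMSM <- function(mu, nu, k = 2, q = 3) {
  n <- length(mu)
  if (length(nu) != n) stop("`mu` and `nu` lengths differ", call. = FALSE)
  if (any(mu < 0 | mu > 1 | nu < 0 | nu > 1) ||
      any(mu^q + nu^q > 1 + 1e-9)) {
    stop("invalid q-ROF pairs for q = ", q, call. = FALSE)
  }
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= ", n, call. = FALSE)
  sub <- utils::combn(n, as.integer(k))
  C <- ncol(sub)
  muProd <- 1; nuProd <- 1
  for (s in seq_len(C)) {
    i <- sub[, s]
    muProd <- muProd * (1 - prod(mu[i]^q))^(1 / C)
    nuProd <- nuProd * (1 - prod((1 - nu[i]^q)))^(1 / C)
  }
  muOut <- (1 - muProd)^(1 / (q * k))
  nuOut <- (1 - (1 - nuProd)^(1 / k))^(1 / q)
  list(mu = muOut, nu = nuOut, score = (1 + muOut^q - nuOut^q) / 2)
}
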