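#' q-rung orthopair fuzzy 2-tuple linguistic numbers
#'
#' A q-RF2L number couples a linguistic 2-tuple \eqn{(s_r, \Delta)} with an
#' orthopair \eqn{\langle m, n \rangle} of membership and non-membership
#' grades constrained by \eqn{m^q + n^q \le 1} for the rung \eqn{q \ge 1}.
#' The rung widens the admissible orthopair region: judgements such as
#' \eqn{\langle 0.8, 0.9 \rangle}, invalid for intuitionistic (\eqn{q = 1})
#' or Pythagorean (\eqn{q = 2}) pairs, become expressible at higher q.
#' Objects of this class are vectors: all fields recycle to a common length.
#'
#' @param index integer vector of linguistic label indices in
#'   \eqn{[0, g - 1]}.
#' @param delta numeric vector of symbolic translations in \eqn{[-0.5, 0.5)}.
#' @param mu,nu membership and non-membership grades in \eqn{[0, 1]}.
#' @param q the rung, an integer-valued scalar \eqn{\ge 1}, shared by all
#'   elements.
#' @param lts the linguistic term set the indices refer to.
#' @return A vector of class \code{qrf2ln}.
#' @examples
#' a <- qrf2ln(2, 0, 0.6, 0.3)
#' score(a)
#' accuracy(a)
#' @export
qrf2ln <- function(index, delta = 0, mu, nu, q = 3, lts = qrf2l::lts()) {
  assert_lts(lts)
  if (length(q) != 1L || is.na(q) || q < 1) {
    stop("`q` must be a single number >= 1", call. = FALSE)
  }
  n <- max(length(index), length(delta), length(mu), length(nu))
  x <- list(index = as.integer(rep_len(index, n)),
            delta = as.numeric(rep_len(delta, n)),
            mu = as.numeric(rep_len(mu, n)),
            nu = as.numeric(rep_len(nu, n)))
  out <- structure(x, q = as.numeric(q), lts = lts, class = "qrf2ln")
  validate_qrf2ln(out)
  out
}

# internal constructor from numeric aggregation values; skips validation when
# an aggregation formula guarantees the invariants
new_qrf2ln <- function(value, mu, nu, q, lts, validate = TRUE) {
  if (validate) {
    tt <- toTwoTuple(value, lts)
    out <- structure(list(index = tt$index, delta = tt$delta,
                          mu = mu, nu = nu),
                     q = q, lts = lts, class = "qrf2ln")
    validate_qrf2ln(out)
  } else {
    # intermediate of an aggregation formula: the linguistic aggregation
    # value may transiently leave [0, g-1]
    r <- round_half_up(value)
    out <- structure(list(index = as.integer(r), delta = value - r,
                          mu = mu, nu = nu),
                     q = q, lts = lts, class = "qrf2ln")
  }
  out
}

validate_qrf2ln <- function(x, where = NULL) {
  q <- attr(x, "q"); L <- attr(x, "lts")$maxIndex
  loc <- function(i) if (is.null(where)) paste0("element ", i) else where(i)
  tol <- 1e-9
  bad <- which(x$index < 0L | x$index > L)
  if (length(bad)) stop(loc(bad[1L]), ": label index ", x$index[bad[1L]],
                        " outside [0, ", L, "]", call. = FALSE)
  bad <- which(x$delta < -0.5 - tol | x$delta >= 0.5)
  if (length(bad)) stop(loc(bad[1L]), ": symbolic translation ",
                        x$delta[bad[1L]], " outside [-0.5, 0.5)",
                        call. = FALSE)
  v <- x$index + x$delta
  bad <- which(v < -tol | v > L + tol)
  if (length(bad)) stop(loc(bad[1L]), ": linguistic value ", v[bad[1L]],
                        " outside [0, ", L, "]", call. = FALSE)
  bad <- which(x$mu < -tol | x$mu > 1 + tol | x$nu < -tol | x$nu > 1 + tol)
  if (length(bad)) stop(loc(bad[1L]),
                        ": membership grades must lie in [0, 1]",
                        call. = FALSE)
  bad <- which(x$mu^q + x$nu^q > 1 + tol)
  if (length(bad)) {
    i <- bad[1L]
    stop(loc(i), ": rung constraint violated, ", x$mu[i], "^", q, " + ",
         x$nu[i], "^", q, " = ", format(x$mu[i]^q + x$nu[i]^q), " > 1",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
length.qrf2ln <- function(x) length(x$index)

#' @export
`[.qrf2ln` <- function(x, i) {
  structure(list(index = x$index[i], delta = x$delta[i],
                 mu = x$mu[i], nu = x$nu[i]),
            q = attr(x, "q"), lts = attr(x, "lts"), class = "qrf2ln")
}

#' @export
format.qrf2ln <- function(x, digits = 4, ...) {
  sprintf("((s%d, %s), <%s, %s>)", x$index,
          formatC(round(x$delta, digits), format = "g"),
          formatC(round(x$mu, digits), format = "g"),
          formatC(round(x$nu, digits), format = "g"))
}

#' @export
print.qrf2ln <- function(x, ...) {
  cat("q-RF2L numbers (q = ", attr(x, "q"), ", g = ",
      attr(x, "lts")$cardinality, "):\n", sep = "")
  cat(paste0("  ", format(x, ...), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
c.qrf2ln <- function(...) {
  xs <- list(...)
  q <- attr(xs[[1L]], "q"); lts <- attr(xs[[1L]], "lts")
  for (x in xs) check_compatible(xs[[1L]], x)
  structure(list(index = unlist(lapply(xs, `[[`, "index")),
                 delta = unlist(lapply(xs, `[[`, "delta")),
                 mu = unlist(lapply(xs, `[[`, "mu")),
                 nu = unlist(lapply(xs, `[[`, "nu"))),
            q = q, lts = lts, class = "qrf2ln")
}

check_compatible <- function(a, b) {
  if (!identical(attr(a, "q"), attr(b, "q"))) {
    stop("operands have different rungs q (", attr(a, "q"), " vs ",
         attr(b, "q"), ")", call. = FALSE)
  }
  if (attr(a, "lts")$cardinality != attr(b, "lts")$cardinality) {
    stop("operands refer to linguistic term sets of different cardinality",
         call. = FALSE)
  }
  invisible(TRUE)
}

# numeric linguistic value ("varsigma" of the 2-tuple)
lvalue <- function(x) x$index + x$delta

#' Refusal grade
#'
#' The refusal (indeterminacy) grade
#' \eqn{\pi = (1 - m^q - n^q)^{1/q} \in [0, 1]} of each element.
#'
#' @param x a \code{qrf2ln} vector.
#' @return numeric vector.
#' @export
refusal <- function(x) {
  q <- attr(x, "q")
  pmax(0, 1 - x$mu^q - x$nu^q)^(1 / q)
}

#' Score and accuracy of q-RF2L numbers
#'
#' The score \eqn{S(\partial) = \varsigma \, (1 + m^q - n^q) / (2g)} maps a
#' q-RF2L number to \eqn{[0, 1]}; \eqn{\varsigma = r + \Delta} is the numeric
#' value of the linguistic part and \eqn{g} the cardinality of the term set.
#' The accuracy \eqn{A(\partial) = \varsigma \, (m^q + n^q)} measures how much
#' of the orthopair mass is committed and breaks score ties.
#'
#' @param x a \code{qrf2ln} vector.
#' @return numeric vector.
#' @examples
#' score(qrf2ln(2, 0, 0.6, 0.3))      # 2 * 1.189 / 14
#' accuracy(qrf2ln(2, 0, 0.6, 0.3))
#' @export
score <- function(x) {
  UseMethod("score")
}

#' @export
score.qrf2ln <- function(x) {
  q <- attr(x, "q"); g <- attr(x, "lts")$cardinality
  if (g <= 1L) stop("degenerate linguistic term set", call. = FALSE)
  lvalue(x) * (1 + x$mu^q - x$nu^q) / (2 * g)
}

#' @rdname score
#' @export
accuracy <- function(x) {
  UseMethod("accuracy")
}

#' @export
accuracy.qrf2ln <- function(x) {
  q <- attr(x, "q")
  lvalue(x) * (x$mu^q + x$nu^q)
}

#' Compare q-RF2L numbers
#'
#' Total order on q-RF2L numbers: the score is the primary key; ties are
#' broken by accuracy. By convention the element with the higher accuracy is
#' the greater one, matching the mainstream orthopair-fuzzy literature; set
#' \code{accuracyHigherWins = FALSE} for the opposite orientation, which some
#' sources print.
#'
#' @param a,b \code{qrf2ln} vectors of equal length (or length one), sharing
#'   q and the term set.
#' @param accuracyHigherWins logical; orientation of the accuracy tie-break.
#' @param tol numeric tolerance for equality of the keys.
#' @return integer vector with elements -1 (\code{a < b}), 0 (equal) or
#'   1 (\code{a > b}).
#' @export
compareQ <- function(a, b, accuracyHigherWins = TRUE, tol = 1e-9) {
  check_compatible(a, b)
  sa <- score(a); sb <- score(b)
  aa <- accuracy(a); ab <- accuracy(b)
  out <- integer(max(length(sa), length(sb)))
  ds <- sa - sb; da <- aa - ab
  out[ds > tol] <- 1L
  out[ds < -tol] <- -1L
  tie <- abs(ds) <= tol
  sgn <- if (accuracyHigherWins) 1L else -1L
  out[tie & da > tol] <- sgn
  out[tie & da < -tol] <- -sgn
  out
}

# ---- operational laws -------------------------------------------------------
#
# The linguistic component of each law is computed on the numeric aggregation
# values r + delta and converted back with toTwoTuple. Product and power can
# push the aggregation value above g - 1; the user-facing functions clamp it
# into range with a warning (the laws are then total functions), while the
# aggregation operators evaluate their closed forms in the unclamped
# aggregation-value domain, where all final results are provably in range.

law_clamp <- function(v, lts, clamp, what) {
  L <- lts$maxIndex
  if (clamp && any(v < 0 | v > L)) {
    warning(what, ": linguistic value outside [0, ", L,
            "], clamped into range", call. = FALSE)
    v <- pmin(pmax(v, 0), L)
  }
  v
}

#' Operational laws for q-RF2L numbers
#'
#' The five basic laws: algebraic sum \code{qAdd} (\eqn{\oplus}), algebraic
#' product \code{qMultiply} (\eqn{\otimes}), scalar multiple
#' \code{qScale} (\eqn{\alpha \partial}), power \code{qPower}
#' (\eqn{\partial^\alpha}) and complement \code{qComplement} (swap of
#' membership and non-membership). Membership grades combine through the
#' algebraic t-norm/t-conorm on the q-th powers, so every law is closed under
#' the rung constraint. The linguistic parts combine arithmetically on the
#' aggregation values; product and power may leave the label range, in which
#' case the result is clamped with a warning unless \code{clamp = FALSE}
#' (useful when the calls are intermediate steps of an aggregation formula
#' whose final value is known to be in range).
#'
#' @param a,b \code{qrf2ln} vectors sharing q and the term set.
#' @param alpha a positive scalar.
#' @param clamp logical; clamp out-of-range linguistic values (with a
#'   warning) instead of failing validation.
#' @return A \code{qrf2ln} vector.
#' @examples
#' a <- qrf2ln(2, 0, 0.6, 0.3); b <- qrf2ln(3, 0, 0.4, 0.5)
#' qAdd(a, b)
#' qScale(2, a)
#' qComplement(qComplement(a))
#' @export
qAdd <- function(a, b, clamp = TRUE) {
  check_compatible(a, b)
  q <- attr(a, "q"); lts <- attr(a, "lts")
  v <- law_clamp(lvalue(a) + lvalue(b), lts, clamp, "qAdd")
  new_qrf2ln(v,
             (a$mu^q + b$mu^q - a$mu^q * b$mu^q)^(1 / q),
             a$nu * b$nu, q, lts, validate = clamp)
}

#' @rdname qAdd
#' @export
qMultiply <- function(a, b, clamp = TRUE) {
  check_compatible(a, b)
  q <- attr(a, "q"); lts <- attr(a, "lts")
  v <- law_clamp(lvalue(a) * lvalue(b), lts, clamp, "qMultiply")
  new_qrf2ln(v, a$mu * b$mu,
             (a$nu^q + b$nu^q - a$nu^q * b$nu^q)^(1 / q),
             q, lts, validate = clamp)
}

#' @rdname qAdd
#' @export
qScale <- function(alpha, a, clamp = TRUE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  q <- attr(a, "q"); lts <- attr(a, "lts")
  v <- law_clamp(alpha * lvalue(a), lts, clamp, "qScale")
  new_qrf2ln(v, (1 - (1 - a$mu^q)^alpha)^(1 / q), a$nu^alpha,
             q, lts, validate = clamp)
}

#' @rdname qAdd
#' @export
qPower <- function(a, alpha, clamp = TRUE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  q <- attr(a, "q"); lts <- attr(a, "lts")
  v <- law_clamp(lvalue(a)^alpha, lts, clamp, "qPower")
  new_qrf2ln(v, a$mu^alpha, (1 - (1 - a$nu^q)^alpha)^(1 / q),
             q, lts, validate = clamp)
}

#' @rdname qAdd
#' @export
qComplement <- function(a) {
  structure(list(index = a$index, delta = a$delta, mu = a$nu, nu = a$mu),
            q = attr(a, "q"), lts = attr(a, "lts"), class = "qrf2ln")
}

#' Hamming distance between q-RF2L numbers
#'
#' \eqn{d(\partial_1, \partial_2) = |(1 + m_1^q - n_1^q)\varsigma_1 -
#' (1 + m_2^q - n_2^q)\varsigma_2| / (2g)}: the absolute difference of the
#' score numerators, normalized by twice the term-set cardinality so that
#' \eqn{d \in [0, 1]}.
#'
#' @param a,b \code{qrf2ln} vectors sharing q and the term set.
#' @return numeric vector of distances.
#' @export
hammingDistance <- function(a, b) {
  check_compatible(a, b)
  q <- attr(a, "q"); g <- attr(a, "lts")$cardinality
  abs((1 + a$mu^q - a$nu^q) * lvalue(a) -
      (1 + b$mu^q - b$nu^q) * lvalue(b)) / (2 * g)
}

# ---- canonical text form ----------------------------------------------------

#' Serialize and parse the canonical cell text form
#'
#' Cells of panel files use the text form \code{"s<r>:<delta>|<mu>,<nu>"},
#' e.g. \code{"s2:0.0|0.6,0.3"}. The delta part may be omitted
#' (\code{"s2|0.6,0.3"}), defaulting to 0.
#'
#' @param x a \code{qrf2ln} vector (for \code{formatCell}).
#' @param text character vector of cell strings (for \code{parseCell}).
#' @param q,lts rung and term set used to validate the parsed values.
#' @return \code{formatCell}: character vector. \code{parseCell}: a
#'   \code{qrf2ln} vector.
#' @examples
#' parseCell("s2:0.0|0.6,0.3")
#' formatCell(qrf2ln(2, 0, 0.6, 0.3))
#' @export
formatCell <- function(x) {
  sprintf("s%d:%.15g|%.15g,%.15g", x$index, x$delta, x$mu, x$nu)
}

#' @rdname formatCell
#' @export
parseCell <- function(text, q = 3, lts = qrf2l::lts()) {
  re <- "^s([0-9]+)(?::(-?[0-9.]+(?:[eE]-?[0-9]+)?))?\\|([0-9.eE-]+),([0-9.eE-]+)$"
  m <- regmatches(text, regexec(re, text))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad)) {
    stop("malformed cell '", text[bad[1L]],
         "', expected \"s<r>:<delta>|<mu>,<nu>\"", call. = FALSE)
  }
  f <- function(i) vapply(m, function(g) {
    s <- g[i + 1L]
    if (i == 2L && s == "") 0 else as.numeric(s)
  }, numeric(1))
  qrf2ln(f(1L), f(2L), f(3L), f(4L), q = q, lts = lts)
}
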