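#' Linguistic term set
#'
#' Creates an ordered linguistic term set \eqn{S = \{s_0, \dots, s_{g-1}\}}
#' of odd cardinality \eqn{g}. The terms are totally ordered by index;
#' \code{s_0} is the worst judgement and \code{s_{g-1}} the best. The default
#' seven-term set spans "extremely poor" to "extremely good", the granularity
#' commonly used for expert elicitation.
#'
#' @param cardinality number of terms \eqn{g}; must be an odd integer
#'   \eqn{\ge 3}. Ignored when \code{labels} is given.
#' @param labels optional character vector of term names, ordered from worst
#'   to best; its length must be odd.
#' @return An object of class \code{qrf2l_lts} with elements
#'   \code{cardinality} (\eqn{g}), \code{maxIndex} (\eqn{g - 1}) and
#'   \code{labels}.
#' @examples
#' S <- lts()
#' S$maxIndex
#' lts(5)
#' @export
lts <- function(cardinality = 7, labels = NULL) {
  if (!is.null(labels)) {
    labels <- as.character(labels)
    cardinality <- length(labels)
  }
  if (length(cardinality) != 1L || is.na(cardinality) ||
      cardinality != as.integer(cardinality)) {
    stop("`cardinality` must be a single integer", call. = FALSE)
  }
  cardinality <- as.integer(cardinality)
  if (cardinality < 3L || cardinality %% 2L == 0L) {
    stop("a linguistic term set must have odd cardinality >= 3, got ",
         cardinality, call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (cardinality == 7L) {
      c("extremely poor", "very poor", "poor", "medium",
        "good", "very good", "extremely good")
    } else {
      paste0("s", seq_len(cardinality) - 1L)
    }
  }
  structure(
    list(cardinality = cardinality, maxIndex = cardinality - 1L,
         labels = labels),
    class = "qrf2l_lts"
  )
}

#' @export
print.qrf2l_lts <- function(x, ...) {
  cat("Linguistic term set, cardinality ", x$cardinality, ":\n", sep = "")
  cat(paste0("  s", seq_along(x$labels) - 1L, " = ", x$labels,
             collapse = "\n"), "\n")
  invisible(x)
}

is_lts <- function(x) inherits(x, "qrf2l_lts")

assert_lts <- function(x) {
  if (!is_lts(x)) stop("`lts` must be created with lts()", call. = FALSE)
  x
}

# round-half-up: ties at .5 go to the upper label so that the symbolic
# translation delta = theta - r always lies in [-0.5, 0.5)
round_half_up <- function(x) floor(x + 0.5)

#' Two-tuple linguistic representation
#'
#' \code{toTwoTuple} converts an aggregation value \eqn{\vartheta \in [0, g-1]}
#' to its equivalent linguistic 2-tuple \eqn{(s_r, \Delta)} with
#' \eqn{r = \mathrm{round}(\vartheta)} (ties rounded up) and
#' \eqn{\Delta = \vartheta - r \in [-0.5, 0.5)}. \code{fromTwoTuple} is its
#' inverse, \eqn{(s_r, \Delta) \mapsto r + \Delta}. The two functions form a
#' bijection between \eqn{[0, g-1]} and the set of valid 2-tuples, so no
#' information is lost when linguistic judgements are aggregated numerically.
#'
#' @param theta numeric vector of aggregation values in \eqn{[0, g-1]}.
#' @param lts a linguistic term set from [lts()].
#' @return \code{toTwoTuple} returns an object of class \code{qrf2l_tt}: a
#'   list with integer vector \code{index} and numeric vector \code{delta}.
#'   \code{fromTwoTuple} returns a numeric vector.
#' @examples
#' S <- lts()
#' toTwoTuple(2.6, S)          # (s3, -0.4)
#' fromTwoTuple(toTwoTuple(2.6, S))
#' @export
toTwoTuple <- function(theta, lts = qrf2l::lts()) {
  assert_lts(lts)
  theta <- as.numeric(theta)
  if (any(is.na(theta))) stop("`theta` contains NA", call. = FALSE)
  L <- lts$maxIndex
  if (any(theta < 0 | theta > L)) {
    bad <- theta[theta < 0 | theta > L][1L]
    stop("aggregation value ", format(bad), " lies outside [0, ", L, "]",
         call. = FALSE)
  }
  r <- round_half_up(theta)
  # round_half_up(L - eps) can reach L + something only at theta = L exactly
  r <- pmin(r, L)
  structure(list(index = as.integer(r), delta = theta - r, lts = lts),
            class = "qrf2l_tt")
}

#' @rdname toTwoTuple
#' @param tt a 2-tuple created by \code{toTwoTuple}.
#' @export
fromTwoTuple <- function(tt) {
  if (!inherits(tt, "qrf2l_tt")) {
    stop("`tt` must be a qrf2l_tt object", call. = FALSE)
  }
  tt$index + tt$delta
}

#' @export
print.qrf2l_tt <- function(x, ...) {
  cat(paste0("(s", x$index, ", ", formatC(x$delta, format = "g"), ")",
             collapse = " "), "\n")
  invisible(x)
}

#' @export
length.qrf2l_tt <- function(x) length(x$index)
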