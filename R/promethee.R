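#' Pairwise deviations for q-RF2L PROMETHEE II
#'
#' For every ordered pair of alternatives (a, b) and every criterion, the
#' deviation is the difference of the score numerators
#' \eqn{A = \varsigma (1 + m^q - n^q)} mapped back to the label scale,
#' \eqn{\check d_j(a, b) = \tfrac{g}{2} (A_{aj} - A_{bj})}, passed through a
#' preference function. The default Type-I (usual criterion) preference
#' keeps the positive part, so for each unordered pair at most one direction
#' is non-zero and the diagonal is zero.
#'
#' @param collective a collective \code{qrf2lMatrix}.
#' @param preference preference function applied elementwise to the signed
#'   deviations; the default is \code{function(d) pmax(d, 0)}.
#' @return A numeric matrix with one row per ordered pair (labelled
#'   \code{"a>b"}) and one column per criterion.
#' @export
pairwiseDeviations <- function(collective, preference = NULL) {
  if (is.null(preference)) preference <- function(d) pmax(d, 0)
  q <- attr(collective, "q"); g <- attr(collective, "lts")$cardinality
  m <- nrow(collective$index); s <- ncol(collective$index)
  A <- (collective$index + collective$delta) *
    (1 + collective$mu^q - collective$nu^q)
  pairs <- expand_pairs(m)
  out <- matrix(0, nrow(pairs), s)
  for (p in seq_len(nrow(pairs))) {
    out[p, ] <- preference((g / 2) * (A[pairs[p, 1L], ] - A[pairs[p, 2L], ]))
  }
  alts <- attr(collective, "dnames")[[1L]]
  rownames(out) <- paste0(alts[pairs[, 1L]], ">", alts[pairs[, 2L]])
  colnames(out) <- attr(collective, "dnames")[[2L]]
  attr(out, "pairs") <- pairs
  attr(out, "alternatives") <- alts
  out
}

expand_pairs <- function(m) {
  g <- expand.grid(b = seq_len(m), a = seq_len(m))[, 2:1]
  as.matrix(g[g[, 1L] != g[, 2L], , drop = FALSE])
}

#' PROMETHEE II outranking flows
#'
#' Aggregates the per-criterion deviations of each ordered pair into a
#' global preference \eqn{\amalg(a, b) = \sum_j w_j \check d_j(a, b)}, then
#' computes the positive flow \eqn{\Psi^+(a) = \frac{1}{m-1} \sum_b
#' \amalg(a, b)}, the negative flow \eqn{\Psi^-(a) = \frac{1}{m-1} \sum_b
#' \amalg(b, a)} and the net flow \eqn{\Psi = \Psi^+ - \Psi^-}. Because one
#' weight vector is shared by all pairs, the two total flows coincide and
#' the net flows sum to zero exactly. Alternatives are ranked by descending
#' net flow.
#'
#' @param deviations a deviation matrix from [pairwiseDeviations()].
#' @param weights criteria weights, recycled/normalized to sum one; the
#'   default treats the criteria evenly.
#' @return A data frame of class \code{outrankingTable} with columns
#'   \code{alternative}, \code{positive}, \code{negative}, \code{net},
#'   \code{rank}.
#' @examples
#' pan <- examplePanel()
#' col <- aggregateExperts(normalizePanel(pan))
#' flows <- prometheeFlows(pairwiseDeviations(col))
#' @export
prometheeFlows <- function(deviations, weights = NULL) {
  pairs <- attr(deviations, "pairs")
  if (is.null(pairs)) {
    stop("`deviations` must come from pairwiseDeviations()", call. = FALSE)
  }
  s <- ncol(deviations)
  m <- max(pairs)
  if (is.null(weights)) weights <- rep(1 / s, s)
  weights <- as.numeric(weights)
  if (length(weights) != s) {
    stop("need one weight per criterion", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("criteria weights must be non-negative and not all zero",
         call. = FALSE)
  }
  weights <- weights / sum(weights)
  glob <- as.numeric(deviations %*% weights)
  pos <- neg <- numeric(m)
  for (p in seq_len(nrow(pairs))) {
    pos[pairs[p, 1L]] <- pos[pairs[p, 1L]] + glob[p]
    neg[pairs[p, 2L]] <- neg[pairs[p, 2L]] + glob[p]
  }
  pos <- pos / (m - 1); neg <- neg / (m - 1)
  net <- pos - neg
  alts <- attr(deviations, "alternatives") %||% paste0("A", seq_len(m))
  rk <- order(-net, seq_len(m))
  out <- data.frame(alternative = alts, positive = pos, negative = neg,
                    net = net, rank = match(seq_len(m), rk))
  class(out) <- c("outrankingTable", "data.frame")
  out
}

#' @export
print.outrankingTable <- function(x, digits = 4, ...) {
  y <- as.data.frame(unclass(x))
  for (cl in c("positive", "negative", "net")) y[[cl]] <- round(y[[cl]], digits)
  print(y, row.names = FALSE)
  ord <- x$alternative[order(x$rank)]
  cat("ranking:", paste(ord, collapse = " > "), "\n")
  invisible(x)
}
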