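#' Matrices of q-RF2L numbers
#'
#' An alternatives-by-criteria grid of q-RF2L numbers, stored as four
#' parallel numeric matrices. Rows are alternatives, columns criteria in
#' descending priority order.
#'
#' @param index,delta,mu,nu numeric matrices of equal dimension holding the
#'   four components of each cell.
#' @param q the rung shared by all cells.
#' @param lts the linguistic term set.
#' @param dimnames optional list of row (alternative) and column (criterion)
#'   names.
#' @return An object of class \code{qrf2lMatrix}.
#' @export
qrf2lMatrix <- function(index, delta = 0 * index, mu, nu, q = 3,
                        lts = qrf2l::lts(), dimnames = NULL) {
  dims <- dim(index)
  if (is.null(dims) || length(dims) != 2L) {
    stop("`index` must be a matrix", call. = FALSE)
  }
  for (comp in list(delta, mu, nu)) {
    if (!identical(dim(comp), dims)) {
      stop("all component matrices must share the same dimension",
           call. = FALSE)
    }
  }
  if (is.null(dimnames)) {
    dimnames <- list(paste0("A", seq_len(dims[1L])),
                     paste0("C", seq_len(dims[2L])))
  }
  out <- structure(list(index = matrix(as.integer(round(index)), dims[1L]),
                        delta = matrix(as.numeric(delta), dims[1L]),
                        mu = matrix(as.numeric(mu), dims[1L]),
                        nu = matrix(as.numeric(nu), dims[1L])),
                   q = as.numeric(q), lts = assert_lts(lts),
                   dnames = dimnames, class = "qrf2lMatrix")
  validate_qrf2ln(as_qrf2ln(out), where = function(i) {
    paste0("cell (", row(out$index)[i], ", ", col(out$index)[i], ")")
  })
  out
}

#' @export
dim.qrf2lMatrix <- function(x) dim(x$index)

# flatten to a qrf2ln vector (column-major)
as_qrf2ln <- function(m) {
  structure(list(index = as.integer(m$index), delta = as.numeric(m$delta),
                 mu = as.numeric(m$mu), nu = as.numeric(m$nu)),
            q = attr(m, "q"), lts = attr(m, "lts"), class = "qrf2ln")
}

#' Extract a row of a q-RF2L matrix as a vector of numbers
#'
#' @param m a \code{qrf2lMatrix}.
#' @param i row (alternative) index.
#' @return A \code{qrf2ln} vector over the criteria.
#' @export
matrixRow <- function(m, i) {
  structure(list(index = m$index[i, ], delta = m$delta[i, ],
                 mu = m$mu[i, ], nu = m$nu[i, ]),
            q = attr(m, "q"), lts = attr(m, "lts"), class = "qrf2ln")
}

#' @export
print.qrf2lMatrix <- function(x, digits = 4, ...) {
  dn <- attr(x, "dnames")
  cells <- matrix(format(as_qrf2ln(x), digits = digits), nrow(x$index),
                  dimnames = dn)
  cat("q-RF2L matrix (q = ", attr(x, "q"), ", g = ",
      attr(x, "lts")$cardinality, "):\n", sep = "")
  print(cells, quote = FALSE)
  invisible(x)
}

#' Group decision panel
#'
#' Bundles the per-expert q-RF2L decision matrices with the problem
#' structure: expert priority order (first matrix = highest-priority expert),
#' criteria types and priority order (first column = highest-priority
#' criterion), the rung q and the linguistic term set.
#'
#' @param matrices list of \code{qrf2lMatrix} objects of identical shape,
#'   one per expert, ordered by descending expert priority.
#' @param criteriaTypes character vector, one of \code{"benefit"} or
#'   \code{"cost"} per criterion.
#' @param alternatives,criteria,experts optional name vectors.
#' @return An object of class \code{decisionPanel}.
#' @export
decisionPanel <- function(matrices, criteriaTypes = NULL,
                          alternatives = NULL, criteria = NULL,
                          experts = NULL) {
  if (!length(matrices)) stop("`matrices` must be non-empty", call. = FALSE)
  if (!all(vapply(matrices, inherits, TRUE, "qrf2lMatrix"))) {
    stop("`matrices` must be a list of qrf2lMatrix objects", call. = FALSE)
  }
  dims <- dim(matrices[[1L]])
  q <- attr(matrices[[1L]], "q"); lts <- attr(matrices[[1L]], "lts")
  for (t in seq_along(matrices)) {
    m <- matrices[[t]]
    if (!identical(dim(m), dims)) {
      stop("expert matrix ", t, " has shape ", paste(dim(m), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"), call. = FALSE)
    }
    if (attr(m, "q") != q ||
        attr(m, "lts")$cardinality != lts$cardinality) {
      stop("expert matrix ", t, " uses a different q or term set",
           call. = FALSE)
    }
  }
  s <- dims[2L]
  if (is.null(criteriaTypes)) criteriaTypes <- rep("benefit", s)
  criteriaTypes <- match.arg(criteriaTypes, c("benefit", "cost"),
                             several.ok = TRUE)
  if (length(criteriaTypes) != s) {
    stop("need one criterion type per column", call. = FALSE)
  }
  structure(list(
    matrices = matrices,
    criteriaTypes = criteriaTypes,
    alternatives = alternatives %||% attr(matrices[[1L]], "dnames")[[1L]],
    criteria = criteria %||% attr(matrices[[1L]], "dnames")[[2L]],
    experts = experts %||% paste0("E", seq_along(matrices)),
    q = q, lts = lts
  ), class = "decisionPanel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decisionPanel <- function(x, ...) {
  d <- dim(x$matrices[[1L]])
  cat("q-RF2L decision panel: ", d[1L], " alternatives x ", d[2L],
      " criteria x ", length(x$matrices), " experts (q = ", x$q,
      ", g = ", x$lts$cardinality, ")\n", sep = "")
  cat("criteria types:", paste(x$criteriaTypes, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a decision panel
#'
#' Converts cost-type criteria into benefit orientation by replacing their
#' cells with the complement (membership and non-membership swapped);
#' benefit cells are left untouched. The criterion type labels are kept, so
#' the operation is an involution; [waspas()] applies it exactly once.
#'
#' @param panel a \code{decisionPanel}.
#' @return The normalized panel.
#' @export
normalizePanel <- function(panel) {
  cost <- panel$criteriaTypes == "cost"
  if (any(cost)) {
    panel$matrices <- lapply(panel$matrices, function(m) {
      tmp <- m$mu[, cost]
      m$mu[, cost] <- m$nu[, cost]
      m$nu[, cost] <- tmp
      m
    })
  }
  panel
}

# matrix of scores per expert: m x s x p array
panel_scores <- function(panel) {
  p <- length(panel$matrices)
  d <- dim(panel$matrices[[1L]])
  out <- array(0, c(d, p))
  for (t in seq_len(p)) {
    m <- panel$matrices[[t]]
    out[, , t] <- matrix(score(as_qrf2ln(m)), d[1L])
  }
  out
}

#' Expert priority degrees and weights
#'
#' For every cell (i, j), the priority degree of expert t is the product of
#' the scores that all strictly higher-priority experts assigned to that
#' cell: \eqn{T^{(1)}_{ij} = 1}, \eqn{T^{(t)}_{ij} = \prod_{z < t}
#' S(\partial^{(z)}_{ij})}. Normalized per cell to weights that the
#' aggregation consumes.
#'
#' @param panel a normalized \code{decisionPanel}.
#' @param digits decimal places at which the normalized weights are consumed
#'   (see \code{\link{priorityWeights}}); \code{NULL} for full precision.
#' @return A list with arrays \code{T} and \code{w} of dimension
#'   alternatives x criteria x experts.
#' @export
expertPriorityWeights <- function(panel, digits = 2) {
  sc <- panel_scores(panel)
  d <- dim(sc)
  Tarr <- array(0, d); Warr <- array(0, d)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    pw <- priorityWeights(sc[i, j, ], digits = digits)
    Tarr[i, j, ] <- pw$T
    Warr[i, j, ] <- pw$w
  }
  list(T = Tarr, w = Warr)
}

#' Aggregate expert matrices into a collective matrix
#'
#' Fuses the per-expert assessments of each cell with the prioritized
#' Maclaurin symmetric mean (or its dual), using the per-cell expert
#' priority weights.
#'
#' @param panel a normalized \code{decisionPanel}.
#' @param operator \code{"pmsm"} or \code{"pdmsm"}.
#' @param k order of the symmetric mean over experts.
#' @param weightDigits precision at which expert priority weights are
#'   consumed.
#' @return A \code{qrf2lMatrix} of collective assessments.
#' @export
aggregateExperts <- function(panel, operator = c("pmsm", "pdmsm"), k = 2,
                             weightDigits = 2) {
  operator <- match.arg(operator)
  w <- expertPriorityWeights(panel, digits = weightDigits)$w
  d <- dim(panel$matrices[[1L]])
  p <- length(panel$matrices)
  if (k > p) stop("`k` exceeds the number of experts", call. = FALSE)
  idx <- delta <- mu <- nu <- matrix(0, d[1L], d[2L])
  agg <- if (operator == "pmsm") qrf2lPMSM else qrf2lPDMSM
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    vals <- do.call(c, lapply(panel$matrices, function(m) {
      structure(list(index = m$index[i, j], delta = m$delta[i, j],
                     mu = m$mu[i, j], nu = m$nu[i, j]),
                q = panel$q, lts = panel$lts, class = "qrf2ln")
    }))
    r <- agg(vals, w[i, j, ], k = k)
    idx[i, j] <- r$index; delta[i, j] <- r$delta
    mu[i, j] <- r$mu; nu[i, j] <- r$nu
  }
  qrf2lMatrix(idx, delta, mu, nu, q = panel$q, lts = panel$lts,
              dimnames = list(panel$alternatives, panel$criteria))
}

#' Criteria priority degrees and weights
#'
#' Per alternative, the priority degree of criterion j is the product of the
#' collective scores of all strictly higher-priority criteria:
#' \eqn{\tilde T_{i1} = 1}, \eqn{\tilde T_{ij} = \prod_{e < j}
#' S(\partial_{ie})}.
#'
#' @param collective a collective \code{qrf2lMatrix}.
#' @param digits precision at which the normalized weights are consumed.
#' @return A list with matrices \code{T} and \code{w} (alternatives x
#'   criteria).
#' @export
criteriaPriorityWeights <- function(collective, digits = 3) {
  d <- dim(collective)
  sc <- matrix(score(as_qrf2ln(collective)), d[1L])
  Tm <- Wm <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    pw <- priorityWeights(sc[i, ], digits = digits)
    Tm[i, ] <- pw$T
    Wm[i, ] <- pw$w
  }
  list(T = Tm, w = Wm)
}

#' Prioritized WASPAS ranking
#'
#' Runs the full group-decision pipeline: normalization, expert aggregation
#' into a collective matrix, criteria aggregation per alternative through
#' the prioritized sum model (PMSM over criteria) and the prioritized
#' product model (PDMSM over criteria), and the convex combination
#' \eqn{\bowtie_i = \theta S(\bowtie_i^{(1)}) + (1 - \theta)
#' S(\bowtie_i^{(2)})}. Alternatives are ranked by descending
#' \eqn{\bowtie_i}; ties break by the accuracy of the sum model, then by
#' input order.
#'
#' @param panel a \code{decisionPanel}.
#' @param theta aggregating coefficient of decision precision in
#'   \eqn{[0, 1]}; 0.5 balances the two models.
#' @param k order of the symmetric means (both stages).
#' @param collectiveOperator operator used for the expert-aggregation stage;
#'   the published workflow reports both variants.
#' @param weightDigits named numeric vector: decimal places at which the
#'   expert-stage and criteria-stage priority weights are consumed.
#' @return A list of class \code{waspasResult}: the collective matrix,
#'   per-alternative \code{psm} and \code{ppm} scores, \code{combined}
#'   measures, and the \code{ranking} (alternative indices, best first).
#' @examples
#' pan <- examplePanel()
#' res <- waspas(pan, theta = 0.5)
#' res$combined
#' @export
waspas <- function(panel, theta = 0.5, k = 2,
                   collectiveOperator = c("pmsm", "pdmsm"),
                   weightDigits = c(expert = 2, criteria = 3)) {
  if (length(theta) != 1L || is.na(theta) || theta < 0 || theta > 1) {
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  }
  collectiveOperator <- match.arg(collectiveOperator)
  panel <- normalizePanel(panel)
  collective <- aggregateExperts(panel, operator = collectiveOperator, k = k,
                                 weightDigits = weightDigits[["expert"]])
  cw <- criteriaPriorityWeights(collective,
                                digits = weightDigits[["criteria"]])$w
  m <- nrow(collective$index)
  psm <- ppm <- numeric(m)
  psmAcc <- numeric(m)
  for (i in seq_len(m)) {
    row <- matrixRow(collective, i)
    sumModel <- qrf2lPMSM(row, cw[i, ], k = k)
    prodModel <- qrf2lPDMSM(row, cw[i, ], k = k)
    psm[i] <- score(sumModel)
    ppm[i] <- score(prodModel)
    psmAcc[i] <- accuracy(sumModel)
  }
  combined <- theta * psm + (1 - theta) * ppm
  ranking <- order(-combined, -psmAcc, seq_len(m))
  names(psm) <- names(ppm) <- names(combined) <- panel$alternatives
  structure(list(collective = collective, psm = psm, ppm = ppm,
                 combined = combined, ranking = ranking,
                 theta = theta, q = panel$q, k = k,
                 operator = collectiveOperator,
                 alternatives = panel$alternatives),
            class = "waspasResult")
}

#' @export
print.waspasResult <- function(x, digits = 4, ...) {
  cat("Prioritized WASPAS (", x$operator, " collective, theta = ", x$theta,
      ", q = ", x$q, ", k = ", x$k, ")\n", sep = "")
  df <- data.frame(alternative = x$alternatives,
                   psm = round(x$psm, digits),
                   ppm = round(x$ppm, digits),
                   combined = round(x$combined, digits),
                   rank = match(seq_along(x$psm), x$ranking))
  print(df, row.names = FALSE)
  cat("ranking:", paste(x$alternatives[x$ranking], collapse = " > "), "\n")
  invisible(x)
}

#' @rdname waspas
#' @export
as.data.frame.waspasResult <- function(x, ...) {
  data.frame(alternative = x$alternatives, psm = x$psm, ppm = x$ppm,
             combined = x$combined,
             rank = match(seq_along(x$psm), x$ranking),
             row.names = NULL)
}

#' Sensitivity scan over theta and q
#'
#' Re-runs the WASPAS pipeline over grids of the combination coefficient
#' theta and the rung q, recording the combined measures and the induced
#' ranking for every grid point. When q varies, the whole pipeline
#' (including priority weights, which depend on q through the score) is
#' recomputed and every input cell is revalidated against the new rung.
#'
#' @param panel a \code{decisionPanel}.
#' @param thetaGrid,qGrid numeric vectors of grid values.
#' @inheritParams waspas
#' @return A data frame with columns \code{theta}, \code{q}, one combined
#'   measure per alternative, and \code{ranking} (a \code{" > "}-separated
#'   label string).
#' @export
sensitivityScan <- function(panel, thetaGrid = seq(0, 1, by = 0.1),
                            qGrid = panel$q, k = 2,
                            collectiveOperator = c("pmsm", "pdmsm"),
                            weightDigits = c(expert = 2, criteria = 3)) {
  collectiveOperator <- match.arg(collectiveOperator)
  rows <- list()
  for (qq in qGrid) {
    pq <- panel_with_q(panel, qq)
    # endpoint runs give psm/ppm; theta only mixes them (affine)
    base <- waspas(pq, theta = 0.5, k = k,
                   collectiveOperator = collectiveOperator,
                   weightDigits = weightDigits)
    for (th in thetaGrid) {
      comb <- th * base$psm + (1 - th) * base$ppm
      rk <- order(-comb, seq_along(comb))
      rows[[length(rows) + 1L]] <- c(
        list(theta = th, q = qq), as.list(comb),
        list(ranking = paste(panel$alternatives[rk], collapse = " > ")))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

# rebuild a panel under a different rung, revalidating every cell
panel_with_q <- function(panel, q) {
  if (q == panel$q) return(panel)
  panel$matrices <- lapply(panel$matrices, function(m) {
    qrf2lMatrix(m$index, m$delta, m$mu, m$nu, q = q, lts = attr(m, "lts"),
                dimnames = attr(m, "dnames"))
  })
  panel$q <- q
  panel
}
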