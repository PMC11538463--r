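#' Read and write decision panels
#'
#' Panels are stored either as JSON (one object with the term-set
#' cardinality, rung, names and per-expert cell grids) or as a CSV block
#' dialect that mirrors the usual printed layout: criteria as columns,
#' alternatives as rows, one block per expert. Cells use the canonical text
#' form \code{"s<r>:<delta>|<mu>,<nu>"}; every cell is validated against the
#' rung constraint on load, with errors addressed by expert, row and
#' column. The format is inferred from the file extension unless given.
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{readPanel}: a \code{decisionPanel}. \code{writePanel}:
#'   \code{path}, invisibly.
#' @export
readPanel <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "json") read_panel_json(path) else read_panel_csv(path)
}

read_panel_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("cardinality", "q", "criteria", "matrices")) {
    if (is.null(doc[[field]])) {
      stop(path, ": missing field '", field, "'", call. = FALSE)
    }
  }
  ltsx <- lts(doc$cardinality)
  crit <- doc$criteria
  types <- doc$criteriaTypes %||% rep("benefit", length(crit))
  mats <- doc$matrices
  if (is.null(dim(mats)) && is.list(mats)) {
    mats <- lapply(mats, as.matrix)
  } else if (length(dim(mats)) == 3L) {
    mats <- lapply(seq_len(dim(mats)[1L]), function(t) mats[t, , ])
  }
  experts <- doc$experts %||% paste0("E", seq_along(mats))
  alts <- doc$alternatives %||% paste0("A", seq_len(nrow(mats[[1L]])))
  matrices <- lapply(seq_along(mats), function(t) {
    cells_to_matrix(mats[[t]], q = doc$q, lts = ltsx,
                    where = paste0(path, ", expert ", experts[t]),
                    dimnames = list(alts, crit))
  })
  decisionPanel(matrices, criteriaTypes = types, alternatives = alts,
                criteria = crit, experts = experts)
}

cells_to_matrix <- function(cells, q, lts, where, dimnames) {
  cells <- as.matrix(cells)
  m <- nrow(cells); s <- ncol(cells)
  idx <- delta <- mu <- nu <- matrix(0, m, s)
  for (i in seq_len(m)) for (j in seq_len(s)) {
    x <- tryCatch(parseCell(cells[i, j], q = q, lts = lts),
                  error = function(e) {
                    stop(where, ", row ", i, ", column ", j, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    idx[i, j] <- x$index; delta[i, j] <- x$delta
    mu[i, j] <- x$mu; nu[i, j] <- x$nu
  }
  qrf2lMatrix(idx, delta, mu, nu, q = q, lts = lts, dimnames = dimnames)
}

read_panel_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  body <- character()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), "\\s*[:=]\\s*")[[1L]]
      if (length(kv) == 2L) header[[kv[1L]]] <- kv[2L]
    } else {
      body <- c(body, ln)
    }
  }
  for (field in c("cardinality", "q", "experts")) {
    if (is.null(header[[field]])) {
      stop(path, ": missing header line '# ", field, ": ...'", call. = FALSE)
    }
  }
  ltsx <- lts(as.integer(header$cardinality))
  q <- as.numeric(header$q)
  experts <- trimws(strsplit(header$experts, ";")[[1L]])
  p <- length(experts)
  rows <- lapply(body, function(ln) {
    scan(text = ln, what = character(), sep = ",", quote = "\"",
         quiet = TRUE)
  })
  ncol <- length(rows[[1L]])
  if (length(rows) %% p != 0L) {
    stop(path, ": ", length(rows), " data rows are not divisible among ", p,
         " experts", call. = FALSE)
  }
  m <- length(rows) %/% p
  if (any(vapply(rows, length, 1L) != ncol)) {
    ragged <- which(vapply(rows, length, 1L) != ncol)[1L]
    stop(path, ": ragged matrix, data row ", ragged, " has ",
         length(rows[[ragged]]), " cells, expected ", ncol, call. = FALSE)
  }
  types <- if (!is.null(header$criteriaTypes)) {
    trimws(strsplit(header$criteriaTypes, ";")[[1L]])
  } else rep("benefit", ncol)
  crit <- if (!is.null(header$criteria)) {
    trimws(strsplit(header$criteria, ";")[[1L]])
  } else paste0("C", seq_len(ncol))
  alts <- if (!is.null(header$alternatives)) {
    trimws(strsplit(header$alternatives, ";")[[1L]])
  } else paste0("A", seq_len(m))
  matrices <- lapply(seq_len(p), function(t) {
    block <- do.call(rbind, rows[seq((t - 1L) * m + 1L, t * m)])
    cells_to_matrix(trimws(block), q = q, lts = ltsx,
                    where = paste0(path, ", expert ", experts[t]),
                    dimnames = list(alts, crit))
  })
  decisionPanel(matrices, criteriaTypes = types, alternatives = alts,
                criteria = crit, experts = experts)
}

#' @rdname readPanel
#' @param panel a \code{decisionPanel}.
#' @export
writePanel <- function(panel, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cellGrid <- function(m) {
    matrix(formatCell(as_qrf2ln(m)), nrow(m$index))
  }
  if (format == "json") {
    doc <- list(cardinality = panel$lts$cardinality, q = panel$q,
                experts = panel$experts, alternatives = panel$alternatives,
                criteria = panel$criteria,
                criteriaTypes = panel$criteriaTypes,
                matrices = lapply(panel$matrices, cellGrid))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    out <- c(
      paste0("# cardinality: ", panel$lts$cardinality),
      paste0("# q: ", panel$q),
      paste0("# experts: ", paste(panel$experts, collapse = "; ")),
      paste0("# alternatives: ", paste(panel$alternatives, collapse = "; ")),
      paste0("# criteria: ", paste(panel$criteria, collapse = "; ")),
      paste0("# criteriaTypes: ", paste(panel$criteriaTypes, collapse = "; ")),
      unlist(lapply(panel$matrices, function(m) {
        apply(cellGrid(m), 1L, function(r) {
          paste0("\"", r, "\"", collapse = ",")
        })
      }))
    )
    writeLines(out, path)
  }
  invisible(path)
}

#' Validate a panel file
#'
#' Loads a panel file and reports whether it is well-formed and satisfies
#' every invariant (shape, rung constraint, symbolic translation range).
#'
#' @inheritParams readPanel
#' @return \code{TRUE} invisibly on success; otherwise an error describing
#'   the first offending cell.
#' @export
validatePanel <- function(path, format = c("auto", "json", "csv")) {
  readPanel(path, format = match.arg(format))
  invisible(TRUE)
}

#' Generate a random valid decision panel
#'
#' Draws a reproducible random panel for simulation and property testing:
#' label indices uniform on the term set, symbolic translations zero (as in
#' elicited judgements, which always sit on a label), and orthopairs by
#' rejection sampling of \eqn{(m, n)} uniform on the unit square under
#' \eqn{m^q + n^q \le 1}. The defaults mirror the triage case study: five
#' patients, four criteria, three experts, q = 3, a seven-term set.
#'
#' @param m,s,p numbers of alternatives, criteria and experts.
#' @param q the rung.
#' @param cardinality odd cardinality of the term set.
#' @param seed optional integer seed; the same seed yields an identical
#'   panel without disturbing the caller's RNG state.
#' @param randomDelta draw symbolic translations uniform on
#'   \eqn{[-0.5, 0.5)} instead of zero.
#' @return A \code{decisionPanel}.
#' @examples
#' generatePanel(seed = 7)
#' @export
generatePanel <- function(m = 5, s = 4, p = 3, q = 3, cardinality = 7,
                          seed = NULL, randomDelta = FALSE) {
  if (min(m, s, p) < 1) stop("dimensions must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  ltsx <- lts(cardinality)
  draw_pair <- function(n) {
    mu <- nu <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      a <- stats::runif(length(need)); b <- stats::runif(length(need))
      ok <- a^q + b^q <= 1
      mu[need[ok]] <- a[ok]; nu[need[ok]] <- b[ok]
      need <- need[!ok]
    }
    list(mu = mu, nu = nu)
  }
  matrices <- lapply(seq_len(p), function(t) {
    pair <- draw_pair(m * s)
    if (randomDelta) {
      # draw continuous linguistic values so index + delta stays in range
      tt <- toTwoTuple(stats::runif(m * s, 0, ltsx$maxIndex), ltsx)
      idx <- matrix(tt$index, m); del <- matrix(tt$delta, m)
    } else {
      idx <- matrix(sample.int(cardinality, m * s, replace = TRUE) - 1L, m)
      del <- matrix(0, m, s)
    }
    qrf2lMatrix(idx, del, matrix(pair$mu, m), matrix(pair$nu, m),
                q = q, lts = ltsx)
  })
  decisionPanel(matrices)
}

#' The published patient-triage panel
#'
#' The worked example shipped with the package: three admission-service
#' experts in priority order assess five patients on four criteria (disease
#' severity, emergency degree, special-disease priority, medical insurance
#' type, in descending priority), all benefit-type, with q = 3 on a
#' seven-term set. Loaded from the packaged fixture file.
#'
#' @return A \code{decisionPanel}.
#' @examples
#' pan <- examplePanel()
#' waspas(pan)
#' @export
examplePanel <- function() {
  readPanel(system.file("extdata", "triage_panel.csv", package = "qrf2l",
                        mustWork = TRUE))
}

#' The published collective assessment matrix
#'
#' The collective (expert-aggregated) decision matrix exactly as published
#' in the case study. The comparison methods of the validation study
#' (PROMETHEE II, Muirhead mean, q-ROF MSM) take this matrix as their
#' input; loading the published values, rather than re-aggregating, mirrors
#' that study and isolates the comparison methods from upstream rounding.
#'
#' @return A \code{qrf2lMatrix}.
#' @examples
#' col <- exampleCollective()
#' prometheeFlows(pairwiseDeviations(col))
#' @export
exampleCollective <- function() {
  pan <- readPanel(system.file("extdata", "triage_collective.csv",
                               package = "qrf2l", mustWork = TRUE))
  pan$matrices[[1L]]
}

#' The published linguistic-free orthopair matrix
#'
#' The group decision matrix of the case study with the linguistic terms
#' stripped, as published for the q-ROF MSM comparison (it differs from the
#' orthopair part of [exampleCollective()] in a few entries of the source
#' tables).
#'
#' @return A list with numeric matrices \code{mu} and \code{nu}
#'   (alternatives x criteria).
#' @export
exampleOrthopairMatrix <- function() {
  raw <- utils::read.csv(system.file("extdata", "triage_orthopair.csv",
                                     package = "qrf2l", mustWork = TRUE))
  mu <- as.matrix(raw[, c(1, 3, 5, 7)])
  nu <- as.matrix(raw[, c(2, 4, 6, 8)])
  dimnames(mu) <- dimnames(nu) <- list(paste0("P", 1:5), paste0("C", 1:4))
  list(mu = mu, nu = nu)
}
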