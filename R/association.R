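#' Pearson correlation with exact two-sided significance
#'
#' R is the sample Pearson coefficient; the two-sided p comes from the
#' exact null distribution of R under bivariate normality via the
#' t-transform \eqn{t = R \sqrt{(n-2)/(1-R^2)}} with n-2 degrees of
#' freedom. Needs n >= 3 and non-constant vectors, otherwise NA.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with elements \code{R}, \code{p}, \code{n}.
#' @export
pearsonRP <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(R = NA_real_, p = NA_real_, n = n))
  R <- stats::cor(x, y)
  p <- if (abs(R) >= 1) 0 else {
    t <- R * sqrt((n - 2) / (1 - R^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(R = R, p = p, n = n)
}

#' Correlation screen over a list of entity pairs
#'
#' Computes Pearson R and its two-sided p for each pair of rows drawn from
#' two expression matrices (major vs minor, clustered mature pairs, or
#' miRNA vs host gene), across the shared tissue columns. Pairs with a
#' constant vector have undefined R and are flagged; they are excluded from
#' significance tallies downstream.
#'
#' @param matA,matB expression matrices (\linkS4class{MirnaExpression}
#'   accepted); typically reads-per-million values.
#' @param pairs data.frame whose first two columns name the row of
#'   \code{matA} and the row of \code{matB} for each pair.
#' @param alpha significance threshold (default 0.01, the pair-screen
#'   default; use 0.05 for host-gene checks).
#' @param adjust optional p-adjustment method passed to
#'   \code{stats::p.adjust} (e.g. "BH"); default "none", matching the
#'   uncorrected screen.
#' @return data.frame with \code{id_a}, \code{id_b}, \code{R}, \code{p},
#'   \code{n}, \code{direction}, \code{significant}, \code{undefined}.
#' @export
correlatePairs <- function(matA, matB, pairs, alpha = 0.01, adjust = "none") {
  A <- exprValues(matA)
  B <- exprValues(matB)
  if (!identical(colnames(A), colnames(B)))
    stop("alignment error: tissue columns differ between matrices")
  ida <- as.character(pairs[[1]])
  idb <- as.character(pairs[[2]])
  bad <- c(setdiff(ida, rownames(A)), setdiff(idb, rownames(B)))
  if (length(bad))
    stop("pair(s) not resolvable: ", paste(unique(bad), collapse = ", "))
  res <- lapply(seq_along(ida), function(i) pearsonRP(A[ida[i], ], B[idb[i], ]))
  R <- vapply(res, `[[`, numeric(1), "R")
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  data.frame(id_a = ida, id_b = idb, R = R, p = p,
             n = vapply(res, `[[`, numeric(1), "n"),
             direction = ifelse(is.na(R), NA_character_,
                                ifelse(R > 0, "positive", "negative")),
             significant = !is.na(p) & p < alpha,
             undefined = is.na(R),
             stringsAsFactors = FALSE)
}

#' Fraction of pairs that are significantly positively correlated
#'
#' @param results data.frame from \code{\link{correlatePairs}} (pairs with
#'   undefined R are excluded from both counts).
#' @return list with \code{count_significant_positive}, \code{count_total},
#'   \code{percent} (rounded to the nearest integer).
#' @export
summarizePositiveFraction <- function(results) {
  res <- results[!results$undefined, , drop = FALSE]
  total <- nrow(res)
  if (total == 0) stop("no defined correlation results to summarise")
  k <- sum(res$significant & res$direction == "positive")
  list(count_significant_positive = k, count_total = total,
       percent = round(100 * k / total))
}
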