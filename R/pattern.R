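#' Specificity measure (SPM) of an expression vector
#'
#' The SPM of tissue j is the cosine of the angle between the expression
#' vector and the unit axis of tissue j,
#' \deqn{SPM_j = x_j / \lVert x \rVert,}
#' so values lie in [0, 1], the squared values sum to 1, and the measure is
#' invariant to global scaling. The formula is isolated here so an
#' alternative definition is a one-line change.
#'
#' @param x non-negative expression vector (e.g. reads per million), not
#'   all zero.
#' @return named numeric vector of per-tissue SPM values.
#' @export
spmScores <- function(x) {
  x <- as.numeric0(x)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("SPM undefined for an all-zero expression vector")
  stats::setNames(x / nrm, names(x))
}

# keep names while coercing
as.numeric0 <- function(x) stats::setNames(as.numeric(x), names(x))

#' Contribution measure (CTM) of a tissue set
#'
#' The CTM of a tissue set S is the norm of the projection of the
#' expression vector onto S relative to the full norm,
#' \deqn{CTM_S = \sqrt{\sum_{j \in S} x_j^2} / \lVert x \rVert
#'            = \sqrt{\sum_{j \in S} SPM_j^2},}
#' i.e. how much of the expression pattern the flagged tissues jointly
#' carry.
#'
#' @param x non-negative expression vector.
#' @param tissues names (or indices) of the tissue set.
#' @return scalar in [0, 1].
#' @export
ctmScore <- function(x, tissues) {
  spm <- spmScores(x)
  sqrt(sum(spm[tissues]^2))
}

#' Classify the tissue pattern of one expression vector
#'
#' Calls the vector tissue-specific when any SPM exceeds
#' \code{spmSpecific} (the top tissue is reported); otherwise
#' tissue-selective when at least two tissues have SPM above
#' \code{spmSelective} and their joint CTM exceeds \code{ctmThreshold};
#' otherwise no patterned call. Specific takes priority over selective, so
#' the calls are mutually exclusive.
#'
#' @param x non-negative expression vector with tissue names.
#' @param spmSpecific SPM threshold for a specific call (default 0.9).
#' @param spmSelective per-tissue SPM threshold feeding the selective set
#'   (default 0.5).
#' @param ctmThreshold joint CTM threshold for a selective call
#'   (default 0.9).
#' @return list with \code{call} ("specific", "selective" or "none"),
#'   \code{tissues} (character), \code{spm} (full vector), \code{ctm}
#'   (of the selective set, NA otherwise).
#' @export
classifyPattern <- function(x, spmSpecific = 0.9, spmSelective = 0.5,
                            ctmThreshold = 0.9) {
  spm <- spmScores(x)
  if (max(spm) > spmSpecific)
    return(list(call = "specific", tissues = names(spm)[which.max(spm)],
                spm = spm, ctm = NA_real_))
  sel <- names(spm)[spm > spmSelective]
  if (length(sel) >= 2) {
    ctm <- sqrt(sum(spm[sel]^2))
    if (ctm > ctmThreshold)
      return(list(call = "selective", tissues = sel, spm = spm, ctm = ctm))
  }
  list(call = "none", tissues = character(0), spm = spm, ctm = NA_real_)
}

#' Tissue-pattern calls for every row of an expression matrix
#'
#' Applies \code{\link{classifyPattern}} to each row (normalised
#' reads-per-million values are the intended input). All-zero rows get an
#' NA call with a flag.
#'
#' @param x a \linkS4class{MirnaExpression} or matrix with tissue columns.
#' @param ... thresholds passed to \code{\link{classifyPattern}}.
#' @return data.frame with \code{mature_id}, \code{call}, \code{tissues}
#'   (comma-separated), \code{max_spm}, \code{ctm}, \code{all_zero}.
#' @export
patternCalls <- function(x, ...) {
  v <- exprValues(x)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    if (sum(v[i, ]) == 0)
      return(data.frame(mature_id = rownames(v)[i], call = NA_character_,
                        tissues = "", max_spm = NA_real_, ctm = NA_real_,
                        all_zero = TRUE, stringsAsFactors = FALSE))
    cl <- classifyPattern(v[i, ], ...)
    data.frame(mature_id = rownames(v)[i], call = cl$call,
               tissues = paste(cl$tissues, collapse = ","),
               max_spm = max(cl$spm), ctm = cl$ctm, all_zero = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
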