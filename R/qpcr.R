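#' Load a qPCR Ct table
#'
#' Tab-separated with columns \code{tissue}, \code{replicate},
#' \code{target}, \code{ct} (threshold cycles). The reference gene (U6
#' snRNA for miRNA assays, 18S rRNA for mRNA assays) appears as one of the
#' targets.
#'
#' @param path TSV path.
#' @return data.frame Ct table.
#' @export
loadCtTable <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tissue", "replicate", "target", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (any(ct$ct <= 0)) stop("validation error: Ct values must be positive")
  ct
}

# replicate-mean Ct per tissue for one target, with presence checks
.meanCt <- function(ct, gene, label) {
  sub <- ct[ct$target == gene, , drop = FALSE]
  if (nrow(sub) == 0) stop("no Ct rows for ", label, " gene ", gene)
  vapply(split(sub$ct, sub$tissue), mean, numeric(1))
}

#' Comparative-CT relative expression (2^-ddCt)
#'
#' Standard comparative-CT quantification: per tissue,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} (replicate means),
#' \eqn{\Delta\Delta Ct = \Delta Ct_{tissue} - \Delta Ct_{calibrator}},
#' fold change \eqn{2^{-\Delta\Delta Ct}}; the calibrator tissue's fold is
#' 1 by construction. When no calibrator is named, the tissue with the
#' lowest mean dCt (highest expression) is used — fold changes are only
#' interpreted relatively.
#'
#' @param ct Ct table (see \code{\link{loadCtTable}}).
#' @param target target gene label.
#' @param reference endogenous reference gene label (default "U6").
#' @param calibrator calibrator tissue; default lowest-dCt tissue.
#' @return data.frame with \code{tissue}, \code{dCt}, \code{ddCt},
#'   \code{fold}; the calibrator is in \code{attr(, "calibrator")}.
#' @export
relativeExpression <- function(ct, target, reference = "U6",
                               calibrator = NULL) {
  tCt <- .meanCt(ct, target, "target")
  rCt <- .meanCt(ct, reference, "reference")
  noRef <- setdiff(names(tCt), names(rCt))
  if (length(noRef))
    stop("missing reference Ct for tissue(s): ", paste(noRef, collapse = ", "))
  dCt <- tCt - rCt[names(tCt)]
  if (is.null(calibrator)) calibrator <- names(dCt)[which.min(dCt)]
  if (!calibrator %in% names(dCt))
    stop("calibrator tissue not present: ", calibrator)
  ddCt <- dCt - dCt[[calibrator]]
  out <- data.frame(tissue = names(dCt), dCt = unname(dCt),
                    ddCt = unname(ddCt), fold = 2^(-unname(ddCt)),
                    stringsAsFactors = FALSE)
  attr(out, "calibrator") <- calibrator
  out
}

#' Preferential-tissue calls by one-way ANOVA and Tukey HSD
#'
#' Tests whether the target is preferentially expressed in particular
#' tissues: a one-way ANOVA on replicate-level log2 relative expression
#' (the negative ddCt scale, variance-stabilised), gated at \code{alpha};
#' when significant, Tukey HSD pairwise comparisons flag the largest
#' top-mean group of tissues each of whose means exceeds every non-flagged
#' tissue's with an HSD-significant difference (co-preferential tissues
#' need not separate from each other).
#'
#' @param ct Ct table with at least 2 replicates per tissue for both genes.
#' @param target,reference gene labels.
#' @param alpha gate and HSD threshold (default 0.05).
#' @param calibrator calibrator tissue passed through to the ddCt scale.
#' @return character vector of flagged tissues (possibly empty), with
#'   attributes \code{anova_p} and \code{tukey} (the HSD table).
#' @export
preferentialTissues <- function(ct, target, reference = "U6", alpha = 0.05,
                                calibrator = NULL) {
  tsub <- ct[ct$target == target, , drop = FALSE]
  rsub <- ct[ct$target == reference, , drop = FALSE]
  if (nrow(tsub) == 0 || nrow(rsub) == 0)
    stop("target or reference gene absent from the Ct table")
  nrep <- table(tsub$tissue)
  if (length(nrep) < 2) stop("need at least two tissues for ANOVA")
  if (any(nrep < 2))
    stop("ANOVA refused: fewer than 2 replicates in tissue(s): ",
         paste(names(nrep)[nrep < 2], collapse = ", "))
  rel <- relativeExpression(ct, target, reference, calibrator)
  dCtCal <- rel$dCt[rel$tissue == attr(rel, "calibrator")]
  # replicate-level dCt: pair each target replicate with its own reference
  # replicate (independent errors across replicates); fall back to the
  # tissue-mean reference when replicate ids do not line up
  key <- paste(tsub$tissue, tsub$replicate)
  rkey <- paste(rsub$tissue, rsub$replicate)
  if (all(key %in% rkey)) {
    refCt <- rsub$ct[match(key, rkey)]
  } else {
    rMean <- vapply(split(rsub$ct, rsub$tissue), mean, numeric(1))
    refCt <- rMean[tsub$tissue]
  }
  df <- data.frame(tissue = factor(tsub$tissue),
                   log2rel = -((tsub$ct - refCt) - dCtCal))
  fit <- stats::aov(log2rel ~ tissue, data = df)
  pA <- summary(fit)[[1]][["Pr(>F)"]][1]
  flagged <- character(0)
  tk <- NULL
  if (pA < alpha) {
    tk <- stats::TukeyHSD(fit, "tissue")$tissue
    means <- sort(vapply(split(df$log2rel, df$tissue), mean, numeric(1)),
                  decreasing = TRUE)
    hsdP <- function(a, b) {
      key <- c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
      tk[intersect(key, rownames(tk))[1], "p adj"]
    }
    # flagged tissues must each exceed every non-flagged tissue with an
    # HSD-significant difference (they need not separate from each other):
    # take the largest top-k prefix of the mean ordering satisfying that
    for (k in rev(seq_len(length(means) - 1))) {
      top <- names(means)[seq_len(k)]
      rest <- names(means)[-seq_len(k)]
      ok <- all(outer(means[top], means[rest], ">")) &&
        all(vapply(top, function(t) all(vapply(rest, function(u)
          hsdP(t, u) < alpha, logical(1))), logical(1)))
      if (ok) { flagged <- top; break }
    }
  }
  structure(flagged, anova_p = pA, tukey = tk)
}
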