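#' Assemble the M / T / Q inputs for coexpression scoring
#'
#' Builds the scoring matrix from the major-form and minor-form count
#' matrices of the candidate precursors: majors whose cross-tissue total is
#' at most \code{minReads} are removed together with their pair (the read
#' filter applies to the pair's major form); minors are kept regardless so
#' that pairs with sparse or absent minors stay in the report (their score
#' is zero by the zero-read rule). Per-tissue fractions Qj come from the
#' full scoring universe (all miRNAs), Ti are row sums of M.
#'
#' Row names in M are \code{major|<precursor>} and \code{minor|<precursor>}.
#'
#' @param major,minor \linkS4class{MirnaExpression} or matrices of raw
#'   read counts (same precursor rows, same tissue columns).
#' @param universe matrix of raw counts over all miRNAs, used only for Qj;
#'   defaults to the stacked major+minor matrix.
#' @param minReads strict lower bound on the major total (default 50).
#' @return A \linkS4class{CoexpressionInputs}; the retained precursor ids
#'   are in \code{attr(, "precursors")}.
#' @export
buildCoexpressionInputs <- function(major, minor, universe = NULL,
                                    minReads = 50) {
  maj <- exprValues(major)
  mino <- exprValues(minor)
  if (!identical(colnames(maj), colnames(mino)))
    stop("alignment error: major/minor tissue columns differ: ",
         paste(union(setdiff(colnames(maj), colnames(mino)),
                     setdiff(colnames(mino), colnames(maj))), collapse = ", "))
  common <- intersect(rownames(maj), rownames(mino))
  maj <- maj[common, , drop = FALSE]
  mino <- mino[common, , drop = FALSE]
  keep <- rowSums(maj) > minReads
  maj <- maj[keep, , drop = FALSE]
  mino <- mino[keep, , drop = FALSE]
  if (is.null(universe)) universe <- rbind(maj, mino)
  uni <- exprValues(universe)
  if (!identical(colnames(uni), colnames(maj)))
    stop("alignment error: universe tissue columns differ from pair matrices")
  M <- rbind(maj, mino)
  rownames(M) <- c(paste0("major|", rownames(maj)),
                   paste0("minor|", rownames(mino)))
  Q <- colSums(uni) / sum(uni)
  obj <- new("CoexpressionInputs", M = M, Ti = rowSums(M), Qj = Q)
  attr(obj, "precursors") <- rownames(maj)
  obj
}

#' Build scoring inputs for arbitrary mature miRNAs
#'
#' Variant of \code{\link{buildCoexpressionInputs}} for scoring any two
#' mature forms against each other (e.g. clustered miRNA pairs): all rows
#' of \code{counts} become entities, filtered at \code{minReads} total.
#'
#' @param counts entity-by-tissue raw count matrix.
#' @param universe matrix for Qj; defaults to \code{counts}.
#' @param minReads strict total-read filter per entity (default 50).
#' @return A \linkS4class{CoexpressionInputs}.
#' @export
coexpressionInputsFromMatrix <- function(counts, universe = counts,
                                         minReads = 50) {
  M <- exprValues(counts)
  M <- M[rowSums(M) > minReads, , drop = FALSE]
  uni <- exprValues(universe)
  Q <- colSums(uni) / sum(uni)
  new("CoexpressionInputs", M = M, Ti = rowSums(M), Qj = Q)
}

#' Tissue specificity Z of each miRNA in each tissue
#'
#' Under proportional allocation of a miRNA's Ti total reads across tissues
#' (tissue j expects the library fraction Qj of them), the observed count
#' Mij is Binomial(Ti, Qj); the specificity statistic is the standardised
#' excess
#' \deqn{Z_{ij} = (M_{ij} - T_i Q_j) / \sqrt{T_i Q_j (1 - Q_j)}}
#' clamped at zero: depletion (negative excess) carries no specificity, and
#' Zij = 0 whenever Mij = 0 or the denominator degenerates (Ti = 0, or Qj
#' is 0 or 1). The formula is isolated here so an alternative transcription
#' is a one-line change.
#'
#' @param inputs a \linkS4class{CoexpressionInputs}.
#' @param entity optional entity (row) name; default all.
#' @return matrix of Z values (or a named vector for one entity).
#' @export
tissueSpecificityZ <- function(inputs, entity = NULL) {
  M <- inputs@M
  Ti <- inputs@Ti
  Qj <- inputs@Qj
  expt <- outer(Ti, Qj)
  denom <- sqrt(outer(Ti, Qj * (1 - Qj)))
  Z <- (M - expt) / denom
  Z[!is.finite(Z)] <- 0
  Z[Z < 0] <- 0
  Z[M == 0] <- 0
  if (!is.null(entity)) {
    if (!entity %in% rownames(M)) stop("unknown entity: ", entity)
    Z[entity, ]
  } else Z
}

#' Tissue coexpression score of a pair of miRNA forms
#'
#' The coexpression score of two forms in tissue j is the product of their
#' tissue-specificity values,
#' \deqn{S_j = Z_{aj} \, Z_{bj},}
#' so it is large only where both forms are jointly enriched, and exactly
#' zero in every tissue where either form has no reads — in particular for
#' any major/minor pair whose minor form has no reads at all.
#'
#' @param inputs a \linkS4class{CoexpressionInputs}.
#' @param a,b entity (row) names, e.g. \code{"major|mir-x"} /
#'   \code{"minor|mir-x"}. An entity absent from the filtered matrix (e.g.
#'   a minor with zero reads everywhere that was never added) scores 0 in
#'   every tissue.
#' @return named numeric vector of per-tissue scores.
#' @export
coexpressionScore <- function(inputs, a, b) {
  zeros <- stats::setNames(rep(0, ncol(inputs@M)), colnames(inputs@M))
  za <- if (a %in% rownames(inputs@M)) tissueSpecificityZ(inputs, a) else zeros
  zb <- if (b %in% rownames(inputs@M)) tissueSpecificityZ(inputs, b) else zeros
  za * zb
}

#' Flag the top decile of coexpression scores
#'
#' Flags the \code{ceiling(fraction * N)} highest scores; ties at the
#' cutoff are all included, so under ties the flag count may exceed the
#' nominal decile size. A score of zero is never flagged (zero means no
#' coexpression evidence). The reported rank percentile uses minimum-rank
#' counting (100 * (number of strictly greater scores + 1) / N).
#'
#' @param scores numeric vector of non-negative scores.
#' @param fraction selection fraction (default 0.1).
#' @return data.frame with \code{score}, \code{rank_percentile},
#'   \code{selected_top10}, in input order.
#' @export
selectTopDecile <- function(scores, fraction = 0.1) {
  n <- length(scores)
  if (n == 0)
    return(data.frame(score = numeric(), rank_percentile = numeric(),
                      selected_top10 = logical()))
  k <- ceiling(fraction * n)
  cutoff <- sort(scores, decreasing = TRUE)[k]
  minrank <- vapply(scores, function(s) sum(scores > s) + 1, numeric(1))
  data.frame(score = scores,
             rank_percentile = 100 * minrank / n,
             selected_top10 = scores >= cutoff & scores > 0)
}

#' Two-sided Fisher exact p for 2x2 tables (vectorised)
#'
#' Exact two-sided p by the point-probability method: the sum of the
#' probabilities of all tables with the observed margins whose hypergeometric
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tie tolerance). A table with an all-zero margin is degenerate
#' and returns p = 1.
#'
#' @param a,b,c,d table cells, recycled to a common length: rows are the
#'   two categories, columns the condition split (e.g. tissue j vs all
#'   other tissues).
#' @return numeric vector of p-values in [0, 1].
#' @export
fisherExactP <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c[i] + d[i]         # row 2 total
    k <- a[i] + c[i]          # column 1 total
    if (m == 0 || nn == 0 || k == 0 || (b[i] + d[i]) == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    probs <- stats::dhyper(support, m, nn, k)
    pObs <- probs[support == a[i]]
    sum(probs[probs <= pObs * (1 + 1e-7)])
  }, numeric(1))
}

#' Fisher screen of sibling minor forms within a family
#'
#' For every ordered pair of minor forms (A, B) produced by members of one
#' paralogous family, tests differential occurrence in tissue j with the
#' 2x2 table [A reads in j, A reads elsewhere; B reads in j, B reads
#' elsewhere] and the two-sided exact test. A pair passes at p below
#' \code{alpha}; \code{a_enriched} records whether A's read fraction in j
#' exceeds B's (the direction used when calling a contributing member).
#' All-zero tables are degenerate (p = 1, flagged).
#'
#' @param minorCounts matrix of raw minor-form counts, one row per family
#'   member (needs >= 2 rows), columns = tissues.
#' @param tissue tissue label (column) to test, or NULL for all tissues.
#' @param alpha significance threshold (default 0.05, uncorrected as in the
#'   source method; apply \code{stats::p.adjust} upstream if desired).
#' @return data.frame with \code{member_a}, \code{member_b}, \code{tissue},
#'   \code{fisher_p}, \code{pass}, \code{a_enriched}, \code{degenerate}.
#' @export
fisherMinorFilter <- function(minorCounts, tissue = NULL, alpha = 0.05) {
  m <- as.matrix(minorCounts)
  if (nrow(m) < 2) stop("need at least two minor forms to compare")
  tset <- if (is.null(tissue)) colnames(m) else tissue
  if (!all(tset %in% colnames(m)))
    stop("unknown tissue(s): ", paste(setdiff(tset, colnames(m)), collapse = ", "))
  grid <- expand.grid(ai = seq_len(nrow(m)), bi = seq_len(nrow(m)),
                      tissue = tset, stringsAsFactors = FALSE)
  grid <- grid[grid$ai != grid$bi, , drop = FALSE]
  tot <- rowSums(m)
  aj <- m[cbind(grid$ai, match(grid$tissue, colnames(m)))]
  bj <- m[cbind(grid$bi, match(grid$tissue, colnames(m)))]
  p <- fisherExactP(aj, tot[grid$ai] - aj, bj, tot[grid$bi] - bj)
  propA <- ifelse(tot[grid$ai] > 0, aj / tot[grid$ai], 0)
  propB <- ifelse(tot[grid$bi] > 0, bj / tot[grid$bi], 0)
  out <- data.frame(member_a = rownames(m)[grid$ai],
                    member_b = rownames(m)[grid$bi],
                    tissue = grid$tissue,
                    fisher_p = p,
                    pass = p < alpha,
                    a_enriched = propA > propB,
                    degenerate = (tot[grid$ai] + tot[grid$bi]) == 0 |
                      (aj + bj) == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-family, per-tissue discrimination report for major/minor pairs
#'
#' The end-to-end discrimination of paralogous precursors: each family
#' member's major/minor pair is scored in every tissue
#' (\code{\link{coexpressionScore}}), the top decile of all member-by-tissue
#' scores is flagged globally (\code{\link{selectTopDecile}}), sibling
#' minors are screened with the Fisher exact test
#' (\code{\link{fisherMinorFilter}}), and a member \emph{passes} in a
#' tissue when its score is in the top decile and its minor form beats
#' every sibling's (p below \code{alpha} and enriched in that tissue). The
#' passing member with the highest score is called the contributing
#' precursor for the family in that tissue; families flagged
#' indistinguishable, or with no qualifying member in any tissue, are
#' marked unresolved.
#'
#' An optional Pearson pre-screen (\code{corPrefilter}) drops members whose
#' major and minor expression are not significantly positively associated
#' across tissues before selection.
#'
#' @param families family table from \code{\link{findFamilies}}.
#' @param major,minor raw major- and minor-form count matrices (precursor
#'   rows; \linkS4class{MirnaExpression} accepted).
#' @param universe raw counts over all miRNAs for Qj; default majors+minors.
#' @param minReads strict major-total read filter (default 50).
#' @param topFraction selection fraction (default 0.1).
#' @param alpha Fisher threshold (default 0.05).
#' @param corPrefilter apply the Pearson pre-screen (default FALSE).
#' @param corAlpha threshold for the pre-screen (default 0.01).
#' @return data.frame with one row per family member per tissue
#'   (\code{family_id}, \code{precursor_id}, \code{major_id},
#'   \code{minor_id}, \code{tissue}, \code{Z_major}, \code{Z_minor},
#'   \code{score}, \code{rank_percentile}, \code{selected_top10},
#'   \code{fisher_p}, \code{passes}); the per-family-per-tissue contributor
#'   calls are in \code{attr(, "calls")} (see
#'   \code{\link{contributorCalls}}).
#' @export
discriminationReport <- function(families, major, minor, universe = NULL,
                                 minReads = 50, topFraction = 0.1,
                                 alpha = 0.05, corPrefilter = FALSE,
                                 corAlpha = 0.01) {
  maj <- exprValues(major)
  mino <- exprValues(minor)
  inputs <- buildCoexpressionInputs(maj, mino, universe, minReads = minReads)
  kept <- attr(inputs, "precursors")
  fams <- families[families$precursor_id %in% kept, , drop = FALSE]
  tis <- colnames(maj)
  Z <- tissueSpecificityZ(inputs)
  rows <- do.call(rbind, lapply(seq_len(nrow(fams)), function(i) {
    p <- fams$precursor_id[i]
    zM <- Z[paste0("major|", p), ]
    zm <- Z[paste0("minor|", p), ]
    data.frame(family_id = fams$family_id[i], precursor_id = p,
               major_id = fams$major_id[i], minor_id = fams$minor_id[i],
               tissue = tis, Z_major = unname(zM), Z_minor = unname(zm),
               score = unname(zM * zm), stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    out <- data.frame(family_id = character(), precursor_id = character(),
                      major_id = character(), minor_id = character(),
                      tissue = character(), Z_major = numeric(),
                      Z_minor = numeric(), score = numeric(),
                      rank_percentile = numeric(),
                      selected_top10 = logical(), fisher_p = numeric(),
                      passes = logical())
    attr(out, "calls") <- data.frame(family_id = character(),
                                     tissue = character(),
                                     contributor = character(),
                                     unresolved = logical(),
                                     reason = character())
    return(out)
  }
  if (corPrefilter) {
    ok <- vapply(unique(rows$precursor_id), function(p) {
      x <- maj[p, ]; y <- mino[p, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(FALSE)
      r <- pearsonRP(x, y)
      !is.na(r$p) && r$p < corAlpha && r$R > 0
    }, logical(1))
    drop <- names(ok)[!ok]
    rows$score[rows$precursor_id %in% drop] <- 0
  }
  sel <- selectTopDecile(rows$score, fraction = topFraction)
  rows$rank_percentile <- sel$rank_percentile
  rows$selected_top10 <- sel$selected_top10
  # Fisher screen within each family
  rows$fisher_p <- NA_real_
  rows$passes <- FALSE
  calls <- list()
  for (f in unique(fams$family_id)) {
    members <- fams$precursor_id[fams$family_id == f]
    indist <- any(fams$indistinguishable[fams$family_id == f])
    if (length(members) >= 2 && !indist) {
      fm <- fisherMinorFilter(mino[members, , drop = FALSE], alpha = alpha)
      for (p in members) {
        vs <- fm[fm$member_a == p, , drop = FALSE]
        # worst-case sibling comparison per tissue
        agg <- do.call(rbind, lapply(split(vs, vs$tissue), function(v)
          data.frame(tissue = v$tissue[1], fisher_p = max(v$fisher_p),
                     beats = all(v$pass & v$a_enriched))))
        idx <- rows$family_id == f & rows$precursor_id == p
        m <- match(rows$tissue[idx], agg$tissue)
        rows$fisher_p[idx] <- agg$fisher_p[m]
        rows$passes[idx] <- rows$selected_top10[idx] & agg$beats[m]
      }
    }
    for (t in tis) {
      cand <- rows[rows$family_id == f & rows$tissue == t & rows$passes, ,
                   drop = FALSE]
      if (indist) {
        calls[[length(calls) + 1L]] <- data.frame(
          family_id = f, tissue = t, contributor = NA_character_,
          unresolved = TRUE, reason = "indistinguishable minors",
          stringsAsFactors = FALSE)
      } else if (nrow(cand)) {
        best <- cand$precursor_id[which.max(cand$score)]
        calls[[length(calls) + 1L]] <- data.frame(
          family_id = f, tissue = t, contributor = best,
          unresolved = FALSE, reason = "", stringsAsFactors = FALSE)
      } else {
        calls[[length(calls) + 1L]] <- data.frame(
          family_id = f, tissue = t, contributor = NA_character_,
          unresolved = TRUE, reason = "no qualifying member",
          stringsAsFactors = FALSE)
      }
    }
  }
  rownames(rows) <- NULL
  attr(rows, "calls") <- do.call(rbind, calls)
  rows
}

#' Extract per-family, per-tissue contributor calls
#'
#' @param report the data.frame returned by
#'   \code{\link{discriminationReport}}.
#' @return data.frame with \code{family_id}, \code{tissue},
#'   \code{contributor} (NA when unresolved), \code{unresolved},
#'   \code{reason}.
#' @export
contributorCalls <- function(report) attr(report, "calls")
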