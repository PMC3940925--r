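#' Assign guide (major) and passenger (minor) arms from read pileups
#'
#' For every precursor, the read start position with the highest count
#' summed across tissues is taken as the authentic major mature form and
#' defines the guide-strand arm; the highest-count start on the opposite
#' arm defines the minor form. A start belongs to the 5p arm when it lies
#' at or before the hairpin midpoint, else to the 3p arm. Ties at the
#' argmax are broken toward the 5'-most position.
#'
#' Precursors with zero reads get all-zero vectors and a \code{zero_reads}
#' flag; precursors with reads on only one arm get an all-zero minor vector,
#' an NA minor position and a \code{one_arm} flag.
#'
#' @param reads a \linkS4class{ReadMappingTable}.
#' @param annotations a \linkS4class{PrecursorAnnotations} giving hairpin
#'   lengths (every precursor present in \code{reads} must be annotated).
#' @return An \linkS4class{ArmProfiles}.
#' @export
assignArms <- function(reads, annotations) {
  stopifnot(is(reads, "ReadMappingTable"),
            is(annotations, "PrecursorAnnotations"))
  hp <- hairpinSeqs(annotations)
  rec <- readRecords(reads)
  tis <- tissueLabels(reads)
  precs <- names(hp)
  missing <- setdiff(unique(rec$precursor_id), precs)
  if (length(missing))
    stop("precursor(s) without annotation: ", paste(missing, collapse = ", "))
  len <- stats::setNames(Biostrings::width(hp), precs)
  n <- length(precs)
  zero <- matrix(0, n, length(tis), dimnames = list(precs, tis))
  majorC <- minorC <- precC <- zero
  info <- data.frame(precursor_id = precs,
                     major_position = NA_integer_, major_arm = NA_character_,
                     minor_position = NA_integer_, minor_arm = NA_character_,
                     zero_reads = FALSE, one_arm = FALSE,
                     stringsAsFactors = FALSE)
  bylist <- split(rec, rec$precursor_id)
  for (p in precs) {
    r <- bylist[[p]]
    if (is.null(r) || sum(r$count) == 0) {
      info[info$precursor_id == p, "zero_reads"] <- TRUE
      next
    }
    perStart <- vapply(split(r$count, r$start), sum, numeric(1))
    starts <- as.integer(names(perStart))
    ord <- order(-perStart, starts)   # max count, then 5'-most
    major <- starts[ord[1]]
    armOf <- function(s) ifelse(s <= len[[p]] / 2, "5p", "3p")
    majArm <- armOf(major)
    opp <- starts[armOf(starts) != majArm]
    i <- info$precursor_id == p
    info[i, "major_position"] <- major
    info[i, "major_arm"] <- majArm
    tisOf <- function(sel) {
      v <- vapply(split(r$count[sel], factor(r$tissue[sel], levels = tis)),
                  sum, numeric(1))
      v[is.na(v)] <- 0
      v
    }
    precC[p, ] <- tisOf(rep(TRUE, nrow(r)))
    majorC[p, ] <- tisOf(r$start == major)
    if (length(opp)) {
      oppCounts <- perStart[as.character(opp)]
      oord <- order(-oppCounts, opp)
      minor <- opp[oord[1]]
      info[i, "minor_position"] <- minor
      info[i, "minor_arm"] <- armOf(minor)
      minorC[p, ] <- tisOf(r$start == minor)
    } else {
      info[i, "one_arm"] <- TRUE
    }
  }
  new("ArmProfiles", info = info, majorCounts = majorC,
      minorCounts = minorC, precursorCounts = precC)
}

#' Quantify expression at the precursor, major or minor level
#'
#' Precursor-level expression sums all reads mapped to the hairpin; major
#' and minor levels take the reads at the profile's designated start
#' positions, per tissue. The per-tissue library totals of the read table
#' are carried along for normalisation.
#'
#' @param reads the \linkS4class{ReadMappingTable} the profiles were
#'   computed from.
#' @param profiles an \linkS4class{ArmProfiles}.
#' @param level one of "precursor", "major", "minor".
#' @return A raw-count \linkS4class{MirnaExpression} (precursor x tissue).
#' @export
quantifyExpression <- function(reads, profiles,
                               level = c("precursor", "major", "minor")) {
  level <- match.arg(level)
  stopifnot(is(reads, "ReadMappingTable"), is(profiles, "ArmProfiles"))
  v <- armCounts(profiles, switch(level, precursor = "precursor",
                                  major = "major", minor = "minor"))
  MirnaExpression(v, level = level, normalized = FALSE,
                  libTotals = tissueTotals(reads))
}

#' Normalise counts to reads per million per tissue
#'
#' Each count is scaled by \code{scale / total}, where \code{total} is that
#' tissue's library size: by default the sum over all read records for the
#' tissue in the source table (carried in the object's metadata), overridable
#' via \code{libTotals}.
#'
#' @param x a raw \linkS4class{MirnaExpression} or plain matrix.
#' @param libTotals optional named per-tissue totals overriding the stored
#'   ones (required for a plain matrix unless its column sums are to be
#'   used).
#' @param scale normalisation constant, default 1e6 (RPM).
#' @return A normalised \linkS4class{MirnaExpression}.
#' @export
normalizeRpm <- function(x, libTotals = NULL, scale = 1e6) {
  v <- exprValues(x)
  if (is.null(libTotals) && is(x, "SummarizedExperiment"))
    libTotals <- metadata(x)$libTotals
  if (is.null(libTotals)) libTotals <- colSums(v)
  tot <- libTotals[colnames(v)]
  if (any(is.na(tot)))
    stop("no library total for tissue(s): ",
         paste(colnames(v)[is.na(tot)], collapse = ", "))
  zero <- tot == 0
  if (any(zero & colSums(v) > 0))
    stop("impossible state: zero library total but nonzero counts in ",
         paste(colnames(v)[zero & colSums(v) > 0], collapse = ", "))
  tot[zero] <- 1  # zero totals imply zero columns; keep them zero
  norm <- sweep(v, 2, tot, "/") * scale
  MirnaExpression(norm, level = if (is(x, "SummarizedExperiment"))
    exprLevel(x) else "unknown",
    normalized = TRUE, scale = scale, libTotals = libTotals)
}

#' Major/minor arm-usage ratios and arm-switch tissues
#'
#' For every precursor whose major form has more than \code{minTotal} reads
#' across tissues (or whose combined major+minor total exceeds it, with
#' \code{filterOn = "combined"}), reports the cross-tissue major and minor
#' totals, their ratio (Inf when the minor has no reads), a coarse ratio
#' class (below 10, 10-400, above 400), and the tissues in which the minor
#' form out-reads the major form (arm switching).
#'
#' @param profiles an \linkS4class{ArmProfiles}.
#' @param minTotal strict lower bound on the filtered total (default 50).
#' @param filterOn apply the bound to the major total (default) or to the
#'   combined major+minor total.
#' @return data.frame with columns \code{precursor_id}, \code{major_total},
#'   \code{minor_total}, \code{ratio}, \code{ratio_class},
#'   \code{arm_switch_tissues} (comma-separated, "" when none).
#' @export
armRatios <- function(profiles, minTotal = 50,
                      filterOn = c("major", "combined")) {
  filterOn <- match.arg(filterOn)
  maj <- armCounts(profiles, "major")
  mino <- armCounts(profiles, "minor")
  majTot <- rowSums(maj)
  minTot <- rowSums(mino)
  keep <- if (filterOn == "major") majTot > minTotal
          else (majTot + minTot) > minTotal
  switches <- vapply(seq_len(nrow(maj)), function(i)
    paste(colnames(maj)[mino[i, ] > maj[i, ]], collapse = ","), character(1))
  ratio <- ifelse(minTot > 0, majTot / minTot, Inf)
  out <- data.frame(precursor_id = rownames(maj),
                    major_total = majTot, minor_total = minTot,
                    ratio = ratio,
                    ratio_class = ifelse(ratio > 400, ">400",
                                  ifelse(ratio < 10, "<10", "10-400")),
                    arm_switch_tissues = switches,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[keep, , drop = FALSE]
}
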