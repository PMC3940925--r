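#' Group precursors into paralogous families sharing one major mature form
#'
#' A paralogous family is a maximal group of two or more precursors whose
#' major mature forms are identical — either the same mature accession
#' (\code{mode = "by_shared_mature_id"}, mirroring miRBase naming where one
#' mature id is produced by several hairpins) or the same mature sequence
#' (\code{mode = "by_sequence"}, for annotation-free inputs). Singletons are
#' excluded. Families whose members also share identical minor sequences
#' are flagged indistinguishable: nothing downstream can separate them.
#'
#' @param annotations a \linkS4class{PrecursorAnnotations}.
#' @param profiles an \linkS4class{ArmProfiles} giving the major arm per
#'   precursor; precursors without a major assignment are skipped with a
#'   warning.
#' @param mode grouping key, see Details.
#' @return data.frame with one row per family member: \code{family_id},
#'   \code{precursor_id}, \code{major_id}, \code{minor_id},
#'   \code{major_seq}, \code{minor_seq}, \code{indistinguishable}.
#' @export
findFamilies <- function(annotations, profiles,
                         mode = c("by_shared_mature_id", "by_sequence")) {
  mode <- match.arg(mode)
  info <- armInfo(profiles)
  mat <- matureRecords(annotations)
  skipped <- info$precursor_id[is.na(info$major_arm)]
  if (length(skipped))
    warning("skipping precursor(s) without major assignment: ",
            paste(skipped, collapse = ", "))
  info <- info[!is.na(info$major_arm), , drop = FALSE]
  pick <- function(p, arm) {
    r <- mat[mat$precursor_id == p & mat$arm == arm, , drop = FALSE]
    if (nrow(r)) r[1, c("mature_id", "sequence")]
    else data.frame(mature_id = NA_character_, sequence = NA_character_)
  }
  members <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
    p <- info$precursor_id[i]
    maj <- pick(p, info$major_arm[i])
    mino <- pick(p, setdiff(c("5p", "3p"), info$major_arm[i]))
    data.frame(precursor_id = p,
               major_id = maj$mature_id, major_seq = maj$sequence,
               minor_id = mino$mature_id, minor_seq = mino$sequence,
               stringsAsFactors = FALSE)
  }))
  if (is.null(members) || nrow(members) == 0)
    return(data.frame(family_id = character(), precursor_id = character(),
                      major_id = character(), minor_id = character(),
                      major_seq = character(), minor_seq = character(),
                      indistinguishable = logical()))
  key <- if (mode == "by_shared_mature_id") members$major_id
         else members$major_seq
  ok <- !is.na(key)
  if (any(!ok))
    warning("skipping precursor(s) without an annotated major mature: ",
            paste(members$precursor_id[!ok], collapse = ", "))
  members <- members[ok, , drop = FALSE]
  key <- key[ok]
  fam <- split(seq_len(nrow(members)), key)
  fam <- fam[vapply(fam, length, integer(1)) >= 2]
  out <- do.call(rbind, lapply(names(fam), function(k) {
    rows <- members[fam[[k]], , drop = FALSE]
    minors <- rows$minor_seq
    indist <- length(rows$precursor_id) >= 2 &&
      !anyNA(minors) && length(unique(minors)) == 1
    cbind(data.frame(family_id = k, stringsAsFactors = FALSE),
          rows, indistinguishable = indist)
  }))
  if (is.null(out))
    out <- data.frame(family_id = character(), precursor_id = character(),
                      major_id = character(), major_seq = character(),
                      minor_id = character(), minor_seq = character(),
                      indistinguishable = logical())
  rownames(out) <- NULL
  out
}

#' Find clustered precursor pairs from genomic loci
#'
#' Single-linkage clustering of precursors on the same chromosome and
#' strand whose inter-interval gap (distance between nearest ends,
#' \code{start2 - end1} for position-sorted non-overlapping intervals) is
#' strictly below \code{maxGap}. All unordered within-cluster pairs are
#' emitted, so a cluster of n precursors contributes n(n-1)/2 pairs.
#'
#' @param annotations a \linkS4class{PrecursorAnnotations} with genomic
#'   loci (precursors without a locus are excluded with a warning), or a
#'   named \code{GRanges} directly.
#' @param maxGap strict gap threshold in bp (default 5000).
#' @return data.frame with columns \code{miRNA_a}, \code{miRNA_b},
#'   \code{chromosome}, \code{strand}, \code{gap_bp}, \code{cluster_id}.
#' @export
findClusterPairs <- function(annotations, maxGap = 5000) {
  loci <- if (is(annotations, "PrecursorAnnotations")) {
    l <- genomicLoci(annotations)
    noLocus <- setdiff(names(hairpinSeqs(annotations)), names(l))
    if (length(l) && length(noLocus))
      warning("precursor(s) without genomic locus excluded: ",
              paste(noLocus, collapse = ", "))
    l
  } else annotations
  empty <- data.frame(miRNA_a = character(), miRNA_b = character(),
                      chromosome = character(), strand = character(),
                      gap_bp = numeric(), cluster_id = character())
  if (length(loci) < 2) return(empty)
  df <- data.frame(id = names(loci),
                   chrom = as.character(GenomicRanges::seqnames(loci)),
                   start = GenomicRanges::start(loci),
                   end = GenomicRanges::end(loci),
                   strand = as.character(GenomicRanges::strand(loci)),
                   stringsAsFactors = FALSE)
  pairs <- list()
  cl <- 0L
  for (grp in split(df, paste(df$chrom, df$strand))) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    gap <- grp$start[-1] - grp$end[-nrow(grp)]
    memb <- cumsum(c(TRUE, gap >= maxGap))  # new cluster when gap >= maxGap
    for (members in split(seq_len(nrow(grp)), memb)) {
      if (length(members) < 2) next
      cl <- cl + 1L
      cmb <- utils::combn(members, 2)
      pairs[[length(pairs) + 1L]] <- data.frame(
        miRNA_a = grp$id[cmb[1, ]], miRNA_b = grp$id[cmb[2, ]],
        chromosome = grp$chrom[1], strand = grp$strand[1],
        gap_bp = pmax(0, pmax(grp$start[cmb[1, ]], grp$start[cmb[2, ]]) -
                         pmin(grp$end[cmb[1, ]], grp$end[cmb[2, ]])),
        cluster_id = paste0("cluster_", cl),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Precursor/host-gene pairs
#'
#' Pass-through pairing of intragenic precursors with their annotated host
#' genes, for the downstream host-gene correlation screen. Host
#' relationships are supplied in the annotations, not inferred from
#' transcript overlap. Precursors without a host gene are omitted.
#'
#' @param annotations a \linkS4class{PrecursorAnnotations}.
#' @return data.frame with columns \code{precursor_id}, \code{host_gene}.
#' @export
hostGenePairs <- function(annotations) {
  hg <- hostGeneMap(annotations)
  hg <- hg[!is.na(hg) & hg != ""]
  data.frame(precursor_id = names(hg), host_gene = unname(hg),
             stringsAsFactors = FALSE)
}
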