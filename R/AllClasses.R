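#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

#' The 15-tissue mouse panel used throughout the package
#'
#' Ordered tissue labels matching the deep-sequencing panel the scoring
#' defaults emulate (bone marrow through ovary). Functions that take a
#' \code{tissues} argument use this vector as their default ordering.
#'
#' @return Character vector of 15 tissue labels.
#' @export
#' @examples
#' mousePanelTissues()
mousePanelTissues <- function() {
  c("bone_marrow", "thymus", "spleen", "lymph_node", "heart", "brain",
    "lung", "liver", "kidney", "pancreas", "skin", "skeletal_muscle",
    "salivary_gland", "testis", "ovary")
}

#' ReadMappingTable: long-form small-RNA read mappings
#'
#' Holds one record per (precursor, read start position within the hairpin,
#' tissue) with the summed read count, plus the stable tissue ordering.
#' Counts are non-negative and the (precursor_id, start, tissue) key is
#' unique (duplicates are summed on construction).
#'
#' @slot records data.frame with columns \code{precursor_id} (character),
#'   \code{start} (integer, 1-based position within the hairpin),
#'   \code{count} (non-negative numeric), \code{tissue} (character).
#' @slot tissues character; ordered unique tissue labels. The order is the
#'   order of first appearance in the input unless an explicit order was
#'   supplied, and is preserved by every downstream matrix.
#'
#' @name ReadMappingTable-class
#' @rdname ReadMappingTable-class
#' @exportClass ReadMappingTable
setClass("ReadMappingTable",
  representation(records = "data.frame", tissues = "character"))

setValidity("ReadMappingTable", function(object) {
  rec <- object@records
  need <- c("precursor_id", "start", "count", "tissue")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(rec) == 0) return(TRUE)
  if (any(rec$count < 0)) return("counts must be non-negative")
  key <- paste(rec$precursor_id, rec$start, rec$tissue, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (precursor_id, start, tissue) records")
  if (!all(rec$tissue %in% object@tissues))
    return("records reference tissues absent from the tissue order")
  TRUE
})

#' Construct a ReadMappingTable
#'
#' Duplicate (precursor, start, tissue) rows are summed; tissue labels are
#' whitespace-trimmed and matched exactly.
#'
#' @param records data.frame with columns \code{precursor_id}, \code{start},
#'   \code{count}, \code{tissue}.
#' @param tissues optional character vector fixing the tissue order; defaults
#'   to order of first appearance.
#' @return A \linkS4class{ReadMappingTable}.
#' @export
ReadMappingTable <- function(records, tissues = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("precursor_id", "start", "count", "tissue")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  rec <- data.frame(
    precursor_id = trimws(as.character(records$precursor_id)),
    start = as.integer(records$start),
    count = as.numeric(records$count),
    tissue = trimws(as.character(records$tissue)),
    stringsAsFactors = FALSE)
  bad <- which(rec$count < 0)
  if (length(bad))
    stop("negative count at input row(s): ", paste(head(bad, 5), collapse = ", "))
  if (nrow(rec)) {
    agg <- stats::aggregate(count ~ precursor_id + start + tissue, data = rec,
                            FUN = sum)
    # restore input encounter order of keys for stable output
    key <- paste(rec$precursor_id, rec$start, rec$tissue, sep = "\r")
    akey <- paste(agg$precursor_id, agg$start, agg$tissue, sep = "\r")
    agg <- agg[order(match(akey, key)), c("precursor_id", "start", "tissue", "count")]
    rownames(agg) <- NULL
    rec <- agg[, need]
  }
  if (is.null(tissues)) tissues <- unique(rec$tissue)
  else {
    tissues <- trimws(as.character(tissues))
    extra <- setdiff(unique(rec$tissue), tissues)
    if (length(extra))
      stop("records contain tissues not in the supplied order: ",
           paste(extra, collapse = ", "))
  }
  new("ReadMappingTable", records = rec, tissues = tissues)
}

#' @describeIn ReadMappingTable-class number of records
#' @param x,object a \code{ReadMappingTable}
#' @export
setMethod("length", "ReadMappingTable", function(x) nrow(x@records))

#' @describeIn ReadMappingTable-class display a summary
#' @export
setMethod("show", "ReadMappingTable", function(object) {
  cat("ReadMappingTable:", nrow(object@records), "records,",
      length(unique(object@records$precursor_id)), "precursors,",
      length(object@tissues), "tissues\n")
  cat("total reads:", sum(object@records$count), "\n")
})

#' Accessors for ReadMappingTable
#'
#' @param x a \linkS4class{ReadMappingTable}
#' @return \code{readRecords} returns the records data.frame;
#'   \code{tissueLabels} the ordered tissue labels; \code{tissueTotals}
#'   the named per-tissue total read counts (the normalisation denominators).
#' @export
readRecords <- function(x) x@records

#' @rdname readRecords
#' @export
tissueLabels <- function(x) {
  if (is(x, "ReadMappingTable")) x@tissues
  else if (is(x, "SummarizedExperiment")) colnames(x)
  else colnames(x)
}

#' @rdname readRecords
#' @export
tissueTotals <- function(x) {
  stopifnot(is(x, "ReadMappingTable"))
  tot <- vapply(split(x@records$count, factor(x@records$tissue, levels = x@tissues)),
                sum, numeric(1))
  tot
}

#' PrecursorAnnotations: hairpins, matures, loci and host genes
#'
#' One object bundling everything known about the precursors: hairpin
#' sequences, mature records (arm, within-hairpin 1-based inclusive
#' coordinates, sequence), genomic loci and optional host-gene assignments.
#'
#' @slot hairpins \code{DNAStringSet} named by precursor id.
#' @slot matures data.frame with columns \code{precursor_id},
#'   \code{mature_id}, \code{arm} ("5p"/"3p"), \code{start}, \code{end}
#'   (1-based inclusive within the hairpin), \code{sequence}.
#' @slot loci \code{GRanges} named by precursor id (may be empty).
#' @slot hostGenes named character (precursor id -> host gene symbol).
#'
#' @name PrecursorAnnotations-class
#' @rdname PrecursorAnnotations-class
#' @exportClass PrecursorAnnotations
setClass("PrecursorAnnotations",
  representation(hairpins = "DNAStringSet", matures = "data.frame",
                 loci = "GRanges", hostGenes = "character"))

setValidity("PrecursorAnnotations", function(object) {
  m <- object@matures
  need <- c("precursor_id", "mature_id", "arm", "start", "end", "sequence")
  if (!all(need %in% names(m)))
    return(paste("matures must have columns", paste(need, collapse = ", ")))
  if (nrow(m)) {
    orphan <- setdiff(m$precursor_id, names(object@hairpins))
    if (length(orphan))
      return(paste("mature features reference unknown hairpins:",
                   paste(orphan, collapse = ", ")))
    len <- Biostrings::width(object@hairpins)[match(m$precursor_id,
                                                    names(object@hairpins))]
    if (any(m$start < 1 | m$end > len | m$start > m$end))
      return("mature coordinates fall outside their hairpin")
    if (!all(m$arm %in% c("5p", "3p"))) return("arm must be 5p or 3p")
    if (anyDuplicated(paste(m$precursor_id, m$arm)))
      return("at most one annotated mature per arm per precursor")
  }
  TRUE
})

#' Construct a PrecursorAnnotations object
#'
#' @param hairpins \code{DNAStringSet} (or named character) of hairpin
#'   sequences, named by precursor id.
#' @param matures data.frame of mature records; an \code{arm} column is
#'   derived from the mature midpoint relative to the hairpin midpoint when
#'   absent, and a \code{sequence} column is extracted from the hairpin when
#'   absent.
#' @param loci optional \code{GRanges} named by precursor id.
#' @param hostGenes optional named character, precursor id -> host gene.
#' @return A \linkS4class{PrecursorAnnotations}.
#' @export
PrecursorAnnotations <- function(hairpins, matures,
                                 loci = GenomicRanges::GRanges(),
                                 hostGenes = character(0)) {
  if (!is(hairpins, "DNAStringSet"))
    hairpins <- Biostrings::DNAStringSet(hairpins)
  m <- as.data.frame(matures, stringsAsFactors = FALSE)
  if (nrow(m)) {
    orphan <- setdiff(m$precursor_id, names(hairpins))
    if (length(orphan))
      stop("mature feature(s) reference hairpins absent from the FASTA: ",
           paste(orphan, collapse = ", "))
    len <- Biostrings::width(hairpins)[match(m$precursor_id, names(hairpins))]
    if (any(m$start < 1 | m$end > len))
      stop("mature coordinates outside hairpin for: ",
           paste(unique(m$precursor_id[m$start < 1 | m$end > len]), collapse = ", "))
    if (is.null(m$arm) || any(is.na(m$arm)) || any(m$arm == "")) {
      mid <- (m$start + m$end) / 2
      derived <- ifelse(mid <= len / 2, "5p", "3p")
      if (is.null(m$arm)) m$arm <- derived
      else m$arm[is.na(m$arm) | m$arm == ""] <- derived[is.na(m$arm) | m$arm == ""]
    }
    if (is.null(m$sequence))
      m$sequence <- as.character(Biostrings::subseq(
        hairpins[m$precursor_id], start = m$start, end = m$end))
  } else {
    m <- data.frame(precursor_id = character(), mature_id = character(),
                    arm = character(), start = integer(), end = integer(),
                    sequence = character(), stringsAsFactors = FALSE)
  }
  m <- m[, c("precursor_id", "mature_id", "arm", "start", "end", "sequence")]
  rownames(m) <- NULL
  new("PrecursorAnnotations", hairpins = hairpins, matures = m,
      loci = loci, hostGenes = hostGenes)
}

#' @describeIn PrecursorAnnotations-class display a summary
#' @param object a \code{PrecursorAnnotations}
#' @export
setMethod("show", "PrecursorAnnotations", function(object) {
  cat("PrecursorAnnotations:", length(object@hairpins), "hairpins,",
      nrow(object@matures), "mature records,",
      length(object@loci), "genomic loci,",
      length(object@hostGenes), "host-gene assignments\n")
})

#' Accessors for PrecursorAnnotations
#'
#' @param x a \linkS4class{PrecursorAnnotations}
#' @return \code{hairpinSeqs}: the \code{DNAStringSet}; \code{matureRecords}:
#'   the mature data.frame; \code{genomicLoci}: the \code{GRanges};
#'   \code{hostGeneMap}: the named character vector.
#' @export
hairpinSeqs <- function(x) x@hairpins

#' @rdname hairpinSeqs
#' @export
matureRecords <- function(x) x@matures

#' @rdname hairpinSeqs
#' @export
genomicLoci <- function(x) x@loci

#' @rdname hairpinSeqs
#' @export
hostGeneMap <- function(x) x@hostGenes

#' MirnaExpression: an entity-by-tissue expression matrix
#'
#' Extends \code{SummarizedExperiment} with a single assay holding raw read
#' counts or reads-per-million values. Metadata records the quantification
#' level ("precursor", "major" or "minor"), whether the matrix is
#' normalised, the scale constant, and the per-tissue library totals used
#' (or to be used) for normalisation.
#'
#' @name MirnaExpression-class
#' @rdname MirnaExpression-class
#' @exportClass MirnaExpression
setClass("MirnaExpression", contains = "SummarizedExperiment")

setValidity("MirnaExpression", function(object) {
  v <- SummarizedExperiment::assay(object)
  if (any(v < 0)) return("expression values must be non-negative")
  TRUE
})

#' Construct a MirnaExpression matrix
#'
#' @param values numeric matrix, rows = entities, columns = tissues.
#' @param level quantification level label.
#' @param normalized logical; TRUE for reads-per-million values.
#' @param scale normalisation constant (1e6 for RPM).
#' @param libTotals optional named per-tissue library totals.
#' @return A \linkS4class{MirnaExpression}.
#' @export
MirnaExpression <- function(values, level = "precursor", normalized = FALSE,
                            scale = 1e6, libTotals = NULL) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values))
  obj <- new("MirnaExpression", se)
  metadata(obj) <- list(level = level, normalized = normalized,
                        scale = scale, libTotals = libTotals)
  obj
}

#' Accessors for MirnaExpression
#'
#' @param x a \linkS4class{MirnaExpression} (plain matrices are passed
#'   through by \code{exprValues} for convenience).
#' @return \code{exprValues}: the numeric matrix; \code{isNormalized}:
#'   logical; \code{exprLevel}: the level label.
#' @export
exprValues <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' @rdname exprValues
#' @export
isNormalized <- function(x) isTRUE(metadata(x)$normalized)

#' @rdname exprValues
#' @export
exprLevel <- function(x) metadata(x)$level

#' ArmProfiles: guide/passenger assignments per precursor
#'
#' @slot info data.frame with one row per precursor: \code{precursor_id},
#'   \code{major_position}, \code{major_arm}, \code{minor_position},
#'   \code{minor_arm} (positions NA when undefined), \code{zero_reads},
#'   \code{one_arm} logical flags.
#' @slot majorCounts,minorCounts,precursorCounts numeric matrices
#'   (precursor x tissue) of reads at the major start, at the minor start,
#'   and summed over all starts.
#'
#' @name ArmProfiles-class
#' @rdname ArmProfiles-class
#' @exportClass ArmProfiles
setClass("ArmProfiles",
  representation(info = "data.frame", majorCounts = "matrix",
                 minorCounts = "matrix", precursorCounts = "matrix"))

setValidity("ArmProfiles", function(object) {
  n <- nrow(object@info)
  if (nrow(object@majorCounts) != n || nrow(object@minorCounts) != n ||
      nrow(object@precursorCounts) != n)
    return("count matrices must have one row per profiled precursor")
  if (any(object@minorCounts > object@precursorCounts + 1e-9))
    return("minor counts cannot exceed precursor counts")
  TRUE
})

#' @describeIn ArmProfiles-class display a summary
#' @param object an \code{ArmProfiles}
#' @export
setMethod("show", "ArmProfiles", function(object) {
  cat("ArmProfiles:", nrow(object@info), "precursors,",
      ncol(object@precursorCounts), "tissues;",
      sum(object@info$zero_reads), "zero-read,",
      sum(object@info$one_arm), "single-arm\n")
})

#' Accessors for ArmProfiles
#'
#' @param x an \linkS4class{ArmProfiles}
#' @param which one of "major", "minor", "precursor".
#' @return \code{armInfo}: the per-precursor assignment data.frame;
#'   \code{armCounts}: the requested precursor-by-tissue count matrix.
#' @export
armInfo <- function(x) x@info

#' @rdname armInfo
#' @export
armCounts <- function(x, which = c("major", "minor", "precursor")) {
  which <- match.arg(which)
  switch(which, major = x@majorCounts, minor = x@minorCounts,
         precursor = x@precursorCounts)
}

#' CoexpressionInputs: the M / T / Q triplet for coexpression scoring
#'
#' @slot M numeric entity-by-tissue read-count matrix (Mij).
#' @slot Ti per-entity totals across tissues (row sums of M).
#' @slot Qj per-tissue fraction of all reads in the scoring universe
#'   (sums to 1).
#'
#' @name CoexpressionInputs-class
#' @rdname CoexpressionInputs-class
#' @exportClass CoexpressionInputs
setClass("CoexpressionInputs",
  representation(M = "matrix", Ti = "numeric", Qj = "numeric"))

setValidity("CoexpressionInputs", function(object) {
  if (any(object@M < 0)) return("M must be non-negative")
  if (length(object@Ti) != nrow(object@M)) return("Ti length must match rows of M")
  if (length(object@Qj) != ncol(object@M)) return("Qj length must match columns of M")
  if (abs(sum(object@Qj) - 1) > 1e-9) return("Qj must sum to 1")
  if (max(abs(object@Ti - rowSums(object@M))) > 1e-6 * max(1, max(object@Ti)))
    return("Ti must equal the row sums of M")
  TRUE
})

#' @describeIn CoexpressionInputs-class display a summary
#' @param object a \code{CoexpressionInputs}
#' @export
setMethod("show", "CoexpressionInputs", function(object) {
  cat("CoexpressionInputs:", nrow(object@M), "entities x", ncol(object@M),
      "tissues; total reads", sum(object@M), "\n")
})
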