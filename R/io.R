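#' Load a long-form read-mapping table
#'
#' Reads a tab-separated file of per-precursor read pileups, one row per
#' (precursor, read start position within the hairpin, tissue), and validates
#' it into a \linkS4class{ReadMappingTable}. Duplicate keys are summed, so
#' loading is insensitive to row order. The canonical dialect has columns
#' \code{precursor_id}, \code{start}, \code{count}, \code{tissue}; other
#' headers can be mapped via \code{columnMap}.
#'
#' @param path path to a TSV file with a header row.
#' @param columnMap named character vector mapping the canonical names to
#'   the file's column names, e.g. \code{c(count = "reads")}.
#' @param tissues optional explicit tissue ordering.
#' @param verbose log the row count and tissue list to stderr.
#' @return A \linkS4class{ReadMappingTable}.
#' @export
loadReadMappings <- function(path, columnMap = character(0), tissues = NULL,
                             verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("precursor_id", "start", "count", "tissue")
  src <- need
  names(src) <- need
  src[names(columnMap)] <- columnMap
  miss <- src[!src %in% names(raw)]
  if (length(miss))
    stop("schema error: missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  rec <- data.frame(precursor_id = raw[[src["precursor_id"]]],
                    start = raw[[src["start"]]],
                    count = raw[[src["count"]]],
                    tissue = raw[[src["tissue"]]],
                    stringsAsFactors = FALSE)
  bad <- which(rec$count < 0)
  if (length(bad))
    stop("validation error: negative count at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  tab <- ReadMappingTable(rec, tissues = tissues)
  if (verbose)
    message("loaded ", nrow(readRecords(tab)), " records (",
            nrow(rec), " input rows) across ",
            length(tissueLabels(tab)), " tissues: ",
            paste(tissueLabels(tab), collapse = ", "))
  tab
}

#' Write a read-mapping table in the canonical TSV dialect
#'
#' @param x a \linkS4class{ReadMappingTable}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeReadMappings <- function(x, path) {
  utils::write.table(readRecords(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load precursor annotations from FASTA + GFF3 (+ host-gene map)
#'
#' Hairpin sequences come from a FASTA; mature coordinates within hairpins
#' from a GFF3 whose seqids are precursor ids (1-based inclusive, the
#' miRBase convention); genomic loci from a second GFF3 whose attributes
#' carry \code{ID=} (the precursor id); host genes from an optional
#' two-column TSV (precursor_id, host_gene). When a mature feature carries
#' no explicit \code{arm} attribute the arm is derived from the mature
#' midpoint relative to the hairpin midpoint.
#'
#' @param hairpinFasta FASTA of hairpin sequences named by precursor id.
#' @param matureGff GFF3 of mature features in hairpin coordinates; the
#'   \code{ID} (or \code{Name}) attribute is the mature id.
#' @param genomicGff optional GFF3 of precursor genomic loci.
#' @param hostMap optional TSV with columns \code{precursor_id},
#'   \code{host_gene}.
#' @return A \linkS4class{PrecursorAnnotations}.
#' @export
loadAnnotations <- function(hairpinFasta, matureGff, genomicGff = NULL,
                            hostMap = NULL) {
  hp <- Biostrings::readDNAStringSet(hairpinFasta)
  names(hp) <- sub("\\s.*$", "", names(hp))
  gff <- rtracklayer::import(matureGff, format = "gff3")
  ids <- as.character(gff$ID)
  if (all(is.na(ids)) && !is.null(gff$Name)) ids <- as.character(gff$Name)
  arm <- if (!is.null(gff$arm)) as.character(gff$arm) else rep(NA_character_,
                                                               length(gff))
  matures <- data.frame(
    precursor_id = as.character(GenomicRanges::seqnames(gff)),
    mature_id = ids,
    arm = arm,
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    stringsAsFactors = FALSE)
  orphan <- setdiff(matures$precursor_id, names(hp))
  if (length(orphan))
    stop("reference error: mature feature(s) for unknown hairpin(s): ",
         paste(orphan, collapse = ", "))
  loci <- GenomicRanges::GRanges()
  if (!is.null(genomicGff)) {
    g <- rtracklayer::import(genomicGff, format = "gff3")
    names(g) <- as.character(g$ID)
    loci <- g
  }
  hosts <- character(0)
  if (!is.null(hostMap)) {
    hm <- utils::read.delim(hostMap, stringsAsFactors = FALSE)
    if (!all(c("precursor_id", "host_gene") %in% names(hm)))
      stop("schema error: host map needs columns precursor_id, host_gene")
    hosts <- stats::setNames(hm$host_gene, hm$precursor_id)
  }
  PrecursorAnnotations(hp, matures, loci = loci, hostGenes = hosts)
}

#' Write annotations back to FASTA/GFF3/TSV
#'
#' Emits the same dialects \code{\link{loadAnnotations}} reads, so a
#' write/read cycle reproduces the object.
#'
#' @param ann a \linkS4class{PrecursorAnnotations}.
#' @param hairpinFasta,matureGff,genomicGff,hostMap output paths
#'   (genomic/host files only written when the object has content).
#' @return invisibly, NULL.
#' @export
writeAnnotations <- function(ann, hairpinFasta, matureGff,
                             genomicGff = NULL, hostMap = NULL) {
  Biostrings::writeXStringSet(hairpinSeqs(ann), hairpinFasta)
  m <- matureRecords(ann)
  gr <- GenomicRanges::GRanges(m$precursor_id,
                               IRanges::IRanges(m$start, m$end))
  gr$source <- "paralomiR"
  gr$type <- "miRNA"
  gr$ID <- m$mature_id
  gr$arm <- m$arm
  rtracklayer::export(gr, matureGff, format = "gff3")
  if (!is.null(genomicGff) && length(genomicLoci(ann))) {
    g <- genomicLoci(ann)
    g$source <- "paralomiR"
    g$type <- "miRNA_primary_transcript"
    g$ID <- names(g)
    rtracklayer::export(g, genomicGff, format = "gff3")
  }
  if (!is.null(hostMap) && length(hostGeneMap(ann))) {
    utils::write.table(
      data.frame(precursor_id = names(hostGeneMap(ann)),
                 host_gene = unname(hostGeneMap(ann))),
      hostMap, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Write an expression matrix as a GenePattern GCT 1.2 file
#'
#' The GCT layout: a "#1.2" version line, a dimension line
#' "rows<TAB>columns", a header (Name, Description, tissue labels), then one
#' row per entity. Values are serialised with 6 significant digits. Zero
#' rows are preserved.
#'
#' @param x a \linkS4class{MirnaExpression} or numeric matrix with dimnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGct <- function(x, path) {
  v <- exprValues(x)
  if (nrow(v) == 0 || ncol(v) == 0)
    stop("refusing to write an empty matrix as GCT")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1, function(r)
    paste(formatC(signif(r, 6), format = "g", digits = 6), collapse = "\t"))
  writeLines(paste(rownames(v), rownames(v), body, sep = "\t"), con)
  invisible(path)
}

#' Parse a GCT 1.2 file back into a matrix
#'
#' @param path a GCT file written by \code{\link{writeGct}} or GenePattern.
#' @return numeric matrix with entity rownames and tissue colnames.
#' @export
readGct <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#1.2") stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]])
  header <- strsplit(lines[3], "\t")[[1]]
  body <- strsplit(lines[3 + seq_len(dims[1])], "\t")
  m <- t(vapply(body, function(f) as.numeric(f[-(1:2)]), numeric(dims[2])))
  if (dims[2] == 1) m <- matrix(m, ncol = 1)
  rownames(m) <- vapply(body, `[`, character(1), 1)
  colnames(m) <- header[-(1:2)]
  m
}

#' Write a tabular report as deterministic TSV
#'
#' Rows are sorted lexicographically over all columns (left to right) so
#' identical inputs always produce byte-identical files; an empty report
#' yields a header-only file.
#'
#' @param report a data.frame.
#' @param path output path.
#' @param sortKeys columns to sort by; default all columns left to right.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path, sortKeys = names(report)) {
  stopifnot(is.data.frame(report))
  if (nrow(report) > 1 && length(sortKeys))
    report <- report[do.call(order, report[sortKeys]), , drop = FALSE]
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
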