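#' Configuration for the synthetic small-RNA study generator
#'
#' The defaults describe the study conditions the rest of the package is
#' exercised against: a 15-tissue mouse-style panel, six two-member
#' paralogous families sharing one major mature sequence with distinct
#' minors, each member planted as the sole contributor in one
#' member-specific tissue; singleton miRNAs including planted
#' tissue-specific and tissue-selective patterns; planted genomic clusters;
#' negative-binomial count noise (size 50, mild overdispersion on top of
#' Poisson, reflecting one pooled sequencing library per tissue); and a
#' filler background bringing each tissue's expected library to
#' \code{librarySize} reads.
#'
#' @param tissues tissue panel (default \code{\link{mousePanelTissues}}).
#' @param nFamilies number of paralogous families (default 6).
#' @param membersPerFamily precursors per family (default 2).
#' @param majorLevel expected major-form reads in a member's contributing
#'   tissue (default 2000).
#' @param minorRatio minor:major expected-read ratio (default 0.1).
#' @param dispersionSize negative-binomial size parameter; larger is less
#'   overdispersed, \code{Inf} gives Poisson-free exact means of 0 noise
#'   (use \code{dispersionSize = Inf} with \code{poisson = FALSE} for the
#'   noise-free limit) (default 50).
#' @param noiseFree logical; TRUE emits exact expected counts (default
#'   FALSE).
#' @param librarySize expected total reads per tissue (default 3e5).
#' @param nSpecific,nSelective,nBroad singleton miRNAs planted with
#'   one-tissue, two-tissue and broad expression (defaults 4, 4, 4).
#' @param singletonLevel expected reads of a planted singleton in its
#'   pattern tissues (default 1500).
#' @param backgroundLevel expected off-pattern singleton reads
#'   (default 2).
#' @param clusterSizes sizes of planted genomic clusters (default c(2, 3)).
#' @param clusterGap intra-cluster gap in bp, below the 5000 bp rule
#'   (default 2000).
#' @param interClusterGap gap separating unclustered loci (default 50000).
#' @param noisePositionRate expected reads at a satellite start adjacent to
#'   the major start, as a fraction of the major level (default 0.01).
#' @param indistinguishableFamilies how many families share the minor
#'   sequence across members as well (default 0).
#' @param nFiller filler background precursors absorbing the remaining
#'   library (default 20).
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(tissues = mousePanelTissues(),
                             nFamilies = 6, membersPerFamily = 2,
                             majorLevel = 2000, minorRatio = 0.1,
                             dispersionSize = 50, noiseFree = FALSE,
                             librarySize = 3e5,
                             nSpecific = 4, nSelective = 4, nBroad = 4,
                             singletonLevel = 1500, backgroundLevel = 2,
                             clusterSizes = c(2, 3), clusterGap = 2000,
                             interClusterGap = 50000,
                             noisePositionRate = 0.01,
                             indistinguishableFamilies = 0,
                             nFiller = 20) {
  stopifnot(length(tissues) >= 2, nFamilies >= 1, membersPerFamily >= 2,
            majorLevel > 0, minorRatio > 0, minorRatio <= 1,
            dispersionSize > 0, librarySize > 0,
            indistinguishableFamilies <= nFamilies)
  if (nFamilies * membersPerFamily > length(tissues))
    stop("infeasible config: need one distinct contributor tissue per ",
         "family member within the panel, or fewer/larger families")
  structure(as.list(environment()), class = "SimulationConfig")
}

# deterministic random sequence of given length
.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.draw <- function(mu, size, noiseFree) {
  if (noiseFree) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = size)
}

#' Simulate a miRBase-style multi-tissue small-RNA study
#'
#' Generates a read-mapping table, full annotations (hairpins, matures,
#' genomic loci, host genes) and a ground-truth record, reproducibly from
#' the seed. Family members share an identical major mature sequence (and
#' mature id) at a common start position and carry member-specific minors
#' on the opposite arm; each member's reads appear in its planted
#' contributor tissue. A satellite start next to the major exercises the
#' argmax arm assignment. Filler precursors bring every tissue's expected
#' total to the configured library size, so per-tissue totals are conserved
#' up to sampling noise.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed; same seed, same output.
#' @return list with \code{reads} (\linkS4class{ReadMappingTable}),
#'   \code{annotations} (\linkS4class{PrecursorAnnotations}), and
#'   \code{truth} (list: \code{contributors}, \code{patterns},
#'   \code{clusters}, \code{arms}, \code{hostGenes}, expected per-tissue
#'   \code{libTotals}).
#' @export
simulateReads <- function(config = simulationConfig(), seed = 1) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  cf <- config
  tis <- cf$tissues
  nT <- length(tis)
  hplen <- 70L
  p5 <- 8L; p3 <- 44L   # canonical mature starts on each arm (22 nt)
  hairpins <- character(0)
  matures <- list()
  recs <- list()
  truthContrib <- list()
  truthArms <- list()
  truthPatterns <- list()
  hostGenes <- character(0)
  expected <- stats::setNames(rep(0, nT), tis)

  addReads <- function(prec, start, mu) {
    cnt <- .draw(mu, cf$dispersionSize, cf$noiseFree)
    keep <- cnt > 0
    if (!any(keep)) return(NULL)
    data.frame(precursor_id = prec, start = start, count = cnt[keep],
               tissue = tis[keep], stringsAsFactors = FALSE)
  }

  # --- paralogous families -------------------------------------------------
  contribTissues <- sample(tis, cf$nFamilies * cf$membersPerFamily)
  ti <- 0L
  for (f in seq_len(cf$nFamilies)) {
    majorArm <- if (f %% 2 == 1) "5p" else "3p"
    majStart <- if (majorArm == "5p") p5 else p3
    minStart <- if (majorArm == "5p") p3 else p5
    majorSeq <- .randSeq(22)
    majorId <- sprintf("sim-miR-F%d-%s", f, majorArm)
    indist <- f <= cf$indistinguishableFamilies
    sharedMinor <- .randSeq(22)
    for (k in seq_len(cf$membersPerFamily)) {
      prec <- sprintf("sim-mir-F%d-%d", f, k)
      minorSeq <- if (indist) sharedMinor else .randSeq(22)
      hp <- .randSeq(hplen)
      substr(hp, majStart, majStart + 21L) <- majorSeq
      substr(hp, minStart, minStart + 21L) <- minorSeq
      hairpins[prec] <- hp
      minorArm <- setdiff(c("5p", "3p"), majorArm)
      minorId <- if (indist) sprintf("sim-miR-F%d-%s", f, minorArm)
                 else sprintf("sim-miR-F%d-%d-%s", f, k, minorArm)
      matures[[length(matures) + 1L]] <- data.frame(
        precursor_id = prec,
        mature_id = c(majorId, minorId),
        arm = c(majorArm, minorArm),
        start = c(majStart, minStart),
        end = c(majStart, minStart) + 21L,
        stringsAsFactors = FALSE)
      ti <- ti + 1L
      onTissue <- contribTissues[ti]
      muMaj <- ifelse(tis == onTissue, cf$majorLevel, 0)
      muMin <- muMaj * cf$minorRatio
      muSat <- muMaj * cf$noisePositionRate
      recs[[length(recs) + 1L]] <- addReads(prec, majStart, muMaj)
      recs[[length(recs) + 1L]] <- addReads(prec, minStart, muMin)
      recs[[length(recs) + 1L]] <- addReads(prec, majStart + 1L, muSat)
      expected <- expected + muMaj + muMin + muSat
      truthContrib[[length(truthContrib) + 1L]] <- data.frame(
        family_id = majorId, tissue = onTissue, contributor = prec,
        stringsAsFactors = FALSE)
      truthArms[[length(truthArms) + 1L]] <- data.frame(
        precursor_id = prec, major_position = majStart,
        major_arm = majorArm, minor_position = minStart,
        stringsAsFactors = FALSE)
      hostGenes[prec] <- sprintf("SimHost%d_%d", f, k)
    }
    truthPatterns[[length(truthPatterns) + 1L]] <- data.frame(
      mature_id = majorId, call = "selective",
      tissues = paste(sort(contribTissues[(ti - cf$membersPerFamily + 1L):ti]),
                      collapse = ","),
      stringsAsFactors = FALSE)
  }

  # --- singleton miRNAs with planted tissue patterns -----------------------
  singletons <- character(0)
  sCount <- 0L
  addSingleton <- function(kind, patternTissues, mus) {
    sCount <<- sCount + 1L
    prec <- sprintf("sim-mir-S%d", sCount)
    singletons <<- c(singletons, prec)
    hp <- .randSeq(hplen)
    hairpins[prec] <<- hp
    matId <- sprintf("sim-miR-S%d-5p", sCount)
    matures[[length(matures) + 1L]] <<- data.frame(
      precursor_id = prec, mature_id = c(matId, sprintf("sim-miR-S%d-3p", sCount)),
      arm = c("5p", "3p"), start = c(p5, p3), end = c(p5, p3) + 21L,
      stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <<- addReads(prec, p5, mus)
    recs[[length(recs) + 1L]] <<- addReads(prec, p3, mus * 0.05)
    expected <<- expected + mus * 1.05
    if (!is.na(kind))
      truthPatterns[[length(truthPatterns) + 1L]] <<- data.frame(
        mature_id = matId, call = kind,
        tissues = paste(sort(patternTissues), collapse = ","),
        stringsAsFactors = FALSE)
    prec
  }
  for (s in seq_len(cf$nSpecific)) {
    t1 <- tis[(s - 1L) %% nT + 1L]
    mus <- ifelse(tis == t1, cf$singletonLevel, cf$backgroundLevel)
    addSingleton("specific", t1, mus)
  }
  for (s in seq_len(cf$nSelective)) {
    pick <- tis[c((2 * s - 2L) %% nT + 1L, (2 * s - 1L) %% nT + 1L)]
    mus <- ifelse(tis %in% pick, cf$singletonLevel, cf$backgroundLevel)
    addSingleton("selective", pick, mus)
  }
  for (s in seq_len(cf$nBroad))
    addSingleton(NA_character_, character(0), rep(cf$singletonLevel / 10, nT))

  # --- filler background to the configured library size --------------------
  remain <- pmax(0, cf$librarySize - expected)
  for (b in seq_len(cf$nFiller)) {
    prec <- sprintf("sim-mir-BG%d", b)
    hairpins[prec] <- .randSeq(hplen)
    matures[[length(matures) + 1L]] <- data.frame(
      precursor_id = prec, mature_id = sprintf("sim-miR-BG%d-5p", b),
      arm = "5p", start = p5, end = p5 + 21L, stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <- addReads(prec, p5, remain / cf$nFiller)
  }

  # --- genomic loci: planted clusters, then isolated loci ------------------
  precAll <- names(hairpins)
  clustered <- list()
  pool <- singletons
  idx <- 0L
  for (ci in seq_along(cf$clusterSizes)) {
    sz <- cf$clusterSizes[ci]
    if (idx + sz > length(pool)) break
    clustered[[ci]] <- pool[(idx + 1L):(idx + sz)]
    idx <- idx + sz
  }
  pos <- 10000L
  lociStart <- integer(0)
  lociId <- character(0)
  for (members in clustered) {
    for (p in members) {
      lociId <- c(lociId, p)
      lociStart <- c(lociStart, pos)
      pos <- pos + hplen + cf$clusterGap
    }
    pos <- pos + cf$interClusterGap
  }
  for (p in setdiff(precAll, unlist(clustered))) {
    lociId <- c(lociId, p)
    lociStart <- c(lociStart, pos)
    pos <- pos + hplen + cf$interClusterGap
  }
  loci <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(lociStart, width = hplen), strand = "+")
  names(loci) <- lociId

  reads <- ReadMappingTable(do.call(rbind, recs), tissues = tis)
  ann <- PrecursorAnnotations(Biostrings::DNAStringSet(hairpins),
                              do.call(rbind, matures),
                              loci = loci, hostGenes = hostGenes)
  truth <- list(
    contributors = do.call(rbind, truthContrib),
    patterns = do.call(rbind, truthPatterns),
    clusters = lapply(clustered, identity),
    arms = do.call(rbind, truthArms),
    hostGenes = hostGenes,
    libTotals = stats::setNames(rep(cf$librarySize, nT), tis))
  list(reads = reads, annotations = ann, truth = truth, config = cf,
       seed = seed)
}

#' Simulate a comparative-CT qPCR table with planted preferential tissues
#'
#' Target Ct values are lowered by \code{effectLog2} cycles in the planted
#' preferential tissues (one cycle = one doubling), with Gaussian replicate
#' noise; the reference gene is flat across tissues.
#'
#' @param preferential character vector of planted preferential tissues.
#' @param tissues tissue panel.
#' @param nReplicates replicates per tissue (default 3).
#' @param effectLog2 Ct depression in preferential tissues (default 2,
#'   i.e. a 4-fold effect).
#' @param sigma replicate noise SD in cycles (default 0.25; 0 gives the
#'   noise-free limit).
#' @param baseCt,refCt baseline target and reference Ct (defaults 28, 15).
#' @param target,reference gene labels (defaults "sim-miR", "U6").
#' @param seed integer seed.
#' @return data.frame Ct table (tissue, replicate, target, ct).
#' @export
simulateCt <- function(preferential, tissues = mousePanelTissues(),
                       nReplicates = 3, effectLog2 = 2, sigma = 0.25,
                       baseCt = 28, refCt = 15, target = "sim-miR",
                       reference = "U6", seed = 1) {
  set.seed(seed)
  grid <- expand.grid(tissue = tissues, replicate = seq_len(nReplicates),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$tissue %in% preferential, baseCt - effectLog2, baseCt)
  tgt <- data.frame(grid, target = target,
                    ct = mu + stats::rnorm(nrow(grid), 0, sigma))
  ref <- data.frame(grid, target = reference,
                    ct = refCt + stats::rnorm(nrow(grid), 0, sigma))
  out <- rbind(tgt, ref)[, c("tissue", "replicate", "target", "ct")]
  rownames(out) <- NULL
  out
}
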