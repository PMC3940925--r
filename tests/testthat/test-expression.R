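test_that("arm assignment takes the argmax start and the opposite-arm argmax", {
  reads <- ReadMappingTable(data.frame(
    precursor_id = "mir-x", start = c(5, 6, 48),
    count = c(100, 3, 10), tissue = "liver"))
  hp <- Biostrings::DNAStringSet(c("mir-x" = paste(rep("A", 70), collapse = "")))
  ann <- PrecursorAnnotations(hp, data.frame(
    precursor_id = "mir-x", mature_id = "miR-x-5p",
    arm = "5p", start = 5, end = 26))
  prof <- assignArms(reads, ann)
  info <- armInfo(prof)
  expect_equal(info$major_position, 5L)
  expect_equal(info$major_arm, "5p")
  expect_equal(info$minor_position, 48L)
  expect_equal(info$minor_arm, "3p")
})

test_that("one-arm and zero-read precursors are flagged", {
  hp <- Biostrings::DNAStringSet(c(a = strrep("A", 70), b = strrep("C", 70)))
  ann <- PrecursorAnnotations(hp, data.frame(
    precursor_id = "a", mature_id = "a-5p", arm = "5p", start = 5, end = 26))
  reads <- ReadMappingTable(data.frame(
    precursor_id = "a", start = 5, count = 10, tissue = "t1"))
  prof <- assignArms(reads, ann)
  info <- armInfo(prof)
  expect_true(info$one_arm[info$precursor_id == "a"])
  expect_true(info$zero_reads[info$precursor_id == "b"])
  expect_true(all(armCounts(prof, "minor") == 0))
  expect_true(is.na(info$minor_position[info$precursor_id == "a"]))
})

test_that("planted argmax positions are recovered on random pileups", {
  # brute-force oracle: plant a known argmax on each arm, scatter noise
  set.seed(101)
  hp <- Biostrings::DNAStringSet(c(p = strrep("G", 70)))
  ann <- PrecursorAnnotations(hp, data.frame(
    precursor_id = "p", mature_id = "p-5p", arm = "5p", start = 3, end = 24))
  for (i in 1:100) {
    maj <- sample(1:35, 1); mino <- sample(36:49, 1)
    noise <- setdiff(sample(1:49, 6), c(maj, mino))
    df <- data.frame(
      precursor_id = "p",
      start = c(maj, mino, noise),
      count = c(500, 200, sample(1:100, length(noise))),
      tissue = sample(c("t1", "t2"), 2 + length(noise), replace = TRUE))
    reads <- ReadMappingTable(df, tissues = c("t1", "t2"))
    # independent argmax over the summed pileup
    agg <- aggregate(count ~ start, readRecords(reads), sum)
    expectMaj <- agg$start[which.max(agg$count)]
    info <- armInfo(assignArms(reads, ann))
    expect_equal(info$major_position, expectMaj)
    expect_equal(info$minor_position, mino)
  }
})

test_that("argmax ties break toward the 5'-most position", {
  hp <- Biostrings::DNAStringSet(c(p = strrep("A", 70)))
  ann <- PrecursorAnnotations(hp, data.frame(
    precursor_id = "p", mature_id = "p-5p", arm = "5p", start = 3, end = 24))
  reads <- ReadMappingTable(data.frame(
    precursor_id = "p", start = c(20, 10), count = c(50, 50), tissue = "t1"))
  expect_equal(armInfo(assignArms(reads, ann))$major_position, 10L)
})

test_that("quantification sums starts per level and conserves totals", {
  reads <- tinyReads()
  ann <- tinyAnnotations()
  prof <- assignArms(reads, ann)
  prec <- exprValues(quantifyExpression(reads, prof, "precursor"))
  maj <- exprValues(quantifyExpression(reads, prof, "major"))
  mino <- exprValues(quantifyExpression(reads, prof, "minor"))
  expect_equal(prec["mir-x", "liver"], 113)
  expect_equal(maj["mir-x", "liver"], 100)
  expect_equal(mino["mir-x", "liver"], 10)
  expect_equal(sum(prec), sum(readRecords(reads)$count))
  expect_true(all(mino <= prec))
})

test_that("identical per-tissue reads give identical matrix columns", {
  df <- expand.grid(start = c(5, 45), tissue = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  df$precursor_id <- "mir-x"; df$count <- c(100, 10, 100, 10)
  reads <- ReadMappingTable(df)
  hp <- Biostrings::DNAStringSet(c("mir-x" = strrep("A", 70)))
  ann <- PrecursorAnnotations(hp, data.frame(
    precursor_id = "mir-x", mature_id = "x-5p", arm = "5p",
    start = 5, end = 26))
  m <- exprValues(quantifyExpression(reads, assignArms(reads, ann), "precursor"))
  expect_equal(m[, "t1"], m[, "t2"])
})

test_that("RPM normalisation scales by library totals and is scale-equivariant", {
  m <- matrix(c(50, 10, 50, 30), 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  norm <- normalizeRpm(m, libTotals = c(t1 = 1e6, t2 = 2e5))
  expect_equal(exprValues(norm)["a", "t1"], 50)      # 50 reads in a million
  expect_true(isNormalized(norm))
  # scaling one tissue's counts and total leaves the column unchanged
  norm2 <- normalizeRpm(m * c(1, 1) %o% c(3, 1),
                        libTotals = c(t1 = 3e6, t2 = 2e5))
  expect_equal(exprValues(norm2), exprValues(norm))
  # conservation: entities partitioning all reads sum to the scale
  sim <- simulateReads(simulationConfig(), seed = 3)
  prof <- assignArms(sim$reads, sim$annotations)
  prec <- quantifyExpression(sim$reads, prof, "precursor")
  n <- exprValues(normalizeRpm(prec))
  expect_equal(unname(colSums(n)), rep(1e6, 15), tolerance = 1e-9)
})

test_that("zero library totals are rejected unless the column is zero", {
  m <- matrix(c(5, 0), 1, dimnames = list("a", c("t1", "t2")))
  expect_error(normalizeRpm(m, libTotals = c(t1 = 0, t2 = 10)), "impossible")
  m0 <- matrix(c(0, 5), 1, dimnames = list("a", c("t1", "t2")))
  expect_equal(exprValues(normalizeRpm(m0, libTotals = c(t1 = 0, t2 = 10)))[1, 1], 0)
})

test_that("arm ratios: filter, Inf sentinel, ratio classes, switch tissues", {
  mkProf <- function(majT1, majT2, minT1, minT2) {
    info <- data.frame(precursor_id = "p", major_position = 5L,
                       major_arm = "5p", minor_position = 45L,
                       minor_arm = "3p", zero_reads = FALSE, one_arm = FALSE)
    new("ArmProfiles", info = info,
        majorCounts = matrix(c(majT1, majT2), 1, dimnames = list("p", c("t1", "t2"))),
        minorCounts = matrix(c(minT1, minT2), 1, dimnames = list("p", c("t1", "t2"))),
        precursorCounts = matrix(c(majT1 + minT1, majT2 + minT2), 1,
                                 dimnames = list("p", c("t1", "t2"))))
  }
  r <- armRatios(mkProf(300, 100, 1, 0))
  expect_equal(r$ratio, 400)
  expect_equal(r$ratio_class, "10-400")
  r2 <- armRatios(mkProf(401, 0, 1, 0))
  expect_equal(r2$ratio_class, ">400")
  r3 <- armRatios(mkProf(300, 100, 0, 0))
  expect_equal(r3$ratio, Inf)
  # switch tissue: minor > major in t2
  r4 <- armRatios(mkProf(90, 10, 10, 50))
  expect_equal(r4$ratio, 100 / 60)
  expect_equal(r4$arm_switch_tissues, "t2")
  expect_equal(r4$ratio_class, "<10")
  # strict > 50 filter on the major total
  expect_equal(nrow(armRatios(mkProf(40, 10, 5, 5))), 0)
  expect_equal(nrow(armRatios(mkProf(40, 11, 5, 5))), 1)
})

test_that("planted arm switches are flagged exactly (brute-force comparison)", {
  set.seed(5)
  for (i in 1:20) {
    maj <- matrix(rpois(10, 50), 2,
                  dimnames = list(c("a", "b"), paste0("t", 1:5)))
    mino <- matrix(rpois(10, 50), 2, dimnames = dimnames(maj))
    prof <- new("ArmProfiles",
      info = data.frame(precursor_id = c("a", "b"), major_position = 5L,
                        major_arm = "5p", minor_position = 45L,
                        minor_arm = "3p", zero_reads = FALSE, one_arm = FALSE),
      majorCounts = maj, minorCounts = mino, precursorCounts = maj + mino)
    r <- armRatios(prof, minTotal = 0)
    for (p in c("a", "b")) {
      planted <- colnames(maj)[mino[p, ] > maj[p, ]]
      got <- strsplit(r$arm_switch_tissues[r$precursor_id == p], ",")[[1]]
      expect_equal(sort(got), sort(planted))
    }
  }
})
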