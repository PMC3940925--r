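toyInputs <- function(M, universe = M) {
  coexpressionInputsFromMatrix(M, universe, minReads = 0)
}

test_that("M/T/Q inputs follow their definitions and the major-read filter", {
  uni <- matrix(c(60, 40, 40, 260), 2, byrow = TRUE,
                dimnames = list(c("u1", "u2"), c("t1", "t2")))
  maj <- matrix(c(60, 40, 30, 10), 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("t1", "t2")))
  mino <- matrix(c(6, 4, 3, 1), 2, byrow = TRUE, dimnames = dimnames(maj))
  inp <- buildCoexpressionInputs(maj, mino, uni, minReads = 50)
  # universe totals per tissue (100, 300) -> Q = (0.25, 0.75)
  expect_equal(unname(inp@Qj), c(0.25, 0.75))
  # p2's major total is 40 <= 50: pair dropped, minors of p1 retained
  expect_setequal(rownames(inp@M), c("major|p1", "minor|p1"))
  expect_equal(unname(inp@Ti), unname(rowSums(inp@M)))
  # single tissue: Q = 1
  one <- coexpressionInputsFromMatrix(
    matrix(100, 1, 1, dimnames = list("a", "t1")), minReads = 0)
  expect_equal(unname(one@Qj), 1)
  # random fixture: Ti equals an independent row-sum recomputation
  set.seed(1)
  r <- matrix(rpois(50, 40), 10,
              dimnames = list(paste0("e", 1:10), paste0("t", 1:5)))
  ri <- toyInputs(r)
  expect_equal(unname(ri@Ti), unname(apply(r, 1, function(x) sum(x))))
  expect_equal(sum(ri@Qj), 1)
})

test_that("tissue specificity matches spreadsheet arithmetic on a toy matrix", {
  M <- matrix(c(90, 10, 20, 80), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  inp <- toyInputs(M)
  Z <- tissueSpecificityZ(inp)
  # by hand: Q = (110/200, 90/200); T = (100, 100)
  q1 <- 110 / 200
  denom <- sqrt(100 * q1 * (1 - q1))
  expect_equal(Z["a", "t1"], (90 - 100 * q1) / denom)
  expect_equal(Z["b", "t2"], (80 - 100 * (1 - q1)) / sqrt(100 * (1 - q1) * q1))
  # depletion is clamped to zero
  expect_equal(Z["a", "t2"], 0)
  expect_equal(Z["b", "t1"], 0)
  # no reads, no specificity
  M0 <- M; M0["a", "t1"] <- 0
  expect_equal(tissueSpecificityZ(toyInputs(M0))["a", "t1"], 0)
  expect_error(tissueSpecificityZ(inp, "nope"), "unknown entity")
})

test_that("coexpression score is the product of pair specificities", {
  M <- matrix(c(500, 20, 50, 5, 10, 400, 1, 40), 4, byrow = TRUE,
              dimnames = list(c("majA", "minA", "majB", "minB"),
                              c("t1", "t2")))
  inp <- toyInputs(M)
  Z <- tissueSpecificityZ(inp)
  s <- coexpressionScore(inp, "majA", "minA")
  expect_equal(unname(s), unname(Z["majA", ] * Z["minA", ]))
  expect_true(all(s >= 0))
  # permuting tissue columns permutes Z and scores identically
  M2 <- M[, c("t2", "t1")]
  s2 <- coexpressionScore(toyInputs(M2), "majA", "minA")
  expect_equal(s2, s[c("t2", "t1")])
})

test_that("pairs with an all-zero minor score exactly zero everywhere", {
  set.seed(7)
  for (i in 1:200) {
    nT <- sample(2:15, 1)
    M <- matrix(rpois(3 * nT, 200), 3,
                dimnames = list(c("maj", "other", "minorZero"),
                                paste0("t", seq_len(nT))))
    M["minorZero", ] <- 0
    inp <- toyInputs(M)
    expect_identical(unname(coexpressionScore(inp, "maj", "minorZero")),
                     rep(0, nT))
    # also when the minor never entered the matrix at all
    expect_identical(unname(coexpressionScore(inp, "maj", "absent-minor")),
                     rep(0, nT))
  }
})

test_that("top-decile selection matches the sort-and-slice oracle", {
  # 10 distinct scores: exactly one flagged
  s10 <- c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10)
  sel <- selectTopDecile(s10)
  expect_equal(sum(sel$selected_top10), 1)
  expect_true(sel$selected_top10[s10 == 10])
  # ties at the cutoff are all included: 20 scores, 2nd and 3rd tied
  s20 <- c(100, rep(90, 2), seq(80, 64, length.out = 17))
  expect_equal(sum(selectTopDecile(s20)$selected_top10), 3)
  # selected scores never include zeros and respect the rank invariant
  set.seed(11)
  for (i in 1:50) {
    s <- round(rexp(sample(5:200, 1)) * 100)
    sel <- selectTopDecile(s)
    expect_equal(sel$selected_top10, bruteTopDecile(s))
    k <- ceiling(0.1 * length(s))
    expect_true(all(sel$rank_percentile[sel$selected_top10] <=
                      100 * k / length(s) + 1e-9))
  }
})

test_that("Fisher exact p matches enumeration and stats::fisher.test", {
  # full hypergeometric enumeration oracle on assorted tables
  tabs <- rbind(c(5, 5, 5, 5), c(10, 0, 0, 10), c(3, 17, 12, 8),
                c(0, 12, 7, 3), c(1, 1, 30, 2), c(8, 0, 4, 4))
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; b <- tabs[i, 2]; c <- tabs[i, 3]; d <- tabs[i, 4]
    expect_equal(fisherExactP(a, b, c, d), enumFisherP(a, b, c, d),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(fisherExactP(a, b, c, d), min(1, ft), tolerance = 1e-7)
  }
  expect_equal(fisherExactP(5, 5, 5, 5), 1)
  expect_equal(fisherExactP(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisherExactP(0, 0, 0, 0), 1)  # degenerate convention
})

test_that("sibling minor screen builds the tissue-vs-elsewhere table", {
  m <- matrix(c(200, 0, 0, 0, 180, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("t1", "t2", "t3")))
  out <- fisherMinorFilter(m, tissue = "t1")
  ab <- out[out$member_a == "A" & out$member_b == "B", ]
  expect_equal(ab$fisher_p, fisherExactP(200, 0, 0, 180), tolerance = 1e-12)
  expect_true(ab$pass)
  expect_true(ab$a_enriched)
  ba <- out[out$member_a == "B" & out$member_b == "A", ]
  expect_false(ba$a_enriched)
  # degenerate all-zero column
  z <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("t1", "t2")))
  dz <- fisherMinorFilter(z, tissue = "t1")
  expect_true(all(dz$fisher_p == 1))
  expect_true(all(dz$degenerate))
  expect_error(fisherMinorFilter(m[1, , drop = FALSE]), "two minor")
})

test_that("discrimination report calls the planted contributor per tissue", {
  sim <- simulateReads(simulationConfig(), seed = 301)
  prof <- assignArms(sim$reads, sim$annotations)
  fams <- findFamilies(sim$annotations, prof)
  rep <- discriminationReport(
    fams,
    quantifyExpression(sim$reads, prof, "major"),
    quantifyExpression(sim$reads, prof, "minor"),
    quantifyExpression(sim$reads, prof, "precursor"))
  expect_named(rep, c("family_id", "precursor_id", "major_id", "minor_id",
                      "tissue", "Z_major", "Z_minor", "score",
                      "rank_percentile", "selected_top10", "fisher_p",
                      "passes"))
  calls <- contributorCalls(rep)
  tr <- sim$truth$contributors
  names(tr)[names(tr) == "contributor"] <- "planted"
  m <- merge(tr, calls, by = c("family_id", "tissue"))
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(!m$unresolved))
  expect_equal(m$contributor, m$planted)
  # tissues with no planted signal stay unresolved
  off <- calls[!paste(calls$family_id, calls$tissue) %in%
                 paste(tr$family_id, tr$tissue), ]
  expect_true(all(off$unresolved))
})

test_that("indistinguishable families are reported unresolved with a reason", {
  sim <- simulateReads(simulationConfig(indistinguishableFamilies = 1),
                       seed = 5)
  prof <- assignArms(sim$reads, sim$annotations)
  fams <- findFamilies(sim$annotations, prof, mode = "by_sequence")
  expect_true(any(fams$indistinguishable))
  rep <- discriminationReport(
    fams,
    quantifyExpression(sim$reads, prof, "major"),
    quantifyExpression(sim$reads, prof, "minor"),
    quantifyExpression(sim$reads, prof, "precursor"))
  calls <- contributorCalls(rep)
  ind <- calls[calls$family_id %in% fams$family_id[fams$indistinguishable], ]
  expect_true(all(ind$unresolved))
  expect_true(all(ind$reason == "indistinguishable minors"))
})
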