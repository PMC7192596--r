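test_that("subtype heuristics reproduce the documented thresholds", {
  # 20 proteins, 8 ICE hits (40%): ICE1
  t1 <- typeIge(20L, 0L, 0L, 8L, 30000L)
  expect_true(t1$ice1)
  expect_identical(t1$final, "ICE")
  # one virion plus one non-virion hit, no ICE: strong phage
  t2 <- typeIge(30L, 1L, 1L, 0L, 40000L)
  expect_true(t2$phage1)
  expect_identical(t2$final, "Phage")
  # phage1 and ice1 together: the composite category
  t3 <- typeIge(20L, 1L, 1L, 8L, 30000L)
  expect_identical(t3$final, "ICE+Phage")
  # ICE2 length dependence: 2 hits of 20 proteins (10%) passes only >=10 kb
  expect_false(typeIge(20L, 0L, 0L, 2L, 8000L)$ice2)
  expect_true(typeIge(20L, 0L, 0L, 2L, 20000L)$ice2)
  # weak phage call
  expect_identical(typeIge(20L, 1L, 0L, 0L, 8000L)$final, "Phage-weak")
})

test_that("all 16 flag combinations map to the documented final types", {
  expected <- function(p1, p2, i1, i2) {
    ice <- i1 || i2
    if (p1 && ice) "ICE+Phage"
    else if (p1) "Phage"
    else if (ice) "ICE"
    else if (p2) "Phage-weak"
    else "Unknown"
  }
  for (p1 in c(FALSE, TRUE)) for (p2 in c(FALSE, TRUE))
    for (i1 in c(FALSE, TRUE)) for (i2 in c(FALSE, TRUE))
      expect_identical(finalType(p1, p2, i1, i2), expected(p1, p2, i1, i2),
                       label = paste(p1, p2, i1, i2))
})

test_that("recall correction reproduces the survey composition arithmetic", {
  out <- estimateComposition(c(phage = 0.378, ice = 0.092),
                             c(phage = 0.982, ice = 0.752))
  expect_equal(round(100 * unname(out["phage"]), 1), 38.5)
  expect_equal(round(100 * unname(out["ice"]), 1), 12.2)
  expect_equal(unname(out["unknown"]), 1 - sum(out[c("phage", "ice")]))
  # recall 1 is the identity
  id <- estimateComposition(c(phage = 0.3), c(phage = 1))
  expect_equal(unname(id["phage"]), 0.3)
  expect_error(estimateComposition(c(phage = 0.3), c(phage = 0)), "positive")
})

test_that("att windows yield 12 attLR and 18 attB peptides", {
  fx <- standardFixture()
  repSeq <- as.character(replicons(fx$query)[["chr"]])
  pep <- buildAttPeptides(repSeq, fx$truth$left, fx$truth$right,
                          drSeq = fx$truth$dr_seq)
  expect_equal(sum(pep$group == "attLR"), 12L)
  expect_equal(sum(pep$group == "attB"), 18L)
  expect_true(all(pep$center >= 1))
  # an all-N window translates to X residues and scores nothing
  nn <- buildAttPeptides(strrep("N", 5000), 2500L, 3500L)
  expect_true(all(grepl("^X*$", nn$peptide[nn$group == "attLR"])))
  hits <- stubHmmScorer(list(list(pfam = "D", peptide = strrep("W", 40),
                                  fullScore = 100)))(nn$peptide)
  expect_equal(nrow(hits), 0L)
})

test_that("one attB frame combination restores the uninterrupted protein", {
  sp <- fixtureSpec(iges = list(list(target = "CDS-domain", drLen = 0L)))
  fx <- generateFixture(sp, seed = 21)
  repSeq <- as.character(replicons(fx$query)[["chr"]])
  pep <- buildAttPeptides(repSeq, fx$truth$left, fx$truth$right)
  dom <- fx$domains[[1]]$peptide
  carrier <- vapply(pep$peptide, grepl, TRUE, pattern = dom, fixed = TRUE)
  expect_true(any(carrier))
  expect_true(all(pep$group[carrier] == "attB"))
})

test_that("the assay separates disruption from restoration", {
  spDis <- fixtureSpec(iges = list(list(target = "CDS-domain", drLen = 0L)))
  fxDis <- generateFixture(spDis, seed = 21)
  repDis <- as.character(replicons(fxDis$query)[["chr"]])
  resDis <- disruptionAssay(
    buildAttPeptides(repDis, fxDis$truth$left, fxDis$truth$right),
    stubHmmScorer(fxDis$domains))
  expect_identical(resDis$outcome, "attB_win")
  expect_gte(resDis$topAttB, 1.1 * resDis$topAttLR)

  spRes <- fixtureSpec(iges = list(list(target = "CDS-domain", drLen = 0L,
                                        restore = TRUE, restoreLen = 600L)))
  fxRes <- generateFixture(spRes, seed = 22)
  repRes <- as.character(replicons(fxRes$query)[["chr"]])
  resRes <- disruptionAssay(
    buildAttPeptides(repRes, fxRes$truth$left, fxRes$truth$right),
    stubHmmScorer(fxRes$domains))
  expect_identical(resRes$outcome, "attLR_win")
})

test_that("the assay is strand-symmetric", {
  sp <- fixtureSpec(iges = list(list(target = "CDS-domain", drLen = 0L)))
  fx <- generateFixture(sp, seed = 23)
  repSeq <- as.character(replicons(fx$query)[["chr"]])
  sc <- stubHmmScorer(fx$domains)
  fwd <- disruptionAssay(
    buildAttPeptides(repSeq, fx$truth$left, fx$truth$right), sc)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(repSeq)))
  n <- nchar(repSeq)
  rev <- disruptionAssay(
    buildAttPeptides(rc, n - fx$truth$right + 1L, n - fx$truth$left + 1L),
    sc)
  expect_identical(rev$outcome, fwd$outcome)
  expect_equal(rev$topAttB, fwd$topAttB)
})

test_that("no spanning hit gives the no_spanning outcome", {
  pep <- data.frame(group = "attLR", site = "attL", strand = "+", frame = 0,
                    peptide = strrep("A", 300), center = 150L)
  res <- disruptionAssay(pep, stubHmmScorer(list(
    list(pfam = "D", peptide = strrep("W", 40), fullScore = 100))))
  expect_identical(res$outcome, "no_spanning")
})

test_that("cohort reporting reproduces percentage arithmetic from counts", {
  tab <- assayReport(3308, 1271, 5, 28, 828, 410)
  expect_equal(tab$pct[tab$row == "Spanning (% of IGEs)"], 38.42)
  expect_equal(tab$pct[tab$row == "No attB (% of spanning)"], 2.20)
  expect_equal(tab$pct[tab$row == "attLR win (% of spanning)"], 65.15)
  expect_equal(tab$pct[tab$row == "attB win (% of spanning)"], 32.26)
  empty <- assayReport(0, 0, 0, 0, 0, 0)
  expect_true(all(is.na(empty$pct[-1])))
})
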