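library(ape)

test_that("clade statistics match hand computations", {
  star <- read.tree(text = "(a:1,b:1,c:1,d:1)90;")
  cs <- cladeStats(star, c(a = "s1", b = "s1", c = "s2", d = "s3"))
  expect_equal(cs$depth, 2)           # all pairwise distances are 2
  expect_equal(cs$purity, 50)         # 2 of 4 use the top site
  expect_equal(cs$support, 0.9)       # percent labels auto-scale
  two <- read.tree(text = "((a:1,b:1)95:1,(c:1,d:1)40:1)root;")
  cs2 <- cladeStats(two, c(a = "x", b = "x", c = "x", d = "y"))
  ab <- cs2[cs2$members == "a,b", ]
  expect_equal(ab$purity, 100)
  expect_equal(ab$depth, 2)
  # missing site: excluded from purity with a flag
  cs3 <- cladeStats(star, c(a = "s1", b = "s1", c = "s2"))
  expect_equal(cs3$nSiteless, 1L)
  expect_equal(cs3$purity, 100 * 2 / 3)
})

test_that("depth is invariant under leaf reordering and rerooting", {
  set.seed(50)
  tr <- rtree(12)
  tr$node.label <- rep("80", tr$Nnode)
  sites <- setNames(sample(c("s1", "s2", "s3"), 12, TRUE), tr$tip.label)
  cs <- cladeStats(tr, sites)
  rot <- cladeStats(rotate(tr, 14), sites)
  key <- function(d) {
    srt <- vapply(strsplit(d$members, ","),
                  function(m) paste(sort(m), collapse = ","), "")
    setNames(d$depth, srt)[order(srt)]
  }
  expect_equal(key(cs), key(rot), tolerance = 1e-9)
})

test_that("the promiscuity screen excludes small clades and deep clades", {
  clades <- data.frame(
    node = 1:4, size = c(4L, 8L, 8L, 8L),
    support = c(0.9, 0.9, 0.9, 0.9),
    depth = c(0.2, 0.2, 5.0, 0.2),
    topSite = "s", purity = c(25, 12.5, 12.5, 80),
    nSiteless = 0L,
    members = c("a,b,c,d", "e1,e2,e3,e4,e5,e6,e7,e8",
                "f1,f2,f3,f4,f5,f6,f7,f8", "g1,g2,g3,g4,g5,g6,g7,g8"),
    stringsAsFactors = FALSE)
  hit <- promiscuityScreen(clades, is607Depth = 1.0)
  # size-4 clade excluded (its minimum purity is 25%), deep clade excluded,
  # pure clade excluded; only the shallow diverse 8-member clade flags
  expect_equal(hit$node, 2L)
  # low support never flags
  clades$support <- 0.3
  expect_equal(nrow(promiscuityScreen(clades, is607Depth = 1.0)), 0L)
})

test_that("a planted shallow-diverse clade is recovered in a random tree", {
  set.seed(51)
  bg <- rtree(20)
  bg$edge.length <- bg$edge.length * 2
  planted <- stree(8, type = "star")
  planted$edge.length <- rep(0.05, 8)
  planted$tip.label <- paste0("p", 1:8)
  tr <- bind.tree(bg, planted, where = 1)
  tr$node.label <- rep("90", tr$Nnode)
  sites <- setNames(sample(c("a", "b"), length(tr$tip.label), TRUE),
                    tr$tip.label)
  sites[paste0("p", 1:8)] <- paste0("site", 1:8)  # all-different sites
  cs <- cladeStats(tr, sites)
  hit <- promiscuityScreen(cs, is607Depth = 0.5)
  memb <- strsplit(hit$members, ",")
  expect_true(any(vapply(memb, function(m)
    all(paste0("p", 1:8) %in% m) && length(m) <= 9, TRUE)))
})

test_that("profile-score membership uses the published 64-bit boundary", {
  sc <- c(x = 64.0, y = 63.9, z = 200)
  m <- classifyIs607(sc)
  expect_true(m[["x"]])
  expect_false(m[["y"]])
  expect_true(m[["z"]])
})

test_that("RGI candidates need clade unity of domain and position", {
  tight <- read.tree(text = "((a:0.05,b:0.05)90:0.1,(c:0.05,d:3.0)90:0.1)r;")
  sites <- c(a = "gX", b = "gX", c = "gX", d = "gX")
  cs <- cladeStats(tight, sites)
  dis <- function(pfam, pos, outcome = "attB_win")
    list(outcome = outcome, bestPfam = pfam, crossoverPos = pos)
  # a,b: same domain, close positions -> one candidate
  d1 <- list(a = dis("DUF1", 30), b = dis("DUF1", 34),
             c = dis("DUF1", 30), d = dis("DUF1", 30))
  out <- detectRgi(cs, d1)
  expect_equal(nrow(out), 1L)
  expect_identical(sort(strsplit(out$members, ",")[[1]]), c("a", "b"))
  expect_identical(out$disruptedPfam, "DUF1")
  # positions 40 residues apart at tolerance 10: no candidate
  d2 <- d1; d2$b$crossoverPos <- 70
  expect_equal(nrow(detectRgi(cs, d2)), 0L)
  # a lone disruptor can never form a candidate
  d3 <- d1; d3$b$outcome <- "attLR_win"
  expect_equal(nrow(detectRgi(cs, d3)), 0L)
})

test_that("the 2x2 chi-square equals the expected-count formula", {
  set.seed(52)
  for (i in 1:25) {
    tab <- matrix(sample(1:500, 4), 2)
    got <- chi2Test2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_)^2 / exp_)
    expect_equal(got$statistic, stat, tolerance = 1e-9)
    expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(chi2Test2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi2Test2x2(0, 0, 5, 5), "zero margin")
})
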