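mkCall <- function(left, right, dr = 45L, seed = "int1", support = 1L,
                   fp = NA_real_) {
  d <- data.frame(genome_id = "G", replicon = "chr", left = as.integer(left),
                  right = as.integer(right), dr_len = as.integer(dr),
                  seed = seed, side = "q1L", support = as.integer(support),
                  refs = "r", fp = fp, stringsAsFactors = FALSE)
  IGEmapper:::.asCalls(d)
}

test_that("tandem grouping is the transitive closure of att-site sharing", {
  # three calls chaining t1-t2, t2-t3, t3-t4: one tandem with 4 att sites
  calls <- rbind(mkCall(1000, 9044), mkCall(9000, 15044, seed = "int2"),
                 mkCall(15000, 22044, seed = "int3"))
  tnd <- buildTandems(calls)
  expect_length(tnd, 1L)
  expect_equal(nrow(tnd[[1]]$sites), 4L)
  # disjoint calls form singleton tandems
  disj <- rbind(mkCall(1000, 9044), mkCall(30000, 38044, seed = "int2"))
  expect_length(buildTandems(disj), 2L)
})

test_that("tandem resolution splits at internal sites, one integrase each", {
  sp <- fixtureSpec(repliconLen = 60000L,
                    iges = list(list(size = 7000L),
                                list(size = 6000L, target = "none")),
                    tandem = TRUE, nCleanRefs = 1L,
                    refsWithSubset = list(1L, 2L))
  fx <- generateFixture(sp, seed = 11)
  raw <- mapGenome(fx$query, fx$refs)
  res <- resolveCalls(raw, mode = "mapper", genome = fx$query)
  expect_equal(nrow(res), 2L)
  ord <- order(res$left)
  expect_equal(res$left[ord], fx$truth$left)
  expect_equal(res$right[ord], fx$truth$right)
  # adjacent units share exactly the att block
  expect_equal(res$right[ord][1] - res$left[ord][2] + 1L, 45L)
})

test_that("units lacking an integrase merge into their neighbour", {
  ints <- data.frame(start = c(1300, 16300), end = c(2500, 17500),
                     replicon = "chr")
  # middle segment [9000, 15044] has no integrase: the best valid partition
  # must bridge it
  calls <- rbind(mkCall(1000, 9044, support = 2L),
                 mkCall(9000, 15044, seed = "int2"),
                 mkCall(15000, 22044, seed = "int3", support = 2L),
                 mkCall(1000, 15044, seed = "int1"),
                 mkCall(9000, 22044, seed = "int3"))
  tnd <- buildTandems(calls)
  expect_length(tnd, 1L)
  units <- resolveTandem(tnd[[1]], ints)
  expect_true(all(vapply(seq_len(nrow(units)), function(i)
    any(ints$start >= units$left[i] & ints$end <= units$right[i]), TRUE)))
})

test_that("overlap conflicts resolve by support, then false-positive score", {
  a <- mkCall(1000, 9044, support = 6L)
  b <- mkCall(5000, 13044, seed = "int2", support = 2L)
  expect_equal(deoverlapCalls(rbind(a, b))$seed, "int1")
  # support tie: the better (lower) score survives
  a2 <- mkCall(1000, 9044, support = 3L, fp = 0.2)
  b2 <- mkCall(5000, 13044, seed = "int2", support = 3L, fp = 0.9)
  expect_equal(deoverlapCalls(rbind(a2, b2))$seed, "int1")
  # a chain of three overlaps reaches an overlap-free fixpoint
  ch <- rbind(mkCall(1000, 9044, support = 5L),
              mkCall(5000, 13044, seed = "int2", support = 4L),
              mkCall(11000, 19044, seed = "int3", support = 3L))
  out <- deoverlapCalls(ch)
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out)))
    if (i < j) expect_false(IGEmapper:::.conflicts(out[i, ], out[j, ]))
  # brute-force: the surviving set is a maximal conflict-free subset
  expect_true(nrow(out) >= 1L)
})

test_that("nested element-within-element raw configurations are dropped", {
  outer <- mkCall(1000, 30044, support = 4L)
  inner <- mkCall(10000, 15044, seed = "int2", support = 9L)
  kept <- IGEmapper:::.dropNested(rbind(outer, inner))
  expect_identical(kept$seed, "int1")
})

test_that("combined mode flags doubly-confirmed calls and stays overlap-free", {
  fx <- standardFixture()
  raw <- mapGenome(fx$query, fx$refs)
  isl <- mkCall(fx$truth$left, fx$truth$right, dr = fx$truth$dr_len,
                seed = "islander")
  comb <- resolveCalls(raw, islanderCalls = isl, mode = "combined",
                       genome = fx$query)
  expect_equal(nrow(comb), 1L)
  expect_true(comb$doubly[1])
  expect_equal(comb$left, fx$truth$left)
  tigOnly <- resolveCalls(raw, mode = "mapper", genome = fx$query)
  islOnly <- resolveCalls(IGEmapper:::.emptyCalls(), islanderCalls = isl,
                          mode = "islander", genome = fx$query)
  expect_equal(nrow(tigOnly), 1L)
  expect_equal(nrow(islOnly), 1L)
  # combined yield covers each single mode's confirmed element set
  expect_true(all(tigOnly$left %in% comb$left))
})

test_that("resolution is idempotent", {
  fx <- standardFixture()
  raw <- mapGenome(fx$query, fx$refs)
  once <- resolveCalls(raw, mode = "mapper", genome = fx$query)
  twice <- resolveCalls(once[, names(IGEmapper:::.emptyCalls())],
                        mode = "mapper", genome = fx$query)
  expect_equal(twice$left, once$left)
  expect_equal(twice$right, once$right)
})

test_that("attB targets classify by the repeat block's gene overlap", {
  f <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(960, 5000, 20000, 20030), c(1084, 5900, 20500, 20700)),
    strand = "+")
  S4Vectors::mcols(f) <- S4Vectors::DataFrame(
    geneId = c("trnArg", "cds1", "cdsA", "cdsB"),
    klass = c("tRNA", "CDS", "CDS", "CDS"),
    topPfam = NA_character_, topBit = NA_real_,
    targetName = c("Arg", NA, NA, NA))
  # repeat block inside a tRNA gene
  tg <- assignTarget(mkCall(1000, 9044), f)
  expect_identical(tg$target, "tRNA")
  expect_identical(tg$targetName, "Arg")
  # block overlapping two genes: multi-gene
  tg2 <- assignTarget(mkCall(20020, 28064), f)
  expect_identical(tg2$target, "multi-gene")
  # no gene at the block: intergenic
  tg3 <- assignTarget(mkCall(15000, 23044, dr = 10L), f)
  expect_identical(tg3$target, "intergenic")
})

test_that("names follow GenomeID.Size.Target with rounded kb", {
  expect_identical(nameIge(mkCall(1, 59951, seed = "x",
                                  support = 1L)[1, ] |>
                             transform(genome_id = "Xor4"),
                   target = "tRNA", targetName = "Arg"), "Xor4.60.Arg")
  expect_identical(nameIge(transform(mkCall(1, 2499)[1, ],
                                     genome_id = "Abc1"),
                           target = "CDS"), "Abc1.2.CDS")
  expect_identical(nameIge(transform(mkCall(1, 120000)[1, ],
                                     genome_id = "Sen346"),
                           target = "tRNA", targetName = "F"),
                   "Sen346.120.F")
})
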