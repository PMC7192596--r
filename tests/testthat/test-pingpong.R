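test_that("flank queries obey the coordinate arithmetic", {
  set.seed(4)
  rep100 <- randomSeq(100000)
  fq <- takeFlankQueries(20000L, rep100, "linear")
  expect_identical(fq$q1L, substr(rep100, 5000, 19999))
  expect_identical(fq$q1R, substr(rep100, 20001, 35000))
  # circular: q1L wraps through position 86001
  fq2 <- takeFlankQueries(1000L, rep100, "circular")
  expect_identical(fq2$q1L,
                   paste0(substr(rep100, 86000, 100000),
                          substr(rep100, 1, 999)))
  expect_equal(nchar(fq2$q1L), 15000L)
  # linear truncation near the start
  rep10 <- randomSeq(10000)
  fq3 <- takeFlankQueries(1000L, rep10, "linear")
  expect_equal(nchar(fq3$q1L), 999L)
  # replicons under 2 kb skip the seed with a warning
  expect_warning(out <- takeFlankQueries(500L, randomSeq(1500), "linear"),
                 "shorter than 2 kb")
  expect_null(out)
})

test_that("phase-I retains truncating matches and drops same-element ones", {
  set.seed(5)
  ref <- randomSeq(40000)
  cfg <- mapperConfig("ige")
  # query flank sharing only its distal 6 kb with the reference: retained
  q1 <- paste0(substr(ref, 10000, 15999), randomSeq(9000))
  bm <- phase1Scan(q1, ref, "q1L", cfg)
  expect_equal(bm$q_end, 6000L)
  # full-length match reaches the proximal end: reference carries the same
  # element, so no call
  expect_null(phase1Scan(substr(ref, 10000, 24999), ref, "q1L", cfg))
  # matches at or under 500 bp are discarded
  q3 <- paste0(substr(ref, 10000, 10460), randomSeq(14500))
  expect_null(phase1Scan(q3, ref, "q1L", cfg))
})

test_that("variant merging sums support onto the best-supported call", {
  base <- data.frame(
    genome_id = "G", replicon = "chr",
    left = c(1000L, 1003L, 950L), right = c(9000L, 8998L, 9100L),
    dr_len = 45L, seed = "int1", side = "q1L",
    support = c(4L, 2L, 1L),
    refs = c("r1,r2,r3,r4", "r5,r6", "r7"), stringsAsFactors = FALSE)
  m <- mergeVariantCalls(base[1:2, ], window = 20L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$left, 1000L)          # coordinates of the 4-support call
  expect_equal(m$support, 6L)          # summed support
  # beyond the window: kept separate
  expect_equal(nrow(mergeVariantCalls(base[c(1, 3), ], window = 20L)), 2L)
  # three-way chain merge: pairwise closure gives a single call
  chain <- base
  chain$left <- c(1000L, 1015L, 1030L)
  chain$right <- c(9000L, 9015L, 9030L)
  expect_equal(nrow(mergeVariantCalls(chain, window = 20L)), 1L)
  expect_equal(sum(mergeVariantCalls(chain, window = 20L)$support), 7L)
})

test_that("identical q1L/q1R calls collapse without double-counted support", {
  both <- data.frame(
    genome_id = "G", replicon = "chr", left = 1000L, right = 9000L,
    dr_len = 45L, seed = "int1", side = c("q1L", "q1R"), support = 2L,
    refs = c("r1,r2", "r1,r2"), stringsAsFactors = FALSE)
  d <- dedupeSides(both)
  expect_equal(nrow(d), 1L)
  expect_equal(d$support, 2L)
  expect_identical(d$side, "both")
  distinct <- both
  distinct$left <- c(1000L, 2000L)
  expect_equal(nrow(dedupeSides(distinct)), 2L)
})

test_that("planted elements are recovered exactly with counted support", {
  fx <- standardFixture()
  calls <- mapGenome(fx$query, fx$refs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$left, fx$truth$left)
  expect_equal(calls$right, fx$truth$right)
  expect_equal(calls$dr_len, fx$truth$dr_len)
  expect_equal(calls$support, 3L)      # one per clean reference genome
  expect_identical(calls$side, "both") # short element: both sides agree
})

test_that("references carrying the same element give no call", {
  fx <- generateFixture(fixtureSpec(nCleanRefs = 0L, nSameIgeRefs = 3L),
                        seed = 8)
  expect_equal(nrow(mapGenome(fx$query, fx$refs)), 0L)
})

test_that("tandem members have lower per-unit support than isolated ones", {
  sp <- fixtureSpec(repliconLen = 60000L,
                    iges = list(list(size = 7000L),
                                list(size = 6000L, target = "none")),
                    tandem = TRUE, nCleanRefs = 1L,
                    refsWithSubset = list(1L, 2L))
  fx <- generateFixture(sp, seed = 11)
  raw <- mapGenome(fx$query, fx$refs)
  unit1 <- raw[raw$left == fx$truth$left[1] & raw$right == fx$truth$right[1], ]
  unit2 <- raw[raw$left == fx$truth$left[2] & raw$right == fx$truth$right[2], ]
  expect_true(nrow(unit1) >= 1L && nrow(unit2) >= 1L)
  iso <- mapGenome(standardFixture()$query, standardFixture()$refs)
  expect_lt(max(unit1$support, unit2$support), iso$support + 1L)
})

test_that("transposed-IS artifacts are rejected by either control route", {
  # 1.5-kb IS: below IS-mode size limits, caught by the IS database
  fx <- generateFixture(fixtureSpec(iges = NULL, is = list(size = 1500L)),
                        seed = 3)
  off <- mapGenome(fx$query, fx$refs, filterIs = FALSE)
  expect_equal(nrow(off), 1L)          # the artifact call
  on <- mapGenome(fx$query, fx$refs, filterIs = TRUE, isDb = fx$isDb)
  expect_equal(nrow(on), 0L)
  # 6-kb IS: the IS-mode ping-pong route rejects without any database
  fx2 <- generateFixture(fixtureSpec(iges = NULL, is = list(size = 6000L)),
                         seed = 4)
  expect_equal(nrow(mapGenome(fx2$query, fx2$refs, filterIs = FALSE)), 1L)
  expect_equal(nrow(mapGenome(fx2$query, fx2$refs, filterIs = TRUE)), 0L)
})

test_that("IS mode reproduces planted IS coordinates exactly", {
  fx <- generateFixture(fixtureSpec(iges = NULL, is = list(size = 6000L)),
                        seed = 4)
  isc <- mapGenome(fx$query, fx$refs, mode = "is", filterIs = FALSE)
  expect_equal(isc$left, fx$isTruth$left)
  expect_equal(isc$right, fx$isTruth$right)
  expect_equal(isc$dr_len, fx$isTruth$dr_len)
})

test_that("partial IS coverage of a match region is not a rejection", {
  fx <- standardFixture()
  calls <- mapGenome(fx$query, fx$refs, filterIs = FALSE)
  # an IS record covering only ~60% of the q1 match region must not reject
  repSeq <- as.character(replicons(fx$query)[["chr"]])
  partial <- substr(repSeq, calls$q1m_start[1],
                    calls$q1m_start[1] +
                      round(0.6 * (calls$q1m_end[1] - calls$q1m_start[1])))
  verdict <- isArtifactFilter(calls[1, ], fx$query, fx$refs,
                              isDb = c(partIS = partial))
  expect_identical(verdict, "keep")
  # no DDE gene in the region and no database: keep
  expect_identical(isArtifactFilter(calls[1, ], fx$query, fx$refs), "keep")
})
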