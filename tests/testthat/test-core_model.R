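test_that("GenomeRecord validity enforces ids, topology and feature bounds", {
  gr <- GenomeRecord("Exa1", c(chr = "ACGTACGTACGT"))
  expect_s4_class(gr, "GenomeRecord")
  expect_identical(genomeId(gr), "Exa1")
  expect_identical(unname(topology(gr)), "circular")
  expect_error(GenomeRecord("", c(chr = "ACGT")), "non-empty")
  expect_error(GenomeRecord("X", c("ACGT")), "names")
  bad <- GenomicRanges::GRanges("chr", IRanges::IRanges(5, 20), strand = "+")
  S4Vectors::mcols(bad) <- S4Vectors::DataFrame(geneId = "g1", klass = "CDS")
  expect_error(
    GenomeRecord("X", c(chr = "ACGTACGTACGT"), topology = c(chr = "linear"),
                 features = bad),
    "beyond linear replicon end")
})

test_that("genome FASTA + feature table round-trips through loadGenome", {
  dir <- withr::local_tempdir()
  fx <- standardFixture()
  fa <- file.path(dir, "Fix1.fasta")
  writeLines(c(">chr planted fixture",
               as.character(replicons(fx$query)[["chr"]])), fa)
  f <- geneFeatures(fx$query)
  tsv <- file.path(dir, "Fix1.tsv")
  write.table(data.frame(
    gene_id = S4Vectors::mcols(f)$geneId,
    replicon_id = as.character(GenomicRanges::seqnames(f)),
    start = GenomicRanges::start(f), end = GenomicRanges::end(f),
    strand = "+", klass = S4Vectors::mcols(f)$klass,
    target_name = S4Vectors::mcols(f)$targetName),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- loadGenome(fa, tsv, genomeId = "Fix1", topology = c(chr = "linear"))
  expect_identical(as.character(replicons(g)[["chr"]]),
                   as.character(replicons(fx$query)[["chr"]]))
  gf <- geneFeatures(g)
  expect_setequal(S4Vectors::mcols(gf)$geneId, S4Vectors::mcols(f)$geneId)
  expect_identical(
    GenomicRanges::start(gf)[match(S4Vectors::mcols(f)$geneId,
                                   S4Vectors::mcols(gf)$geneId)],
    GenomicRanges::start(f))
  # mismatched replicon ids are a hard error
  bad <- file.path(dir, "bad.tsv")
  write.table(data.frame(gene_id = "g", replicon_id = "nope", start = 1,
                         end = 10, strand = "+", klass = "CDS"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadGenome(fa, bad), "absent from FASTA")
})

test_that("GFF3 annotation is read with recombinase classes", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">chr", strrep("ACGT", 3000)), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tgene\t100\t1300\t.\t+\t.\tID=int1;klass=Y-Int",
    "chr\ttest\ttRNA\t2000\t2085\t.\t+\t.\tID=trn1;target_name=Arg",
    "chr\ttest\tgene\t3000\t3900\t.\t-\t.\tID=cds1;klass=CDS"), gff)
  g <- loadGenome(fa, gff, genomeId = "Gff1")
  f <- geneFeatures(g)
  kl <- setNames(S4Vectors::mcols(f)$klass, S4Vectors::mcols(f)$geneId)
  expect_identical(kl[["int1"]], "Y-Int")
  expect_identical(kl[["trn1"]], "tRNA")   # falls back to the feature type
  expect_identical(kl[["cds1"]], "CDS")
  expect_identical(
    S4Vectors::mcols(f)$targetName[S4Vectors::mcols(f)$geneId == "trn1"],
    "Arg")
})

test_that("call tables round-trip coordinates exactly", {
  fx <- standardFixture()
  calls <- mapGenome(fx$query, fx$refs)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCallTable(calls, path)
  back <- readCallTable(path)
  expect_identical(back$left, calls$left)
  expect_identical(back$right, calls$right)
  expect_identical(back$dr_len, calls$dr_len)
  expect_identical(back$refs, calls$refs)
  # att blocks are reported explicitly and consistently
  tab <- read.delim(path)
  expect_equal(tab$attL_end - tab$attL_start + 1L, tab$dr_len)
  expect_equal(tab$attR_end - tab$attR_start + 1L, tab$dr_len)
})

test_that("integrase classification partitions genes by domain content", {
  mk <- function(ids) {
    g <- GenomicRanges::GRanges("chr",
      IRanges::IRanges(seq(1, by = 2000, length.out = length(ids)),
                       width = 900), strand = "+")
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(
      geneId = ids, klass = rep("CDS", length(ids)))
    g
  }
  feats <- mk(c("g1", "g2", "g3", "g4", "g5", "g6", "g7"))
  hits <- data.frame(
    subject_id = c("g1", "g2", "g2", "g3", "g4", "g4", "g5", "g6", "g6"),
    pfam = c("Phage_integrase", "Phage_integrase", "XerC",
             "Resolvase", "Resolvase", "Recombinase", "DDE_Tnp_1",
             "Phage_integrase", "intI_Cterm"),
    bitscore = c(120, 110, 80, 95, 90, 85, 70, 100, 60),
    env_start = 1L, env_end = 100L, stringsAsFactors = FALSE)
  out <- classifyIntegrases(feats, hits)
  kl <- setNames(S4Vectors::mcols(out)$klass, S4Vectors::mcols(out)$geneId)
  expect_identical(kl[["g1"]], "Y-Int")
  expect_identical(kl[["g2"]], "Xer")      # Phage_integrase + Xer subfamily
  expect_identical(kl[["g3"]], "S-Core")   # Resolvase only
  expect_identical(kl[["g4"]], "S-Int")    # Resolvase + Recombinase
  expect_identical(kl[["g5"]], "DDE")
  expect_identical(kl[["g6"]], "IntI")
  expect_identical(kl[["g7"]], "CDS")      # unhit genes stay CDS
  # classification is a partition: exactly one class each
  expect_length(kl, 7L)
  expect_false(anyNA(kl))
  # Xer / IntI never seed mapping
  gnm <- GenomeRecord("X", c(chr = strrep("ACGT", 5000)), features = out)
  expect_false(any(c("g2", "g6") %in% seedGenes(gnm, "ige")$geneId))
})

test_that("sub-threshold hits and gathering cutoffs are honoured", {
  g <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 900), strand = "+")
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(geneId = "g1", klass = "CDS")
  weak <- data.frame(subject_id = "g1", pfam = "Phage_integrase",
                     bitscore = 15, env_start = 1L, env_end = 50L)
  expect_identical(
    S4Vectors::mcols(classifyIntegrases(g, weak))$klass, "CDS")
  expect_identical(
    S4Vectors::mcols(classifyIntegrases(
      g, weak, gaCutoffs = c(Phage_integrase = 10)))$klass, "Y-Int")
})
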