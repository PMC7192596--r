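# Deterministic synthetic-genome fixture generator. Produces a query genome
# with planted integrative elements (direct repeats duplicated at both ends,
# an integrase gene near one end of each element), reference genomes with the
# uninterrupted att site, optional transposed insertion sequences, tandem
# arrays and domain-bearing target genes, together with a ground-truth table.
#
# Junction determinacy: wherever two unrelated sequences abut at a planted
# junction, chance identity of the first few bases would genuinely lengthen
# the direct repeat and make the att boundary ambiguous (as it is in real
# genomes). Each planted segment therefore starts and ends with one of the
# homopolymer tags AAAA/CCCC/GGGG/TTTT, assigned so that any two sequences
# meeting at a junction disagree at all four positions. Truth-table termini
# are then well defined and recoverable exactly.

.JTAGS <- c("AAAA", "CCCC", "GGGG", "TTTT")

`%||%` <- function(a, b) if (is.null(a)) b else a

.setStr <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

# reverse-translation table: one unambiguous codon per amino acid
.AA2CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.pep2dna <- function(pep) {
  paste(.AA2CODON[strsplit(pep, "")[[1]]], collapse = "")
}

.randPeptide <- function(n) {
  paste(sample(names(.AA2CODON), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic fixture
#'
#' Defaults describe the standard planted-element scenario: one 8-kb element
#' with a 45-bp direct repeat and a tyrosine-integrase gene 300 bp from its
#' left end, integrated into a tRNA-gene att site on a 40-kb linear
#' replicon, with three uninterrupted ("clean") reference genomes.
#'
#' @param repliconLen Replicon length in bp.
#' @param topology `"linear"` or `"circular"`.
#' @param iges List of per-element specs; each a list overriding any of
#'   `size` (span in bp including both repeat copies), `drLen`, `intOffset`,
#'   `intLen`, `intKlass`, `target` (`"tRNA"`, `"CDS-domain"` or `"none"`),
#'   `targetName`, `restore` (carry a target-restoring fragment at the start
#'   of the element) and `restoreLen`. Use `iges = NULL` for an element-free
#'   backbone (IS-only fixtures).
#' @param tandem If `TRUE`, elements are planted as a tandem array sharing
#'   att sites (all must then use the same `drLen`; at most 3 members).
#' @param nCleanRefs Number of uninterrupted reference genomes.
#' @param nSameIgeRefs Number of references carrying the same element(s).
#' @param refsWithSubset For tandem fixtures: list of integer vectors; each
#'   adds a reference carrying only the listed elements.
#' @param is Optional transposed-IS scenario: list overriding `size`, `drLen`
#'   (target-site duplication length), `gapToInt` (distance from IS end to a
#'   backbone integrase gene planted for the scenario) and `refOffset` (how
#'   far downstream of that gene the IS sits in the references).
#' @param mutRate Per-base substitution rate applied to reference genomes
#'   (no indels).
#' @return A `FixtureSpec` list.
#' @export
fixtureSpec <- function(repliconLen = 40000L, topology = "linear",
                        iges = list(list()), tandem = FALSE,
                        nCleanRefs = 3L, nSameIgeRefs = 0L,
                        refsWithSubset = NULL, is = NULL, mutRate = 0) {
  igeDefault <- list(size = 8000L, drLen = 45L, intOffset = 300L,
                     intLen = 1200L, intKlass = "Y-Int", target = "tRNA",
                     targetName = "Arg", restore = FALSE, restoreLen = 300L)
  iges <- lapply(iges, function(x) utils::modifyList(igeDefault, x))
  for (ig in iges) {
    if (ig$size - 2L * ig$drLen < ig$intOffset + ig$intLen)
      stop("element too small for its integrase gene")
    if (ig$size > repliconLen / 2) stop("element larger than half the replicon")
  }
  if (tandem && length(iges) > 3L)
    stop("tandem fixtures support at most 3 members")
  if (!tandem && length(iges) > 1L)
    stop("multiple elements require tandem = TRUE")
  if (!is.null(is))
    is <- utils::modifyList(list(size = 1500L, drLen = 4L, gapToInt = 600L,
                                 refOffset = 15000L), is)
  structure(list(repliconLen = as.integer(repliconLen), topology = topology,
                 iges = iges, tandem = tandem,
                 nCleanRefs = as.integer(nCleanRefs),
                 nSameIgeRefs = as.integer(nSameIgeRefs),
                 refsWithSubset = refsWithSubset, is = is,
                 mutRate = mutRate),
            class = "FixtureSpec")
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[hit] <- vapply(ch[hit],
                    function(b) sample(setdiff(.DNA_ALPHA, b), 1L), "")
  paste(ch, collapse = "")
}

#' Generate a synthetic fixture
#'
#' Builds the query genome, reference sequences and ground truth from a
#' [fixtureSpec()]. Output is byte-for-byte determined by `spec` and `seed`.
#'
#' @param spec A `FixtureSpec`.
#' @param seed Integer RNG seed.
#' @param genomeId Genome identifier for the query.
#' @return List with `query` ([GenomeRecord-class]), `refs` (named character
#'   vector of reference genome sequences), `truth` (data.frame of planted
#'   termini: `ige_id`, `left`, `right`, `dr_len`, `target`, `target_name`,
#'   `dr_seq`), `isDb` (named character vector of planted IS sequences,
#'   possibly empty), `isTruth` (planted IS span on the query, or NULL) and
#'   `domains` (list describing planted protein domains, consumable by
#'   [stubHmmScorer()]).
#' @export
generateFixture <- function(spec, seed = 1L, genomeId = "Fix1") {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(seed)
  n0 <- spec$repliconLen
  anc <- .randDna(n0)
  feats <- list()
  domains <- list()
  truth <- list()
  p <- as.integer(round(n0 * 0.55))

  if (length(spec$iges)) {
    tgt <- spec$iges[[1]]$target
    if (identical(tgt, "CDS-domain")) {
      pep <- .randPeptide(160L)
      dom <- substr(pep, 51L, 110L)
      geneDna <- paste0("ATG", .pep2dna(pep), "TAA")
      gstart <- p - (3L + 80L * 3L)  # crossover lands mid-domain (codon ~81)
      anc <- paste0(substr(anc, 1L, gstart - 1L), geneDna,
                    substr(anc, gstart + nchar(geneDna), n0))
      feats[[length(feats) + 1L]] <-
        list(id = "targetCDS", start = gstart,
             end = gstart + nchar(geneDna) - 1L, klass = "CDS",
             targetName = spec$iges[[1]]$targetName)
      domains[[length(domains) + 1L]] <-
        list(pfam = "DUF_fix1", peptide = dom, fullScore = 100,
             geneId = "targetCDS")
    } else if (identical(tgt, "tRNA")) {
      feats[[length(feats) + 1L]] <-
        list(id = "targetRNA", start = p - 40L,
             end = p + spec$iges[[1]]$drLen + 39L, klass = "tRNA",
             targetName = spec$iges[[1]]$targetName)
    }
    # junction tags on the ancestral backbone around the insertion locus;
    # not applied when the target is a domain-bearing gene (they would
    # overwrite its codons) or carries a restoring fragment - those fixtures
    # test the disruption assay, not exact terminus mapping
    if (!spec$iges[[1]]$restore && !identical(tgt, "CDS-domain")) {
      anc <- .setStr(anc, p + spec$iges[[1]]$drLen, .JTAGS[1L])
      anc <- .setStr(anc, p - 4L, .JTAGS[1L])
    }
  }

  cur <- anc
  shiftAll <- function(pos, by) {
    feats <<- lapply(feats, function(f) {
      if (f$start >= pos) { f$start <- f$start + by; f$end <- f$end + by }
      f
    })
  }

  at <- p
  for (i in seq_along(spec$iges)) {
    ig <- spec$iges[[i]]
    dr <- ig$drLen
    coreLen <- ig$size - 2L * dr
    core <- .randDna(coreLen)
    tagS <- .JTAGS[c(3L, 4L, 2L)[i]]   # starts: GGGG, TTTT, CCCC
    tagE <- .JTAGS[c(4L, 2L, 3L)[i]]   # ends:   TTTT, CCCC, GGGG
    if (ig$restore) {
      restoreFrag <- substr(cur, at + dr, at + dr + ig$restoreLen - 1L)
      core <- paste0(restoreFrag, substr(core, ig$restoreLen + 1L, coreLen))
      core <- .setStr(core, ig$restoreLen + 1L, tagS)
    } else {
      core <- .setStr(core, 1L, tagS)
    }
    core <- .setStr(core, coreLen - 3L, tagE)
    drSeq <- substr(cur, at, at + dr - 1L)
    shiftAll(at + dr, coreLen + dr)
    cur <- paste0(substr(cur, 1L, at + dr - 1L), core,
                  substr(cur, at, nchar(cur)))
    # integrase coordinates are in post-insertion space: add after shifting
    intStart <- at + dr + ig$intOffset
    feats[[length(feats) + 1L]] <-
      list(id = sprintf("int%d", i), start = intStart,
           end = intStart + ig$intLen - 1L, klass = ig$intKlass,
           targetName = NA_character_)
    truth[[length(truth) + 1L]] <-
      data.frame(ige_id = sprintf("ige%d", i), left = at,
                 right = at + ig$size - 1L, dr_len = dr,
                 target = switch(ig$target, tRNA = "tRNA",
                                 `CDS-domain` = "CDS", "intergenic"),
                 target_name = ig$targetName, dr_seq = drSeq,
                 stringsAsFactors = FALSE)
    at <- at + dr + coreLen   # next tandem member integrates at the
  }                           # restored (right) repeat copy

  isDb <- character(0)
  isTruth <- NULL
  isSpec <- spec$is
  rIns <- NA_integer_
  if (!is.null(isSpec)) {
    if (length(spec$iges))
      stop("the transposed-IS scenario requires an element-free backbone")
    isSeq <- .randDna(isSpec$size)
    isSeq <- .setStr(isSeq, 1L, .JTAGS[3L])
    isSeq <- .setStr(isSeq, isSpec$size - 3L, .JTAGS[3L])
    ddeLen <- min(isSpec$size - 300L, 3000L)
    intPos <- as.integer(round(n0 * 0.25))   # backbone integrase locus
    qIns <- intPos - isSpec$gapToInt
    rIns <- intPos + isSpec$refOffset
    dri <- isSpec$drLen
    # junction tags and homopolymer target-site duplications go on the
    # SHARED backbone so query and references agree outside the IS copies
    for (at0 in c(qIns, rIns)) {
      anc <- .setStr(anc, at0 - 4L, .JTAGS[1L])
      anc <- .setStr(anc, at0 + dri, .JTAGS[1L])
    }
    if (dri > 0L) {
      anc <- .setStr(anc, qIns, strrep("T", dri))
      anc <- .setStr(anc, rIns, strrep("C", dri))
    }
    cur <- anc
    shiftAll(qIns + dri, isSpec$size + dri)
    cur <- paste0(substr(cur, 1L, qIns + dri - 1L), isSeq,
                  substr(cur, qIns, nchar(cur)))
    # backbone integrase and the IS transposase, in post-insertion space
    intFinal <- intPos + isSpec$size + dri
    feats[[length(feats) + 1L]] <-
      list(id = "intIS", start = intFinal, end = intFinal + 1199L,
           klass = "Y-Int", targetName = NA_character_)
    feats[[length(feats) + 1L]] <-
      list(id = "dde1", start = qIns + dri + 150L,
           end = qIns + dri + 150L + ddeLen - 1L,
           klass = "DDE", targetName = NA_character_)
    isDb <- c(IS_fix1 = isSeq)
    isTruth <- data.frame(left = qIns,
                          right = qIns + isSpec$size + 2L * dri - 1L,
                          dr_len = dri, stringsAsFactors = FALSE)
  }

  # references carry the IS transposed to the downstream backbone locus
  refIs <- function(r) {
    if (is.null(isSpec)) return(r)
    paste0(substr(r, 1L, rIns + isSpec$drLen - 1L), isDb[[1L]],
           substr(r, rIns, nchar(r)))
  }
  refs <- character(0)
  for (j in seq_len(spec$nCleanRefs))
    refs[sprintf("ref_clean_%d", j)] <- .mutate(refIs(anc), spec$mutRate)
  for (j in seq_len(spec$nSameIgeRefs))
    refs[sprintf("ref_same_%d", j)] <- .mutate(cur, spec$mutRate)
  for (j in seq_along(spec$refsWithSubset %||% list())) {
    keep <- spec$refsWithSubset[[j]]
    r <- anc
    atr <- p
    for (i in seq_along(spec$iges)) {
      ig <- spec$iges[[i]]
      dr <- ig$drLen
      coreLen <- ig$size - 2L * dr
      coreQ <- substr(cur, truth[[i]]$left + dr,
                      truth[[i]]$left + dr + coreLen - 1L)
      if (i %in% keep) {
        r <- paste0(substr(r, 1L, atr + dr - 1L), coreQ,
                    substr(r, atr, nchar(r)))
        atr <- atr + dr + coreLen
      }
    }
    refs[sprintf("ref_sub_%d", j)] <- .mutate(r, spec$mutRate)
  }

  fdf <- if (length(feats)) do.call(rbind, lapply(feats, function(f)
    data.frame(id = f$id, start = f$start, end = f$end, klass = f$klass,
               targetName = f$targetName, stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges()
  if (!is.null(fdf)) {
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(fdf$start, fdf$end),
                                 strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = fdf$id, klass = fdf$klass, topPfam = NA_character_,
      topBit = NA_real_, targetName = fdf$targetName)
  }
  query <- GenomeRecord(genomeId, c(chr = cur),
                        topology = c(chr = spec$topology), features = gr)
  list(query = query, refs = refs,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       isDb = isDb, isTruth = isTruth, domains = domains)
}

#' Generate mock elements as negative controls
#'
#' For each real call, draws `k` random same-length segments from the same
#' replicon (uniform start, avoiding overlap with any real element span),
#' mirroring the mock-set construction used to control the domain-disruption
#' assay.
#'
#' @param calls Call data.frame with `replicon`, `left`, `right`.
#' @param genome The source [GenomeRecord-class].
#' @param k Mocks per element (default 5).
#' @param seed RNG seed.
#' @return Call-style data.frame of mock segments (`dr_len` 0).
#' @export
generateMockIges <- function(calls, genome, k = 5L, seed = 1L) {
  set.seed(seed)
  out <- list()
  lens <- setNames(Biostrings::width(replicons(genome)),
                   names(replicons(genome)))
  for (i in seq_len(nrow(calls))) {
    len <- calls$right[i] - calls$left[i] + 1L
    n <- lens[[calls$replicon[i]]]
    real <- calls[calls$replicon == calls$replicon[i], , drop = FALSE]
    got <- 0L; tries <- 0L
    while (got < k && tries < 2000L) {
      tries <- tries + 1L
      s <- sample.int(n - len - 1000L, 1L) + 500L
      e <- s + len - 1L
      if (any(pmax(real$left, s) <= pmin(real$right, e))) next
      got <- got + 1L
      out[[length(out) + 1L]] <-
        data.frame(genome_id = genomeId(genome),
                   replicon = calls$replicon[i], left = s, right = e,
                   dr_len = 0L, seed = sprintf("mock_%d_%d", i, got),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyCalls())
  .asCalls(do.call(rbind, out))
}
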