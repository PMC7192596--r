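# Recombinase gene classification from per-protein HMM hits.

#' Default HMM name sets for recombinase classification
#'
#' The classifier recognises the tyrosine-integrase domain
#' (`Phage_integrase`), the serine-recombinase catalytic domain (`Resolvase`)
#' and the large serine-integrase C-terminal domain (`Recombinase`), plus
#' configurable lists of Xer-subfamily, integron-integrase and DDE-transposase
#' profiles. These lists are configuration, not curation: supply your own via
#' the arguments of [classifyIntegrases()].
#' @export
recombinaseHmmSets <- function() {
  list(
    yint = "Phage_integrase",
    resolvase = "Resolvase",
    recombinase = "Recombinase",
    xer = c("XerC", "XerD", "XerS", "XerH"),
    inti = "intI_Cterm",
    dde = c("DDE_Tnp_1", "DDE_Tnp_IS66", "DDE_Tnp_ISL3", "DDE_1", "DDE_3",
            "Transposase_mut", "rve", "HTH_Tnp_1", "Transposase_11")
  )
}

#' Classify recombinase genes from an HMM hit table
#'
#' Assigns each gene exactly one class: `Y-Int` (tyrosine-integrase hit, not
#' reclassified as `Xer` or `IntI`), `S-Int` (serine catalytic plus
#' C-terminal integrase domain), `S-Core` (catalytic domain only), `DDE`
#' (transposase profile), or its prior class (`CDS` for unhit protein genes).
#' `Xer` and `IntI` genes are flagged so they are never used to seed element
#' mapping. A gene with both tyrosine- and serine-family hits is classed by
#' the better bitscore and flagged in the `classNote` metadata column.
#'
#' Hits are admitted at per-HMM gathering cutoffs when supplied, otherwise at
#' a global 20-bit floor.
#'
#' @param features `GRanges` of gene features (metadata `geneId`, `klass`).
#' @param hmmHits data.frame as from [readHmmHits()], keyed by `subject_id`
#'   matching `geneId`.
#' @param hmmSets Named list as [recombinaseHmmSets()].
#' @param gaCutoffs Optional named numeric of per-HMM score cutoffs.
#' @param scoreFloor Global bitscore floor (default 20).
#' @return The features with updated `klass`, `topPfam`, `topBit` and
#'   `classNote` metadata.
#' @export
classifyIntegrases <- function(features, hmmHits,
                               hmmSets = recombinaseHmmSets(),
                               gaCutoffs = NULL, scoreFloor = 20) {
  if (!nrow(hmmHits)) return(features)
  cut <- rep(scoreFloor, nrow(hmmHits))
  if (!is.null(gaCutoffs)) {
    m <- match(hmmHits$pfam, names(gaCutoffs))
    cut[!is.na(m)] <- gaCutoffs[m[!is.na(m)]]
  }
  hits <- hmmHits[hmmHits$bitscore >= cut, , drop = FALSE]
  mc <- S4Vectors::mcols(features)
  if (is.null(mc$topPfam)) mc$topPfam <- NA_character_
  if (is.null(mc$topBit)) mc$topBit <- NA_real_
  mc$classNote <- NA_character_
  bygene <- split(hits, hits$subject_id)
  for (gid in names(bygene)) {
    i <- which(mc$geneId == gid)
    if (!length(i)) next
    h <- bygene[[gid]]
    top <- h[which.max(h$bitscore), ]
    mc$topPfam[i] <- top$pfam
    mc$topBit[i] <- top$bitscore
    pf <- h$pfam
    hasY <- hmmSets$yint %in% pf
    hasRes <- hmmSets$resolvase %in% pf
    hasRec <- hmmSets$recombinase %in% pf
    hasXer <- any(hmmSets$xer %in% pf)
    hasIntI <- any(hmmSets$inti %in% pf)
    hasDde <- any(hmmSets$dde %in% pf)
    useY <- hasY
    if (hasY && hasRes) {
      # multi-domain conflict: class by better bitscore, flag
      yScore <- max(h$bitscore[pf == hmmSets$yint])
      sScore <- max(h$bitscore[pf == hmmSets$resolvase])
      useY <- yScore >= sScore
      mc$classNote[i] <- "Y/S domain conflict; classed by bitscore"
    }
    mc$klass[i] <-
      if (useY) {
        if (hasXer) "Xer" else if (hasIntI) "IntI" else "Y-Int"
      } else if (hasRes) {
        if (hasRec) "S-Int" else "S-Core"
      } else if (hasDde) "DDE" else mc$klass[i]
  }
  S4Vectors::mcols(features) <- mc
  features
}

#' Seed genes for element mapping
#'
#' Returns the features usable as mapping seeds: integrase classes
#' (`Y-Int`, `S-Int`, `S-Core`) in element mode, `DDE` transposases in IS
#' mode. `Xer` and `IntI` are excluded by construction. The seed coordinate
#' is the gene midpoint, `floor((start+end)/2)`.
#'
#' @param genome A [GenomeRecord-class].
#' @param mode `"ige"` or `"is"`.
#' @return data.frame with `geneId`, `replicon`, `midpoint`, `klass`.
#' @export
seedGenes <- function(genome, mode = c("ige", "is")) {
  mode <- match.arg(mode)
  f <- geneFeatures(genome)
  want <- if (mode == "ige") c("Y-Int", "S-Int", "S-Core") else "DDE"
  f <- f[S4Vectors::mcols(f)$klass %in% want]
  data.frame(
    geneId = S4Vectors::mcols(f)$geneId,
    replicon = as.character(GenomicRanges::seqnames(f)),
    midpoint = as.integer(floor((GenomicRanges::start(f) +
                                 GenomicRanges::end(f)) / 2)),
    klass = S4Vectors::mcols(f)$klass, stringsAsFactors = FALSE)
}
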