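# The seven false-positive metrics: mononucleotide (G+C) bias, dinucleotide
# (genomic signature) bias, housekeeping and foreignness gene-content
# enrichment differences, hypothetical-gene fraction difference, length, and
# delta-int (integration-module cohesion).

#' Mononucleotide (G+C) bias
#'
#' Absolute difference between the G+C fraction of the candidate element and
#' that of its whole replicon.
#'
#' @param igeSeq,repliconSeq DNA character strings.
#' @return Non-negative numeric.
#' @export
monoBias <- function(igeSeq, repliconSeq) {
  abs(.gcFrac(igeSeq) - .gcFrac(repliconSeq))
}

# dinucleotide relative-abundance profile (genomic signature convention:
# frequencies on the sequence together with its reverse complement)
.dinucRho <- function(seq) {
  s2 <- .revComp(seq)
  mono <- c(table(factor(c(strsplit(seq, "")[[1]], strsplit(s2, "")[[1]]),
                         levels = .DNA_ALPHA)))
  fMono <- mono / sum(mono)
  di <- c(table(factor(c(.kmers(seq, 2L), .kmers(s2, 2L)),
                       levels = as.vector(outer(.DNA_ALPHA, .DNA_ALPHA,
                                                paste0)))))
  fDi <- di / sum(di)
  expX <- outer(fMono, fMono)
  rho <- matrix(fDi[as.vector(outer(.DNA_ALPHA, .DNA_ALPHA, paste0))],
                4, 4, dimnames = list(.DNA_ALPHA, .DNA_ALPHA)) / expX
  rho[!is.finite(rho)] <- NA
  rho
}

#' Dinucleotide bias (genomic signature difference)
#'
#' Mean absolute difference over the 16 dinucleotide relative abundances
#' rho*XY = fXY / (fX fY), each computed on the sequence concatenated with
#' its reverse complement: delta* = (1/16) sum |rho*XY(element) -
#' rho*XY(replicon)|. Terms with a zero mononucleotide frequency are skipped
#' with a warning.
#'
#' @param igeSeq,repliconSeq DNA character strings of length >= 2.
#' @return Non-negative numeric.
#' @export
dinucBias <- function(igeSeq, repliconSeq) {
  if (nchar(igeSeq) < 2L || nchar(repliconSeq) < 2L)
    stop("sequences must have length >= 2")
  d <- abs(.dinucRho(igeSeq) - .dinucRho(repliconSeq))
  if (anyNA(d)) warning("zero mononucleotide frequency; term(s) skipped")
  sum(d, na.rm = TRUE) / 16
}

#' Build a Pfam enrichment factor table
#'
#' For each Pfam, the enrichment factor is its count among the positive gene
#' set divided by its count among all genes. Pfams absent from the positive
#' set score 0; Pfams absent from the full gene set are excluded.
#'
#' @param positivePfams Character vector of top-Pfam names of the positive
#'   gene set (one entry per gene; NA for genes without a call).
#' @param allPfams Top-Pfam names of all genes.
#' @return Named numeric vector of enrichment factors.
#' @export
buildEnrichmentTable <- function(positivePfams, allPfams) {
  allTab <- table(allPfams[!is.na(allPfams)])
  if (!length(allTab)) return(setNames(numeric(0), character(0)))
  posTab <- table(factor(positivePfams[!is.na(positivePfams)],
                         levels = names(allTab)))
  setNames(as.numeric(posTab) / as.numeric(allTab), names(allTab))
}

#' Gene-content metrics: housekeeping, foreignness, hypothetical
#'
#' Housekeeping and foreignness are the mean enrichment factor over the
#' element's Pfam-called genes minus the corresponding mean over all genes
#' of the replicon (using the housekeeping- or foreignness-trained table
#' respectively). Hypothetical is the fraction of element protein genes with
#' no Pfam call minus the replicon fraction. An element with no Pfam-called
#' gene has housekeeping/foreignness imputed as 0 (flagged via attribute).
#'
#' @param igePfams Top-Pfam names of the element's protein genes (NA = none).
#' @param repliconPfams Top-Pfam names of all replicon protein genes.
#' @param hkTable,fgTable Enrichment tables from [buildEnrichmentTable()].
#' @return Named numeric: `housekeeping`, `foreignness`, `hypothetical`.
#' @export
geneContentMetrics <- function(igePfams, repliconPfams, hkTable, fgTable) {
  look <- function(pf, tab) {
    v <- tab[pf]; v[is.na(v)] <- 0; as.numeric(v)
  }
  meanEnr <- function(pf, tab) {
    pf <- pf[!is.na(pf)]
    if (!length(pf)) return(NA_real_)
    mean(look(pf, tab))
  }
  hk <- meanEnr(igePfams, hkTable) - meanEnr(repliconPfams, hkTable)
  fg <- meanEnr(igePfams, fgTable) - meanEnr(repliconPfams, fgTable)
  imputed <- FALSE
  if (is.na(hk) || is.na(fg)) { hk <- fg <- 0; imputed <- TRUE }
  hyp <- mean(is.na(igePfams)) - mean(is.na(repliconPfams))
  out <- c(housekeeping = hk, foreignness = fg, hypothetical = hyp)
  attr(out, "imputed") <- imputed
  out
}

#' Delta-int: integration-module cohesion
#'
#' Shortest distance in bp between an integrase gene in the element and an
#' element terminus, replaced by 1 when an integrase gene extends beyond a
#' terminus; interior distances are floored at 1 so the metric is safe for
#' log-scaled modelling.
#'
#' @param igeLeft,igeRight Element termini (bp).
#' @param intStarts,intEnds Coordinates of integrase genes overlapping the
#'   element.
#' @return Integer >= 1.
#' @export
deltaInt <- function(igeLeft, igeRight, intStarts, intEnds) {
  if (!length(intStarts)) stop("no integrase gene in element")
  if (any(intStarts < igeLeft | intEnds > igeRight)) return(1L)
  max(1L, min(pmin(intStarts - igeLeft, igeRight - intEnds)))
}

#' Compute the seven-metric vector for one call
#'
#' @param call One-row call data.frame (`replicon`, `left`, `right`).
#' @param genome Query [GenomeRecord-class].
#' @param hkTable,fgTable Enrichment tables.
#' @return Named numeric of the seven metrics in canonical order
#'   (`mono_bias`, `dinuc_bias`, `housekeeping`, `foreignness`,
#'   `hypothetical`, `length`, `delta_int`).
#' @export
metricVector <- function(call, genome, hkTable, fgTable) {
  repSeq <- as.character(replicons(genome)[[call$replicon]])
  igeSeq <- substr(repSeq, call$left, call$right)
  f <- geneFeatures(genome)
  f <- f[as.character(GenomicRanges::seqnames(f)) == call$replicon]
  protein <- S4Vectors::mcols(f)$klass %in%
    c("CDS", "Y-Int", "S-Int", "S-Core", "DDE", "Xer", "IntI")
  fp <- f[protein]
  inIge <- GenomicRanges::start(fp) >= call$left &
           GenomicRanges::end(fp) <= call$right
  gc <- geneContentMetrics(S4Vectors::mcols(fp)$topPfam[inIge],
                           S4Vectors::mcols(fp)$topPfam, hkTable, fgTable)
  ints <- f[S4Vectors::mcols(f)$klass %in% c("Y-Int", "S-Int", "S-Core")]
  ints <- ints[GenomicRanges::end(ints) >= call$left &
               GenomicRanges::start(ints) <= call$right]
  di <- if (length(ints))
    deltaInt(call$left, call$right, GenomicRanges::start(ints),
             GenomicRanges::end(ints)) else NA_integer_
  c(mono_bias = monoBias(igeSeq, repSeq),
    dinuc_bias = dinucBias(igeSeq, repSeq),
    gc[c("housekeeping", "foreignness", "hypothetical")],
    length = call$right - call$left + 1,
    delta_int = as.numeric(di))
}
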