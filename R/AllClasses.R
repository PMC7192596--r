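#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' GenomeRecord: a replicon set with typed gene features
#'
#' Container for one query (or reference) genome: its replicon sequences,
#' per-replicon topology, and gene features carrying recombinase class calls.
#' Gene classes (`klass` metadata column) follow the recombinase taxonomy used
#' for seeding: `Y-Int` (tyrosine integrase), `S-Int` (serine recombinase with
#' the large C-terminal integrase domain), `S-Core` (catalytic domain only),
#' `DDE` (classical transposase), `Xer` and `IntI` (housekeeping/integron
#' recombinases, never used as seeds), plus `tRNA`, `tmRNA`, `rRNA`,
#' `other-RNA` and `CDS`.
#'
#' @slot genomeId Short genome identifier (three-letter genus/species
#'   abbreviation plus a serial number, e.g. `"Eco1"`).
#' @slot replicons A named [Biostrings::DNAStringSet] of replicon sequences.
#' @slot topology Named character vector, `"circular"` or `"linear"` per
#'   replicon.
#' @slot features A [GenomicRanges::GRanges] of gene features with metadata
#'   columns `geneId`, `klass`, and optionally `topPfam`, `topBit`,
#'   `targetName`.
#' @slot geneticCode Integer NCBI translation table.
#' @slot kingdom `"Bacteria"` or `"Archaea"`.
#'
#' @seealso [loadGenome()], [geneFeatures()], [mapGenome()]
#' @export
setClass("GenomeRecord",
  representation(
    genomeId    = "character",
    replicons   = "DNAStringSet",
    topology    = "character",
    features    = "GRanges",
    geneticCode = "integer",
    kingdom     = "character"
  )
)

.GENE_KLASSES <- c("Y-Int", "S-Int", "S-Core", "DDE", "Xer", "IntI",
                   "tRNA", "tmRNA", "rRNA", "other-RNA", "CDS")

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  rn <- names(object@replicons)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
    msg <- c(msg, "replicons must have unique non-empty names")
  if (any(Biostrings::width(object@replicons) == 0L))
    msg <- c(msg, "replicon sequences must be non-empty")
  if (!all(names(object@topology) %in% rn) ||
      !setequal(names(object@topology), rn))
    msg <- c(msg, "topology must be named by replicon id")
  if (!all(object@topology %in% c("circular", "linear")))
    msg <- c(msg, "topology values must be 'circular' or 'linear'")
  if (length(object@features)) {
    f <- object@features
    if (!all(as.character(GenomicRanges::seqnames(f)) %in% rn))
      msg <- c(msg, "feature replicon ids not found among replicons")
    if (is.null(mcols(f)$klass) || is.null(mcols(f)$geneId))
      msg <- c(msg, "features need 'geneId' and 'klass' metadata columns")
    else if (!all(mcols(f)$klass %in% .GENE_KLASSES))
      msg <- c(msg, "unknown feature klass value")
    lens <- Biostrings::width(object@replicons)[
      match(as.character(GenomicRanges::seqnames(f)), rn)]
    bad <- GenomicRanges::start(f) < 1L | GenomicRanges::start(f) > lens
    if (any(bad))
      msg <- c(msg, sprintf("feature out of bounds: %s",
                            paste(mcols(f)$geneId[bad], collapse = ", ")))
    # origin-spanning features may have end > length only on circular replicons
    over <- GenomicRanges::end(f) > lens
    if (any(over & object@topology[as.character(GenomicRanges::seqnames(f))][over] != "circular"))
      msg <- c(msg, sprintf("feature beyond linear replicon end: %s",
        paste(mcols(f)$geneId[over], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param genomeId Genome identifier string.
#' @param replicons Named `DNAStringSet` (or named character vector) of
#'   replicon sequences.
#' @param topology Named character vector (`"circular"`/`"linear"`); defaults
#'   to circular for every replicon.
#' @param features `GRanges` of gene features (may be empty).
#' @param geneticCode NCBI translation table number (default 11).
#' @param kingdom `"Bacteria"` (default) or `"Archaea"`.
#' @return A validated [GenomeRecord-class] object.
#' @examples
#' gr <- GenomeRecord("Exa1", c(chr = "ACGTACGTACGT"))
#' genomeId(gr)
#' @export
GenomeRecord <- function(genomeId, replicons, topology = NULL,
                         features = GenomicRanges::GRanges(),
                         geneticCode = 11L, kingdom = "Bacteria") {
  if (is.character(replicons))
    replicons <- Biostrings::DNAStringSet(replicons)
  if (is.null(topology)) {
    topology <- setNames(rep("circular", length(replicons)), names(replicons))
  }
  new("GenomeRecord", genomeId = genomeId, replicons = replicons,
      topology = topology[names(replicons)], features = features,
      geneticCode = as.integer(geneticCode), kingdom = kingdom)
}

#' @describeIn GenomeRecord-class Genome identifier accessor.
#' @param x A `GenomeRecord`.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@genomeId)

#' @describeIn GenomeRecord-class Replicon sequences accessor.
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))

#' @export
setMethod("replicons", "GenomeRecord", function(x) x@replicons)

#' @describeIn GenomeRecord-class Replicon topology accessor.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @export
setMethod("topology", "GenomeRecord", function(x) x@topology)

#' @describeIn GenomeRecord-class Gene feature accessor.
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @export
setMethod("geneFeatures", "GenomeRecord", function(x) x@features)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@genomeId, "(", object@kingdom, ")\n")
  cat(" ", length(object@replicons), "replicon(s),",
      sum(Biostrings::width(object@replicons)), "bp total\n")
  if (length(object@features)) {
    tab <- table(mcols(object@features)$klass)
    cat(" ", length(object@features), "features:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else cat("  no features\n")
})

#' FpModel: trained false-positive scoring model
#'
#' Result of [trainFpModel()]: the standardization/PCA basis used to draw the
#' convex hull around confirmed calls, the fitted logistic-link linear model
#' on the seven raw metrics, the chosen score cutoff and the held-out AUROC.
#' Higher scores indicate a more credible element (the model predicts the
#' "confirmed-like" class); calls score as passing via [fpScore()].
#'
#' @slot coefficients Named numeric: intercept plus one weight per metric.
#' @slot cutoff Score threshold; scores `>= cutoff` pass.
#' @slot auroc Held-out area under the ROC curve.
#' @slot center,scale Standardization parameters used before PCA.
#' @slot rotation PCA rotation matrix.
#' @slot hullPlane Integer pair: which principal components the hull was
#'   drawn in (default 1 and 3).
#' @slot hull Matrix of hull vertex coordinates in that plane.
#' @export
setClass("FpModel",
  representation(
    coefficients = "numeric",
    cutoff       = "numeric",
    auroc        = "numeric",
    center       = "numeric",
    scale        = "numeric",
    rotation     = "matrix",
    hullPlane    = "integer",
    hull         = "matrix"
  )
)

setValidity("FpModel", function(object) {
  if (length(object@coefficients) != 8L)
    return("coefficients must be intercept + 7 metric weights")
  if (any(!is.finite(object@coefficients))) return("non-finite coefficients")
  TRUE
})

setMethod("show", "FpModel", function(object) {
  cat("FpModel: 7-metric linear false-positive score\n")
  cat("  held-out AUROC:", round(object@auroc, 3),
      " cutoff:", signif(object@cutoff, 4), "\n")
})

# Metric order used throughout the false-positive machinery.
.FP_METRICS <- c("mono_bias", "dinuc_bias", "housekeeping", "foreignness",
                 "hypothetical", "length", "delta_int")
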