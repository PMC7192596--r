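# Readers and writers: genomes (FASTA + GFF3/TSV feature tables), HMM hit
# tables, and element call tables.

#' Load a genome with its gene annotation
#'
#' Reads replicon sequences from FASTA and gene features from either GFF3
#' (via rtracklayer, attribute `klass` or `gene_class` giving the recombinase
#' class) or a tab-separated feature table with columns `gene_id`,
#' `replicon_id`, `start`, `end`, `strand`, `klass` and optionally
#' `top_pfam`, `top_bit`, `target_name`.
#'
#' @param fastaPath Path to a (multi-)FASTA of replicons. FASTA headers are
#'   truncated at the first whitespace to form replicon ids.
#' @param annotationPath Path to a GFF3 (`.gff`/`.gff3`) or TSV feature table.
#' @param genomeId Genome identifier; defaults to the FASTA basename.
#' @param topology Named topology vector as in [GenomeRecord()]; defaults to
#'   circular.
#' @param geneticCode,kingdom Passed to [GenomeRecord()].
#' @return A [GenomeRecord-class].
#' @export
loadGenome <- function(fastaPath, annotationPath = NULL, genomeId = NULL,
                       topology = NULL, geneticCode = 11L,
                       kingdom = "Bacteria") {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(genomeId))
    genomeId <- sub("\\.(fa|fasta|fna)$", "", basename(fastaPath))
  feats <- GenomicRanges::GRanges()
  if (!is.null(annotationPath)) {
    feats <- if (grepl("\\.gff3?$", annotationPath, ignore.case = TRUE))
      .readGff3Features(annotationPath) else readFeatureTable(annotationPath)
    unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(feats))),
                       names(seqs))
    if (length(unknown))
      stop("annotation refers to replicon(s) absent from FASTA: ",
           paste(unknown, collapse = ", "))
  }
  GenomeRecord(genomeId, seqs, topology = topology, features = feats,
               geneticCode = geneticCode, kingdom = kingdom)
}

.readGff3Features <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  g <- rtracklayer::import(path, format = "gff3")
  id <- S4Vectors::mcols(g)$ID
  if (is.null(id)) id <- paste0("feat", seq_along(g))
  klass <- S4Vectors::mcols(g)$klass
  if (is.null(klass)) klass <- S4Vectors::mcols(g)$gene_class
  ty <- as.character(S4Vectors::mcols(g)$type)
  fromType <- ifelse(ty == "tRNA", "tRNA",
              ifelse(ty == "tmRNA", "tmRNA",
              ifelse(ty == "rRNA", "rRNA", "CDS")))
  klass <- if (is.null(klass)) fromType else
    ifelse(is.na(klass), fromType, klass)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                IRanges::ranges(g),
                                strand = GenomicRanges::strand(g))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    geneId = as.character(id), klass = as.character(klass),
    topPfam = if (!is.null(S4Vectors::mcols(g)$top_pfam))
      as.character(S4Vectors::mcols(g)$top_pfam) else NA_character_,
    topBit = if (!is.null(S4Vectors::mcols(g)$top_bit))
      as.numeric(S4Vectors::mcols(g)$top_bit) else NA_real_,
    targetName = if (!is.null(S4Vectors::mcols(g)$target_name))
      as.character(S4Vectors::mcols(g)$target_name) else NA_character_)
  out
}

#' Read a tabular gene feature table
#'
#' @param path TSV with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `klass`, and optionally `top_pfam`, `top_bit`, `target_name`.
#' @return A `GRanges` with the metadata layout used by [GenomeRecord()].
#' @export
readFeatureTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "replicon_id", "start", "end", "strand", "klass")
  if (!all(need %in% names(d)))
    stop("feature table missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  g <- GenomicRanges::GRanges(d$replicon_id,
                              IRanges::IRanges(d$start, d$end),
                              strand = d$strand)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    geneId = d$gene_id, klass = d$klass,
    topPfam = if ("top_pfam" %in% names(d)) d$top_pfam else NA_character_,
    topBit = if ("top_bit" %in% names(d)) as.numeric(d$top_bit) else NA_real_,
    targetName = if ("target_name" %in% names(d)) d$target_name
                 else NA_character_)
  g
}

#' Read a per-protein HMM hit table
#'
#' @param path TSV with columns `subject_id`, `pfam`, `bitscore`,
#'   `env_start`, `env_end` (1-based residue coordinates).
#' @return A data.frame, validated (finite scores, env_start <= env_end).
#' @export
readHmmHits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "pfam", "bitscore", "env_start", "env_end")
  if (!all(need %in% names(d)))
    stop("HMM hit table missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (any(!is.finite(d$bitscore))) stop("non-finite bitscore in HMM hit table")
  if (any(d$env_start > d$env_end)) stop("env_start > env_end in HMM hit table")
  d
}

# Canonical internal call table layout. `left`/`right` are the outer edges of
# the element span (including both direct-repeat copies); `dr_len` the length
# of the repeat block shared by attL and attR.
.CALL_COLS <- c("genome_id", "replicon", "left", "right", "dr_len", "seed",
                "side", "support", "refs", "q1m_start", "q1m_end",
                "q2m_start", "q2m_end", "dr_seq",
                "attB_context", "inferred", "fp", "type", "target", "name")

.emptyCalls <- function() {
  data.frame(genome_id = character(0), replicon = character(0),
             left = integer(0), right = integer(0), dr_len = integer(0),
             seed = character(0), side = character(0), support = integer(0),
             refs = character(0), q1m_start = integer(0),
             q1m_end = integer(0), q2m_start = integer(0),
             q2m_end = integer(0), dr_seq = character(0),
             attB_context = character(0), inferred = logical(0),
             fp = numeric(0), type = character(0), target = character(0),
             name = character(0), stringsAsFactors = FALSE)
}

.asCalls <- function(d) {
  for (col in .CALL_COLS) if (is.null(d[[col]]))
    d[[col]] <- .emptyCalls()[[col]][NA][seq_len(nrow(d))]
  if (nrow(d)) {
    d$support[is.na(d$support)] <- 0L
    d$inferred[is.na(d$inferred)] <- FALSE
  }
  d[, .CALL_COLS]
}

#' Write / read an element call table
#'
#' The on-disk layout reports the recombinant sites explicitly
#' (`attL_start`, `attL_end`, `attR_start`, `attR_end`); `attL_start` and
#' `attR_end` are the outer element edges and the att blocks both have length
#' `dr_len`. Coordinates round-trip exactly.
#'
#' @param calls Internal call data.frame (as produced by [mapGenome()] or
#'   [resolveCalls()]).
#' @param path Output TSV path.
#' @export
writeCallTable <- function(calls, path) {
  calls <- .asCalls(calls)
  out <- data.frame(
    genome_id = calls$genome_id, replicon = calls$replicon,
    attL_start = calls$left, attL_end = calls$left + calls$dr_len - 1L,
    attR_start = calls$right - calls$dr_len + 1L,
    attR_end = calls$right, dr_len = calls$dr_len,
    strand = "+", seed_gene = calls$seed, side = calls$side,
    support = calls$support, refs = calls$refs,
    q1m_start = calls$q1m_start, q1m_end = calls$q1m_end,
    q2m_start = calls$q2m_start, q2m_end = calls$q2m_end,
    dr_seq = calls$dr_seq, attB_context = calls$attB_context,
    inferred = calls$inferred, fp_score = calls$fp, type = calls$type,
    target = calls$target, name = calls$name, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCallTable
#' @return `readCallTable` returns the internal call data.frame.
#' @export
readCallTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(dr_seq = "character",
                                        attB_context = "character"))
  calls <- data.frame(
    genome_id = as.character(d$genome_id), replicon = as.character(d$replicon),
    left = d$attL_start, right = d$attR_end, dr_len = d$dr_len,
    seed = as.character(d$seed_gene), side = as.character(d$side),
    support = d$support, refs = as.character(d$refs),
    q1m_start = d$q1m_start, q1m_end = d$q1m_end,
    q2m_start = d$q2m_start, q2m_end = d$q2m_end,
    dr_seq = as.character(d$dr_seq),
    attB_context = as.character(d$attB_context), inferred = d$inferred,
    fp = d$fp_score, type = as.character(d$type),
    target = as.character(d$target), name = as.character(d$name),
    stringsAsFactors = FALSE)
  .asCalls(calls)
}
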