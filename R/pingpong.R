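# Two-phase ("ping-pong") comparative-genomic mapping. Phase I probes a
# reference collection with 15-kb flank queries taken left and right of the
# seed integrase midpoint; a match truncating at the element junction seeds a
# 3-kb return query from the reference, reaching back over the direct-repeat
# block; phase II aligns the return query to the source replicon, where the
# proximal segment re-finds the junction and the distal segment fixes the far
# terminus. The overlap of the two phase-II segments is the direct repeat.

#' Mapping configuration
#'
#' Defaults follow the published element-mode parameters: 15-kb flank
#' queries, 3-kb return queries reaching 250 bp back over the direct repeat,
#' phase-I matches retained when longer than 500 bp, and 2--200-kb element
#' size limits. IS mode uses a 30-bp reachback and 5--15-kb size limits.
#'
#' @param mode `"ige"` or `"is"`.
#' @param flankLen Flank query length (bp).
#' @param q2Len Return query length (bp), including the reachback.
#' @param reachback Return-query overlap into the phase-I match (bp).
#' @param minSize,maxSize Element size limits (bp).
#' @param minMatch Phase-I matches must be strictly longer than this (bp).
#' @param reachTol Slop (bp) when testing whether a phase-I match reaches the
#'   coordinate-proximal query end (indicating a reference that carries the
#'   same element).
#' @param mergeWindow Termini within this window merge as variants (bp).
#' @param distTol Junction-agreement tolerance when identifying the proximal
#'   phase-II segment (bp).
#' @param gapTol Largest unmatched gap (bp) tolerated between the proximal
#'   and distal phase-II segments; within it the junction is called with a
#'   zero-length repeat.
#' @return A named list of parameters.
#' @export
mapperConfig <- function(mode = c("ige", "is"), flankLen = 15000L,
                         q2Len = 3000L,
                         reachback = if (mode[1L] == "is") 30L else 250L,
                         minSize = if (mode[1L] == "is") 5000L else 2000L,
                         maxSize = if (mode[1L] == "is") 15000L else 200000L,
                         minMatch = 500L, reachTol = 10L, mergeWindow = 20L,
                         distTol = 50L, gapTol = 20L) {
  mode <- match.arg(mode)
  list(mode = mode, flankLen = as.integer(flankLen),
       q2Len = as.integer(q2Len), reachback = as.integer(reachback),
       minSize = as.integer(minSize), maxSize = as.integer(maxSize),
       minMatch = as.integer(minMatch), reachTol = as.integer(reachTol),
       mergeWindow = as.integer(mergeWindow), distTol = as.integer(distTol),
       gapTol = as.integer(gapTol))
}

#' Take the left and right flank queries around a seed
#'
#' `q1L` is the `flankLen` bases ending at `midpoint - 1`; `q1R` the
#' `flankLen` bases starting at `midpoint + 1`. Queries wrap the origin on
#' circular replicons and truncate at the ends of linear ones.
#'
#' @param midpoint Seed coordinate (integrase or transposase gene midpoint).
#' @param repliconSeq Replicon sequence (character).
#' @param topology `"circular"` or `"linear"`.
#' @param flankLen Flank length in bp.
#' @return List with `q1L`, `q1R` (character) and `startL`, `startR`: the
#'   (possibly unnormalized) replicon coordinate of position 1 of each query.
#' @export
takeFlankQueries <- function(midpoint, repliconSeq, topology = "linear",
                             flankLen = 15000L) {
  n <- nchar(repliconSeq)
  if (n < 2000L) {
    warning("replicon shorter than 2 kb; seed skipped")
    return(NULL)
  }
  fl <- min(flankLen, if (topology == "circular") n - 1L else flankLen)
  sL <- midpoint - fl; eL <- midpoint - 1L
  sR <- midpoint + 1L; eR <- midpoint + fl
  if (topology == "linear") { sL <- max(1L, sL); eR <- min(n, eR) }
  q1L <- if (eL >= sL) .subseqTopo(repliconSeq, sL, eL, topology) else ""
  q1R <- if (eR >= sR) .subseqTopo(repliconSeq, sR, eR, topology) else ""
  list(q1L = q1L, q1R = q1R, startL = sL, startR = sR)
}

# map a q1-local coordinate to a (normalized) replicon coordinate
.q1ToGenome <- function(pos, start, n) ((start + pos - 2L) %% n) + 1L

#' Phase-I scan of one flank query against one reference sequence
#'
#' Retains matches longer than `minMatch` whose query-side alignment does not
#' reach the coordinate-proximal end of the flank (a full-length match means
#' the reference carries the same element). Returns the single best retained
#' match: the one ending closest to the seed (ties broken by score).
#'
#' @param q1 Flank query (character).
#' @param refSeq Reference sequence (character).
#' @param side `"q1L"` or `"q1R"`.
#' @param config [mapperConfig()] list.
#' @param engine Match engine, e.g. [internalEngine()].
#' @return One-row match data.frame, or NULL if no retained match.
#' @export
phase1Scan <- function(q1, refSeq, side = c("q1L", "q1R"),
                       config = mapperConfig(), engine = internalEngine()) {
  side <- match.arg(side)
  if (nchar(q1) < config$minMatch) return(NULL)
  m <- engine(q1, refSeq)
  if (!nrow(m)) return(NULL)
  m <- m[m$length > config$minMatch, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  nq <- nchar(q1)
  keep <- if (side == "q1L") m$q_end < nq - config$reachTol
          else m$q_start > 1L + config$reachTol
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  ord <- if (side == "q1L") order(-m$q_end, -m$score)
         else order(m$q_start, -m$score)
  m[ord[1L], , drop = FALSE]
}

#' Phase-II return query from the reference
#'
#' Takes `q2Len` bases of the reference adjacent to the coordinate-proximal
#' end of a phase-I match, reaching `reachback` bases back into the matched
#' region to cover the direct-repeat block. Orientation is normalized to the
#' query strand.
#'
#' @param match One-row phase-I match.
#' @param refSeq Reference sequence (character).
#' @param side `"q1L"` or `"q1R"`.
#' @param config [mapperConfig()] list.
#' @return List with `q2` (character, possibly truncated at reference ends;
#'   `truncated` flag set) or NULL if the region is unavailable.
#' @export
phase2Return <- function(match, refSeq, side = c("q1L", "q1R"),
                         config = mapperConfig()) {
  side <- match.arg(side)
  ns <- nchar(refSeq)
  rb <- config$reachback; ql <- config$q2Len
  if (side == "q1L") {
    if (match$strand == "+") { a <- match$s_end - rb + 1L; b <- a + ql - 1L }
    else { b <- match$s_start + rb - 1L; a <- b - ql + 1L }
  } else {
    if (match$strand == "+") { b <- match$s_start + rb - 1L; a <- b - ql + 1L }
    else { a <- match$s_end - rb + 1L; b <- a + ql - 1L }
  }
  a0 <- max(1L, a); b0 <- min(ns, b)
  if (b0 - a0 + 1L < rb + 100L) return(NULL)
  q2 <- substr(refSeq, a0, b0)
  # on minus-strand matches the adjacent reference region is read back in
  # query orientation
  if (match$strand == "-") q2 <- .revComp(q2)
  list(q2 = q2, truncated = (a0 != a || b0 != b))
}

#' Locate the distal terminus from phase-II matches
#'
#' Pairs the proximal phase-II segment (re-finding the phase-I junction on
#' the source replicon) with a distal segment beyond the element; their
#' overlap in return-query coordinates is the direct-repeat length and their
#' replicon coordinates fix both termini. Ambiguous distal segments resolve
#' toward the smallest element within size limits (flagged).
#'
#' @param q2m Matches of the return query against the source replicon.
#' @param q2 The return query sequence.
#' @param side `"q1L"` or `"q1R"`.
#' @param junction Replicon coordinate of the phase-I junction.
#' @param midpoint Seed midpoint (the element must contain it).
#' @param config [mapperConfig()] list.
#' @return One-row call data.frame (columns `left`, `right`, `dr_len`,
#'   `dr_seq`, `q2m_start`, `q2m_end`, `ambiguous`) or NULL for no call.
#' @export
locateDistalEnd <- function(q2m, q2, side = c("q1L", "q1R"), junction,
                            midpoint, config = mapperConfig()) {
  side <- match.arg(side)
  q2m <- q2m[q2m$strand == "+", , drop = FALSE]
  if (!nrow(q2m)) return(NULL)
  if (side == "q1L") {
    prox <- q2m[abs(q2m$s_end - junction) <= config$distTol, , drop = FALSE]
    if (!nrow(prox)) return(NULL)
    prox <- prox[which.max(prox$score), ]
    cand <- q2m[q2m$s_start > junction - config$reachback &
                q2m$q_start > prox$q_start, , drop = FALSE]
    cand <- cand[!(cand$s_start == prox$s_start &
                   cand$s_end == prox$s_end), , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    # overlap of the two phase-II segments in return-query coordinates is
    # the direct repeat; a small unmatched gap (variant att core) gives a
    # repeat-free junction
    ov <- prox$q_end - cand$q_start + 1L
    dr <- pmax(0L, ov)
    left <- ifelse(ov >= 0L, prox$s_end - ov + 1L, prox$s_end + 1L)
    right <- ifelse(ov >= 0L, cand$s_start + ov - 1L, cand$s_start - 1L)
    ok <- ov >= -config$gapTol & right > midpoint &
      (right - left + 1L) >= config$minSize &
      (right - left + 1L) <= config$maxSize
  } else {
    prox <- q2m[abs(q2m$s_start - junction) <= config$distTol, , drop = FALSE]
    if (!nrow(prox)) return(NULL)
    prox <- prox[which.max(prox$score), ]
    cand <- q2m[q2m$s_end < junction + config$reachback &
                q2m$q_end < prox$q_end, , drop = FALSE]
    cand <- cand[!(cand$s_start == prox$s_start &
                   cand$s_end == prox$s_end), , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    ov <- cand$q_end - prox$q_start + 1L
    dr <- pmax(0L, ov)
    left <- ifelse(ov >= 0L, cand$s_end - ov + 1L, cand$s_end + 1L)
    right <- ifelse(ov >= 0L, prox$s_start + ov - 1L, prox$s_start - 1L)
    ok <- ov >= -config$gapTol & left < midpoint &
      (right - left + 1L) >= config$minSize &
      (right - left + 1L) <= config$maxSize
  }
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  dr <- dr[ok]; left <- left[ok]; right <- right[ok]
  size <- right - left + 1L
  i <- which.min(size)
  drSeq <- if (dr[i] > 0L) {
    if (side == "q1L") substr(q2, cand$q_start[i], prox$q_end)
    else substr(q2, prox$q_start, cand$q_end[i])
  } else ""
  data.frame(left = left[i], right = right[i], dr_len = dr[i],
             dr_seq = drSeq, q2m_start = cand$s_start[i],
             q2m_end = cand$s_end[i], ambiguous = length(size) > 1L,
             stringsAsFactors = FALSE)
}

#' Merge slightly variant calls
#'
#' Sequence variation near the att site among references causes small
#' fluctuations in called termini. Calls whose two termini each differ by at
#' most `window` bp are merged transitively; the merged call takes the
#' coordinates of the best-supported member and the union of supporting
#' references.
#'
#' @param calls Call data.frame (shared seed).
#' @param window Merge window in bp (default 20).
#' @return Merged call data.frame.
#' @export
mergeVariantCalls <- function(calls, window = 20L) {
  n <- nrow(calls)
  if (n <= 1L) return(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(calls$left[i] - calls$left[j]) <= window &&
        abs(calls$right[i] - calls$right[j]) <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- lapply(unique(comp), function(cc) {
    grp <- calls[comp == cc, , drop = FALSE]
    refs <- unique(unlist(strsplit(grp$refs, ",")))
    best <- grp[which.max(grp$support), , drop = FALSE]
    best$support <- length(refs)
    best$refs <- paste(refs, collapse = ",")
    best
  })
  do.call(rbind, out)
}

#' Deduplicate identical calls from the two flank sides
#'
#' Short elements are called from both `q1L` and `q1R`; identical-coordinate
#' calls collapse to one without double-counting reference support.
#'
#' @param calls Call data.frame.
#' @return Deduplicated calls (side set to `"both"` where collapsed).
#' @export
dedupeSides <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  key <- paste(calls$replicon, calls$left, calls$right, calls$seed)
  out <- lapply(unique(key), function(kk) {
    grp <- calls[key == kk, , drop = FALSE]
    if (nrow(grp) == 1L) return(grp)
    refs <- unique(unlist(strsplit(grp$refs, ",")))
    one <- grp[1L, , drop = FALSE]
    one$side <- if (length(unique(grp$side)) > 1L) "both" else one$side
    one$support <- length(refs)
    one$refs <- paste(refs, collapse = ",")
    one
  })
  do.call(rbind, out)
}

# does any single alignment of region sequence against an IS record cover
# (essentially) the whole region?
.coveredByIsDb <- function(regionSeq, isDb, engine, covFrac = 0.95) {
  for (isSeq in isDb) {
    m <- engine(regionSeq, isSeq)
    if (nrow(m) && max(m$q_end - m$q_start + 1L) >=
        covFrac * nchar(regionSeq)) return(TRUE)
  }
  FALSE
}

.regionInIs <- function(region, repliconId, genome, refdb, engine, isDb,
                        isConfig) {
  f <- geneFeatures(genome)
  dde <- f[S4Vectors::mcols(f)$klass == "DDE" &
           as.character(GenomicRanges::seqnames(f)) == repliconId]
  dde <- dde[GenomicRanges::start(dde) >= region[1L] &
             GenomicRanges::end(dde) <= region[2L]]
  for (i in seq_along(dde)) {
    mid <- as.integer(floor((GenomicRanges::start(dde)[i] +
                             GenomicRanges::end(dde)[i]) / 2))
    isCalls <- mapSeed(S4Vectors::mcols(dde)$geneId[i], mid, repliconId,
                       genome, refdb, config = isConfig, engine = engine,
                       filterIs = FALSE)
    if (nrow(isCalls) &&
        any(isCalls$left <= region[1L] & isCalls$right >= region[2L]))
      return(TRUE)
  }
  if (length(isDb)) {
    seq <- substr(as.character(replicons(genome)[[repliconId]]),
                  region[1L], region[2L])
    return(.coveredByIsDb(seq, isDb, engine))
  }
  FALSE
}

#' Reject calls arising from transposed insertion sequences
#'
#' A phase-I (or phase-II) match lying entirely within a transposon produces
#' a spurious element call when the IS has transposed between query and
#' reference. If a DDE transposase gene lies in the match region, the region
#' is probed by running the mapper in IS mode from that gene; if the
#' resulting IS call contains the entire match, the call is rejected.
#' Otherwise the match region is searched against an IS sequence database
#' and rejected when a single IS record covers the whole region.
#'
#' @param call One-row call data.frame (with `q1m_start`/`q1m_end` and
#'   `q2m_start`/`q2m_end` match regions).
#' @param genome Query [GenomeRecord-class].
#' @param refdb Named character vector of reference sequences.
#' @param engine Match engine.
#' @param isDb Named character vector of IS sequences (optional).
#' @param isConfig IS-mode [mapperConfig()].
#' @return `"keep"` or `"reject"`.
#' @export
isArtifactFilter <- function(call, genome, refdb, engine = internalEngine(),
                             isDb = character(0),
                             isConfig = mapperConfig("is")) {
  regions <- list(c(call$q1m_start, call$q1m_end),
                  c(call$q2m_start, call$q2m_end))
  for (rg in regions) {
    if (any(is.na(rg))) next
    if (.regionInIs(rg, call$replicon, genome, refdb, engine, isDb, isConfig))
      return("reject")
  }
  "keep"
}

#' Map one seed gene by two-phase alignment
#'
#' Runs the full ping-pong cycle for one seed: flank queries, phase-I scans
#' against every reference, phase-II return queries, terminus location,
#' variant merging and side deduplication. Support is the number of distinct
#' uninterrupted reference genomes mapping the same merged call.
#'
#' @param seedId Seed gene id.
#' @param midpoint Seed midpoint coordinate.
#' @param repliconId Replicon carrying the seed.
#' @param genome Query [GenomeRecord-class].
#' @param refdb Named character vector of reference genome sequences.
#' @param config [mapperConfig()].
#' @param engine Match engine.
#' @param isDb IS database for the artifact filter.
#' @param filterIs Apply the IS-artifact filter (default TRUE).
#' @return Call data.frame (possibly empty).
#' @export
mapSeed <- function(seedId, midpoint, repliconId, genome, refdb,
                    config = mapperConfig(), engine = internalEngine(),
                    isDb = character(0), filterIs = TRUE) {
  repSeq <- as.character(replicons(genome)[[repliconId]])
  topo <- topology(genome)[[repliconId]]
  n <- nchar(repSeq)
  fq <- takeFlankQueries(midpoint, repSeq, topo, config$flankLen)
  if (is.null(fq)) return(.emptyCalls())
  rows <- list()
  for (side in c("q1L", "q1R")) {
    q1 <- if (side == "q1L") fq$q1L else fq$q1R
    start1 <- if (side == "q1L") fq$startL else fq$startR
    if (nchar(q1) <= config$minMatch) next
    for (rn in names(refdb)) {
      bm <- phase1Scan(q1, refdb[[rn]], side, config, engine)
      if (is.null(bm)) next
      jloc <- if (side == "q1L") bm$q_end else bm$q_start
      junction <- .q1ToGenome(jloc, start1, n)
      p2 <- phase2Return(bm, refdb[[rn]], side, config)
      if (is.null(p2)) next
      q2m <- engine(p2$q2, repSeq)
      cl <- locateDistalEnd(q2m, p2$q2, side, junction, midpoint, config)
      if (is.null(cl)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genomeId(genome), replicon = repliconId,
        left = cl$left, right = cl$right, dr_len = cl$dr_len,
        seed = seedId, side = side, support = 1L, refs = rn,
        q1m_start = .q1ToGenome(bm$q_start, start1, n),
        q1m_end = .q1ToGenome(bm$q_end, start1, n),
        q2m_start = cl$q2m_start, q2m_end = cl$q2m_end,
        dr_seq = cl$dr_seq, attB_context = p2$q2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyCalls())
  calls <- .asCalls(do.call(rbind, rows))
  merged <- lapply(split(calls, calls$side), mergeVariantCalls,
                   window = config$mergeWindow)
  calls <- dedupeSides(do.call(rbind, merged))
  rownames(calls) <- NULL
  if (filterIs && nrow(calls)) {
    verdict <- vapply(seq_len(nrow(calls)), function(i)
      isArtifactFilter(calls[i, ], genome, refdb, engine, isDb,
                       mapperConfig("is", flankLen = config$flankLen)), "")
    calls <- calls[verdict == "keep", , drop = FALSE]
  }
  calls
}

#' Map all seeds of a genome
#'
#' @param genome Query [GenomeRecord-class] with classified features.
#' @param refdb Named character vector of reference genome sequences.
#' @param mode `"ige"` (integrase seeds) or `"is"` (DDE transposase seeds).
#' @param config [mapperConfig()]; defaults to the mode's standard values.
#' @param engine Match engine.
#' @param isDb IS database for the artifact filter.
#' @param filterIs Apply the IS-artifact filter.
#' @return Raw call data.frame across seeds.
#' @export
mapGenome <- function(genome, refdb, mode = c("ige", "is"),
                      config = NULL, engine = internalEngine(),
                      isDb = character(0), filterIs = TRUE) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- mapperConfig(mode)
  seeds <- seedGenes(genome, mode)
  out <- lapply(seq_len(nrow(seeds)), function(i)
    mapSeed(seeds$geneId[i], seeds$midpoint[i], seeds$replicon[i], genome,
            refdb, config, engine, isDb, filterIs))
  res <- do.call(rbind, c(list(.emptyCalls()), out))
  rownames(res) <- NULL
  res
}
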