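# Internal deterministic local-alignment engine: seed-and-extend on exact
# k-mers, ungapped extension with affine-free +1/-3 scoring, maximal-scoring
# segment extraction per diagonal. Designed for mutation-free and
# low-substitution comparisons (no indels), where it reproduces the segment
# structure an external nucleotide aligner reports, with exact coordinates.

# Extract all maximal scoring segments from a score vector (+1 match,
# -mispen mismatch): recursive Kadane. Returns matrix [start, end, score].
.maxSegs <- function(sc, minScore) {
  out <- list()
  stack <- list(c(1L, length(sc)))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- iv[1L]; b <- iv[2L]
    if (b < a) next
    cs <- cumsum(sc[a:b])
    pref <- c(0, cs)
    pm <- cummin(pref[-length(pref)])
    val <- cs - pm
    e <- which.max(val)
    if (val[e] < minScore) next
    s <- which.min(pref[seq_len(e)])  # index into pref; segment starts at s
    out[[length(out) + 1L]] <- c(a + s - 1L, a + e - 1L, val[e])
    if (s - 2L >= 1L) stack[[length(stack) + 1L]] <- c(a, a + s - 3L)
    if (e + 1L <= b - a + 1L) stack[[length(stack) + 1L]] <- c(a + e, b)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}

# numeric k-mer encoding: each k-mer as a base-4 number held exactly in a
# double (k <= 26); positions containing non-ACGT bases encode as NA
.encodeKmers <- function(raw, k) {
  code <- match(as.integer(raw), c(65L, 67L, 71L, 84L)) - 1L
  n <- length(code) - k + 1L
  if (n < 1L) return(numeric(0))
  val <- numeric(n)
  pw <- 4^((k - 1L):0)
  for (j in seq_len(k)) val <- val + code[j:(j + n - 1L)] * pw[j]
  val
}

# sorted-position index over subject k-mers, reused across strands
.subjectIndex <- function(sraw, k, maxOcc = 100L) {
  sv <- .encodeKmers(sraw, k)
  keep <- which(!is.na(sv))
  si <- keep[order(sv[keep])]
  list(pos = si, val = sv[si], maxOcc = maxOcc)
}

.matchOneStrand <- function(query, sIndex, sraw, k, minLen, minScore,
                            mispen, gapMax, pad, minIdent) {
  nq <- nchar(query); ns <- length(sraw)
  if (nq < k) return(NULL)
  qraw <- charToRaw(query)
  qv <- .encodeKmers(qraw, k)
  qok <- which(!is.na(qv))
  if (!length(qok)) return(NULL)
  v <- qv[qok]
  hi <- findInterval(v, sIndex$val)
  lo <- findInterval(v - 0.5, sIndex$val) + 1L
  cnt <- pmax(0L, hi - lo + 1L)
  cnt[cnt > sIndex$maxOcc] <- 0L   # repeat-mask hyper-abundant seeds
  sel <- cnt > 0L
  if (!any(sel)) return(NULL)
  qpos <- rep(qok[sel], cnt[sel])
  spos <- sIndex$pos[sequence(cnt[sel], from = lo[sel])]
  dg <- spos - qpos
  res <- list()
  byDiag <- split(qpos, dg)
  for (dn in names(byDiag)) {
    d <- as.integer(dn)
    qp <- sort(unique(byDiag[[dn]]))
    cl <- split(qp, cumsum(c(1L, diff(qp) > gapMax)))
    lo <- max(1L, 1L - d); hi <- min(nq, ns - d)
    for (cc in cl) {
      a <- max(lo, cc[1L] - pad)
      b <- min(hi, cc[length(cc)] + k - 1L + pad)
      if (b < a) next
      mism <- qraw[a:b] != sraw[(a:b) + d]
      sc <- ifelse(mism, -mispen, 1)
      segs <- .maxSegs(sc, minScore)
      if (!nrow(segs)) next
      for (r in seq_len(nrow(segs))) {
        qs <- a + segs[r, 1L] - 1L; qe <- a + segs[r, 2L] - 1L
        len <- qe - qs + 1L
        nmatch <- (segs[r, 3L] + mispen * len) / (1 + mispen)
        ident <- nmatch / len
        if (len < minLen || ident < minIdent) next
        res[[length(res) + 1L]] <-
          c(qs, qe, qs + d, qe + d, len, ident, segs[r, 3L])
      }
    }
  }
  if (!length(res)) return(NULL)
  m <- do.call(rbind, res)
  m[!duplicated(m[, c(1, 3), drop = FALSE]), , drop = FALSE]
}

#' Local alignment matches between two sequences (internal engine)
#'
#' Deterministic seed-and-extend matcher returning ungapped local alignment
#' segments in the same record layout as the external BLASTN adapter:
#' 1-based query/subject coordinates, strand, length and identity. Suitable
#' for comparisons without indels (the synthetic-fixture regime); for real
#' survey data plug in [blastnEngine()] instead.
#'
#' @param query,subject DNA sequences as character strings.
#' @param k Seed k-mer length (default 16).
#' @param minLen Minimum reported segment length (default 25 bp, so that
#'   short direct-repeat and reachback segments are reported).
#' @param minScore Minimum segment score, +1 per match / -`mispen` per
#'   mismatch (default 22).
#' @param mispen Mismatch penalty (default 3).
#' @param gapMax Seed-clustering gap along a diagonal (default 300 bp).
#' @param pad Extension padding around a seed cluster (default 150 bp).
#' @param minIdent Minimum segment identity (default 0.75).
#' @param bothStrands Also search the reverse complement of the query.
#' @return data.frame with columns `q_start`, `q_end`, `s_start`, `s_end`,
#'   `strand`, `length`, `identity`, `score`. Query coordinates always refer
#'   to the forward query; for minus-strand matches the subject interval is
#'   reported with `s_start <= s_end`.
#' @examples
#' set.seed(1)
#' a <- paste(sample(c("A","C","G","T"), 3000, TRUE), collapse = "")
#' b <- paste0(substr(a, 1001, 2000), substr(a, 1, 500))
#' matchSegments(b, a)
#' @export
matchSegments <- function(query, subject, k = 16L, minLen = 25L,
                          minScore = 22, mispen = 3, gapMax = 300L,
                          pad = 150L, minIdent = 0.75, bothStrands = TRUE) {
  empty <- data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  ns <- nchar(subject)
  if (ns < k || nchar(query) < k) return(empty)
  sraw <- charToRaw(subject)
  sIndex <- .subjectIndex(sraw, k)
  nq <- nchar(query)
  rows <- list()
  fwd <- .matchOneStrand(query, sIndex, sraw, k, minLen, minScore,
                         mispen, gapMax, pad, minIdent)
  if (!is.null(fwd))
    rows[[1L]] <- data.frame(q_start = fwd[, 1L], q_end = fwd[, 2L],
                             s_start = fwd[, 3L], s_end = fwd[, 4L],
                             strand = "+", length = fwd[, 5L],
                             identity = fwd[, 6L], score = fwd[, 7L],
                             stringsAsFactors = FALSE)
  if (bothStrands) {
    rc <- .revComp(query)
    rev <- .matchOneStrand(rc, sIndex, sraw, k, minLen, minScore,
                           mispen, gapMax, pad, minIdent)
    if (!is.null(rev))
      rows[[length(rows) + 1L]] <-
        data.frame(q_start = nq - rev[, 2L] + 1L, q_end = nq - rev[, 1L] + 1L,
                   s_start = rev[, 3L], s_end = rev[, 4L], strand = "-",
                   length = rev[, 5L], identity = rev[, 6L],
                   score = rev[, 7L], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out$q_start <- as.integer(out$q_start); out$q_end <- as.integer(out$q_end)
  out$s_start <- as.integer(out$s_start); out$s_end <- as.integer(out$s_end)
  out$length <- as.integer(out$length)
  out
}

#' Internal engine as an engine closure
#'
#' The mapping functions take an `engine` argument: any
#' `function(query, subject)` returning the [matchSegments()] record layout.
#' @param ... Fixed arguments passed on to [matchSegments()].
#' @return An engine function.
#' @export
internalEngine <- function(...) {
  function(query, subject) matchSegments(query, subject, ...)
}

#' External BLASTN adapter as an engine closure
#'
#' Runs the `blastn` executable (via `-subject`, so no database formatting is
#' needed) with default task settings and parses tabular output into the
#' shared match record. Requires `blastn` on the PATH.
#'
#' @param task BLASTN task (default `"megablast"`, the default-mode search).
#' @return An engine function, or an error at call time if `blastn` is not
#'   available.
#' @export
blastnEngine <- function(task = "megablast") {
  function(query, subject) {
    if (Sys.which("blastn") == "")
      stop("blastn not found on PATH")
    qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
    on.exit(unlink(c(qf, sf)))
    writeLines(c(">q", query), qf)
    writeLines(c(">s", subject), sf)
    out <- suppressWarnings(system2("blastn",
      c("-task", task, "-query", qf, "-subject", sf, "-outfmt",
        shQuote("6 qstart qend sstart send length pident sstrand bitscore")),
      stdout = TRUE))
    if (!length(out))
      return(matchSegments("A", "T"))  # empty record frame
    d <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE)
    names(d) <- c("q_start", "q_end", "s_start", "s_end", "length",
                  "pident", "sstrand", "score")
    minus <- d$sstrand == "minus"
    tmp <- d$s_start[minus]
    d$s_start[minus] <- d$s_end[minus]
    d$s_end[minus] <- tmp
    data.frame(q_start = d$q_start, q_end = d$q_end, s_start = d$s_start,
               s_end = d$s_end, strand = ifelse(minus, "-", "+"),
               length = d$length, identity = d$pident / 100,
               score = d$score, stringsAsFactors = FALSE)
  }
}
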