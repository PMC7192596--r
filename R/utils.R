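# Internal string/sequence helpers. The alignment engine and the fixture
# generator work on plain upper-case character strings for speed; Biostrings
# objects are used at the package boundary (I/O, translation).

.DNA_ALPHA <- c("A", "C", "G", "T")

.revComp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", intToUtf8(rev(utf8ToInt(x))))
}

.gcFrac <- function(x) {
  n <- nchar(x)
  if (n == 0L) stop("empty sequence")
  gc <- nchar(gsub("[^GCgc]", "", x))
  acgt <- nchar(gsub("[^ACGTacgt]", "", x))
  if (acgt == 0L) stop("sequence contains no unambiguous bases")
  gc / acgt
}

# Extract [start, end] from a replicon, wrapping the origin when circular.
# start may be < 1 and end may exceed the length on circular replicons;
# on linear replicons the range is truncated to the sequence.
.subseqTopo <- function(seq, start, end, topology) {
  n <- nchar(seq)
  if (end < start) stop("end < start in .subseqTopo")
  if (topology == "circular") {
    if (end - start + 1L > n) stop("range longer than circular replicon")
    idx0 <- (seq.int(start, end) - 1L) %% n + 1L
    # fast path: contiguous
    if (start >= 1L && end <= n) return(substr(seq, start, end))
    chunks <- split(idx0, cumsum(c(1L, diff(idx0) != 1L)))
    paste(vapply(chunks, function(ix) substr(seq, ix[1L], ix[length(ix)]), ""),
          collapse = "")
  } else {
    substr(seq, max(1L, start), min(n, end))
  }
}

# Positions of all k-mers of x (1-based start positions), as character vector.
.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

.randDna <- function(n) paste(sample(.DNA_ALPHA, n, replace = TRUE), collapse = "")

# Rank-based AUROC used internally where a full ROC object is not needed.
.auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

.cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
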