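# Independent oracles used across tests.

# union-find connected components; clusters of size >= 2 labelled 1..k in
# order of smallest member, singletons 0 (the oracle for density clustering
# with radius 1 / min 2 on a unit-weight graph)
ufComponents <- function(edges, ids) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(match(edges$ige_a[r], ids))
    b <- find(match(edges$ige_b[r], ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, 1L)
  out <- integer(length(ids))
  k <- 0L
  for (r in unique(roots)) {
    member <- roots == r
    if (sum(member) >= 2L) { k <- k + 1L; out[member] <- k }
  }
  setNames(out, ids)
}

# same-partition comparison ignoring label numbering
samePartition <- function(a, b) {
  keyA <- split(names(a), a)
  keyB <- split(names(b), b)
  setequal(lapply(keyA[names(keyA) != "0"], sort),
           lapply(keyB[names(keyB) != "0"], sort)) &&
    setequal(names(a)[a == 0L], names(b)[b == 0L])
}

# brute-force dinucleotide relative-abundance difference (genomic signature
# convention), written independently of the package implementation
bruteDinucBias <- function(s1, s2) {
  rho <- function(s) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    both <- c(s, rc)
    nucs <- c("A", "C", "G", "T")
    monoC <- setNames(numeric(4), nucs)
    diC <- matrix(0, 4, 4, dimnames = list(nucs, nucs))
    for (x in both) {
      ch <- strsplit(x, "")[[1]]
      for (b in ch) monoC[b] <- monoC[b] + 1
      if (length(ch) > 1) for (i in seq_len(length(ch) - 1))
        diC[ch[i], ch[i + 1]] <- diC[ch[i], ch[i + 1]] + 1
    }
    fM <- monoC / sum(monoC)
    fD <- diC / sum(diC)
    out <- matrix(NA_real_, 4, 4, dimnames = list(nucs, nucs))
    for (x in nucs) for (y in nucs)
      if (fM[x] > 0 && fM[y] > 0) out[x, y] <- fD[x, y] / (fM[x] * fM[y])
    out
  }
  d <- abs(rho(s1) - rho(s2))
  sum(d, na.rm = TRUE) / 16
}

randomSeq <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# one standard planted-element fixture, cached for reuse within a test file
standardFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateFixture(fixtureSpec(), seed = 7)
    cache
  }
})
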