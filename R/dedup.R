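# Deduplication of vertically inherited near-identical elements: fragment
# average nucleotide identity, a filtered similarity graph, all-pairs
# shortest paths, and density clustering with radius 1 / minimum 2, which on
# a unit-weight graph equals connected components (asserted against a
# union-find oracle in the test suite).

#' Fragment-based average nucleotide identity between two sequences
#'
#' Sequence `a` is cut into non-overlapping `fragLen`-bp fragments; each is
#' mapped to its best local match in `b` (admission: identity >= 0.8 over
#' >= 60 percent of the fragment, emulating the mapping admission of
#' fragment-ANI tools). ANI is the mean identity of mapped fragments and the
#' alignment fraction the proportion of fragments mapped. Fewer than
#' `minFrag` mapped fragments yields no estimate.
#'
#' @param a,b DNA character strings.
#' @param fragLen Fragment length (default 500 bp, accommodating the minimum
#'   element size).
#' @param minFrag Minimum mapped fragments (default 2).
#' @param engine Match engine.
#' @return List with `ani`, `af`, `nMapped`, `nFrag`; `ani`/`af` are `NA`
#'   when fewer than `minFrag` fragments map or `a` is shorter than
#'   `fragLen * minFrag`.
#' @export
pairwiseAni <- function(a, b, fragLen = 500L, minFrag = 2L,
                        engine = internalEngine()) {
  nFrag <- nchar(a) %/% fragLen
  if (nFrag < minFrag)
    return(list(ani = NA_real_, af = NA_real_, nMapped = 0L, nFrag = nFrag))
  idents <- rep(NA_real_, nFrag)
  for (i in seq_len(nFrag)) {
    frag <- substr(a, (i - 1L) * fragLen + 1L, i * fragLen)
    m <- engine(frag, b)
    if (!nrow(m)) next
    m <- m[m$length >= 0.6 * fragLen & m$identity >= 0.8, , drop = FALSE]
    if (!nrow(m)) next
    best <- m[which.max(m$score), ]
    # identity over the full fragment: unaligned tails count as mismatch
    idents[i] <- best$identity * best$length / fragLen
  }
  mapped <- which(!is.na(idents))
  if (length(mapped) < minFrag)
    return(list(ani = NA_real_, af = NA_real_, nMapped = length(mapped),
                nFrag = nFrag))
  list(ani = mean(idents[mapped]), af = length(mapped) / nFrag,
       nMapped = length(mapped), nFrag = nFrag)
}

#' Build the filtered ANI edge list over a set of element sequences
#'
#' ANI is directional; both directions are computed and the pair keeps an
#' edge if either direction passes the thresholds.
#'
#' @param seqs Named character vector of element sequences.
#' @param aniMin,afMin Edge thresholds (defaults 0.95 and 0.9).
#' @param fragLen,minFrag,engine Passed to [pairwiseAni()].
#' @return data.frame with `ige_a`, `ige_b`, `ani`, `af`.
#' @export
aniEdges <- function(seqs, aniMin = 0.95, afMin = 0.9, fragLen = 500L,
                     minFrag = 2L, engine = internalEngine()) {
  ids <- names(seqs)
  out <- list()
  n <- length(seqs)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ab <- pairwiseAni(seqs[[i]], seqs[[j]], fragLen, minFrag, engine)
    ba <- pairwiseAni(seqs[[j]], seqs[[i]], fragLen, minFrag, engine)
    pick <- NULL
    if (!is.na(ab$ani) && ab$ani > aniMin && ab$af > afMin) pick <- ab
    else if (!is.na(ba$ani) && ba$ani > aniMin && ba$af > afMin) pick <- ba
    if (!is.null(pick))
      out[[length(out) + 1L]] <- data.frame(ige_a = ids[i], ige_b = ids[j],
                                            ani = pick$ani, af = pick$af,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ige_a = character(0), ige_b = character(0),
                      ani = numeric(0), af = numeric(0)))
  do.call(rbind, out)
}

# DBSCAN on a precomputed distance matrix (eps-radius, minPts including the
# point itself); returns integer labels, 0 = noise
.dbscanDist <- function(D, eps, minPts) {
  n <- nrow(D)
  labels <- rep(0L, n)
  cl <- 0L
  core <- vapply(seq_len(n), function(i)
    sum(D[i, ] <= eps, na.rm = TRUE) >= minPts, TRUE)
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      nb <- which(D[q, ] <= eps & seq_len(n) != q)
      for (v in nb) {
        if (labels[v] == 0L) {
          labels[v] <- cl
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
  }
  labels
}

#' Cluster elements on the filtered ANI graph
#'
#' Unit-weight edges; all-pairs shortest-path lengths; density clustering on
#' the distance matrix with radius 1 and minimum cluster seed of 2.
#' Singletons stay unclustered.
#'
#' @param edges Edge data.frame (`ige_a`, `ige_b`), already filtered.
#' @param ids Character vector of all element ids (including singletons).
#' @return Integer vector of cluster labels named by id (0 = unclustered).
#' @export
clusterIges <- function(edges, ids) {
  n <- length(ids)
  if (!n) return(setNames(integer(0), character(0)))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$ige_a, ids),
                                    match(edges$ige_b, ids)))
  D <- igraph::distances(g)   # unit weights: shortest path lengths
  labels <- .dbscanDist(D, eps = 1, minPts = 2L)
  setNames(labels, ids)
}

#' Choose one representative per cluster
#'
#' Deterministic: highest support, then best (lowest) false-positive score,
#' then lexicographically smallest id.
#'
#' @param labels Cluster labels from [clusterIges()].
#' @param calls Call data.frame with `name` (or id), `support`, `fp`.
#' @param idCol Column of `calls` holding the element id.
#' @return data.frame with `cluster`, `representative`, `members`.
#' @export
chooseRepresentative <- function(labels, calls, idCol = "name") {
  cls <- sort(unique(labels[labels > 0L]))
  out <- lapply(cls, function(cc) {
    ids <- names(labels)[labels == cc]
    sub <- calls[match(ids, calls[[idCol]]), , drop = FALSE]
    sup <- sub$support; sup[is.na(sup)] <- 0L
    fp <- sub$fp; fp[is.na(fp)] <- Inf
    ord <- order(-sup, fp, ids)
    data.frame(cluster = cc, representative = ids[ord[1L]],
               members = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(cluster = integer(0), representative = character(0),
                      members = character(0)))
  do.call(rbind, out)
}

#' Deduplicate a call set by ANI clustering
#'
#' @param calls Resolved call data.frame with `name` ids.
#' @param genome Source [GenomeRecord-class] (sequences are cut from it).
#' @param ... Passed to [aniEdges()].
#' @return List with `calls` (representatives plus singletons), `labels`,
#'   `edges` and `clusters`.
#' @export
dedupeIges <- function(calls, genome, ...) {
  if (!nrow(calls)) return(list(calls = calls, labels = integer(0),
                                edges = NULL, clusters = NULL))
  seqs <- vapply(seq_len(nrow(calls)), function(i)
    substr(as.character(replicons(genome)[[calls$replicon[i]]]),
           calls$left[i], calls$right[i]), "")
  names(seqs) <- calls$name
  edges <- aniEdges(seqs, ...)
  labels <- clusterIges(edges, names(seqs))
  reps <- chooseRepresentative(labels, calls)
  keep <- labels == 0L | calls$name %in% reps$representative
  list(calls = calls[keep, , drop = FALSE], labels = labels, edges = edges,
       clusters = reps)
}
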