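# Integrase-tree analytics: per-clade depth (mean pairwise patristic
# distance), attB site-usage purity and bootstrap support; the shallow/
# diverse promiscuity screen anchored by the IS607 clade; profile-score
# membership calls; detection of regulated-gene-integrity candidate clades;
# and the 2x2 chi-square used for enrichment statements.

#' Per-clade statistics from an integrase tree
#'
#' For every internal node of a tree with branch supports, computes the
#' member set, bootstrap support (node labels; percentages auto-detected and
#' scaled to fractions), depth (mean pairwise patristic distance among
#' members) and site-usage purity (percentage of members using the clade's
#' most frequent attB site). Leaves missing from `siteMap` are excluded from
#' purity (flagged by `nSiteless`).
#'
#' @param tree An [ape::phylo] tree, node labels holding supports.
#' @param siteMap Named character vector: leaf id -> attB site descriptor.
#' @return data.frame with `node`, `size`, `support`, `depth`, `topSite`,
#'   `purity`, `nSiteless`, `members` (comma-joined leaf ids).
#' @export
cladeStats <- function(tree, siteMap) {
  nt <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  D <- stats::cophenetic(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100   # percent -> fraction
  nodes <- (nt + 1L):(nt + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  out <- lapply(seq_along(nodes), function(i) {
    tips <- tree$tip.label[desc[[i]]]
    k <- length(tips)
    if (k < 2L) return(NULL)
    sub <- D[tips, tips, drop = FALSE]
    depth <- mean(sub[upper.tri(sub)])
    sites <- siteMap[tips]
    sites <- sites[!is.na(sites)]
    if (length(sites)) {
      tab <- sort(table(sites), decreasing = TRUE)
      topSite <- names(tab)[1L]
      purity <- 100 * as.numeric(tab[1L]) / length(sites)
    } else { topSite <- NA_character_; purity <- NA_real_ }
    data.frame(node = nodes[i], size = k,
               support = sup[nodes[i] - nt], depth = depth,
               topSite = topSite, purity = purity,
               nSiteless = k - length(sites),
               members = paste(tips, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen clades for site promiscuity
#'
#' Flags high-support clades that are shallow yet use diverse attB sites:
#' purity below `purityMax` and depth at most the anchor depth of the large
#' promiscuous IS607 clade. Clades of four or fewer members are excluded
#' (their minimum possible purity is already 25 percent).
#'
#' @param clades data.frame from [cladeStats()].
#' @param is607Depth Depth anchor (mean pairwise distance of the IS607
#'   clade).
#' @param purityMax Purity bound in percent (default 25).
#' @param supportMin High-support threshold as a fraction (default 0.5).
#' @return The flagged subset of `clades`.
#' @export
promiscuityScreen <- function(clades, is607Depth, purityMax = 25,
                              supportMin = 0.5) {
  keep <- !is.na(clades$support) & clades$support >= supportMin &
    clades$size > 4L & !is.na(clades$purity) & clades$purity < purityMax &
    clades$depth <= is607Depth
  clades[keep, , drop = FALSE]
}

#' Profile-score membership call (IS607-style)
#'
#' Clade membership from a single profile score at a fixed bitscore cutoff;
#' the published IS607 profile separates its clade perfectly at 64 bits.
#'
#' @param scores Named numeric of profile bitscores per integrase.
#' @param cutoff Bitscore cutoff (default 64).
#' @return Named logical.
#' @export
classifyIs607 <- function(scores, cutoff = 64) {
  setNames(scores >= cutoff, names(scores))
}

#' Detect regulated-gene-integrity candidate clades
#'
#' A candidate is a tight (depth at most `depthMax`), high-support clade of
#' two or more deduplicated members, all of whose members disrupt the same
#' domain without restoration (attB win on the same Pfam) at crossover
#' positions within `posTol` residues of each other. Candidates contained
#' within a larger candidate are dropped.
#'
#' @param clades data.frame from [cladeStats()].
#' @param disruptions Named list: leaf id -> [disruptionAssay()] result.
#' @param posTol Crossover-position tolerance in residues (default 10).
#' @param depthMax Tight-clade depth cutoff (default 0.5 substitutions/site
#'   mean pairwise).
#' @param supportMin High-support threshold (default 0.5).
#' @return data.frame with `node`, `size`, `depth`, `support`,
#'   `disruptedPfam`, `positions`, `members`.
#' @export
detectRgi <- function(clades, disruptions, posTol = 10L, depthMax = 0.5,
                      supportMin = 0.5) {
  cand <- list()
  for (i in seq_len(nrow(clades))) {
    cl <- clades[i, ]
    if (is.na(cl$support) || cl$support < supportMin) next
    if (cl$depth > depthMax || cl$size < 2L) next
    tips <- strsplit(cl$members, ",")[[1]]
    ds <- disruptions[tips]
    if (any(vapply(ds, is.null, TRUE))) next
    if (!all(vapply(ds, function(d) identical(d$outcome, "attB_win"), TRUE)))
      next
    pfams <- vapply(ds, function(d) d$bestPfam, "")
    if (length(unique(pfams)) != 1L) next
    pos <- vapply(ds, function(d) as.numeric(d$crossoverPos), 0)
    if (any(is.na(pos)) || diff(range(pos)) > posTol) next
    cand[[length(cand) + 1L]] <-
      data.frame(node = cl$node, size = cl$size, depth = cl$depth,
                 support = cl$support, disruptedPfam = pfams[1L],
                 positions = paste(pos, collapse = ","),
                 members = cl$members, stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(node = integer(0), size = integer(0),
                      depth = numeric(0), support = numeric(0),
                      disruptedPfam = character(0), positions = character(0),
                      members = character(0)))
  out <- do.call(rbind, cand)
  # keep maximal candidates only
  memb <- lapply(out$members, function(m) strsplit(m, ",")[[1]])
  keep <- vapply(seq_along(memb), function(i)
    !any(vapply(seq_along(memb), function(j)
      i != j && all(memb[[i]] %in% memb[[j]]) &&
        length(memb[[j]]) > length(memb[[i]]), TRUE)), TRUE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom: the form used for
#' site-usage and disruption-enrichment contrasts.
#'
#' @param a,b,c,d Cell counts (first row `a`, `b`; second row `c`, `d`).
#' @return List with `statistic`, `p`, `n`.
#' @export
chi2Test2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  m <- matrix(c(a, c, b, d), 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       n = sum(m))
}
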