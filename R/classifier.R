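# Element subtyping (phage / ICE heuristics from HMM content) and the
# domain-disruption assay: six-frame translation of 998-bp windows centered
# on each terminus, reconstruction of the uninterrupted attB peptides by
# joining chromosomal halves in all frame combinations, and comparison of
# top domain bitscores between attLR and attB.

#' Resolve the four subtype flags into a final type
#'
#' `Phage1` (at least one virion and one non-virion phage-HMM hit) with any
#' ICE flag resolves to `ICE+Phage` (an unresolved tandem or one type
#' integrated in the other); `Phage2` (any phage hit) with an ICE flag
#' resolves to `ICE`; otherwise the strongest single flag wins (`Phage`,
#' `ICE`, `Phage-weak`), and no flag gives `Unknown`.
#'
#' @param phage1,phage2,ice1,ice2 Logical flags.
#' @return One of `"Phage"`, `"Phage-weak"`, `"ICE"`, `"ICE+Phage"`,
#'   `"Unknown"`.
#' @export
finalType <- function(phage1, phage2, ice1, ice2) {
  ice <- ice1 || ice2
  if (phage1 && ice) return("ICE+Phage")
  if (phage1) return("Phage")
  if (phage2 && ice) return("ICE")
  if (ice) return("ICE")
  if (phage2) return("Phage-weak")
  "Unknown"
}

#' Subtype one element from its HMM content
#'
#' Heuristics: `Phage1` needs >=1 virion and >=1 non-virion phage-HMM hit;
#' `Phage2` >=1 phage hit of either category; `ICE1` >=7 ICE-HMM hits
#' covering >=15 percent of the element's proteins; `ICE2` >=2 ICE hits
#' covering >=12 percent (element <10 kb) or >=7 percent (>=10 kb).
#'
#' @param nProteins Number of protein genes in the element.
#' @param virionHits,nonvirionHits Number of proteins hitting virion /
#'   non-virion phage HMMs.
#' @param iceHits Number of proteins hitting ICE HMMs.
#' @param igeLen Element length in bp.
#' @return List with the four flags and `final`.
#' @export
typeIge <- function(nProteins, virionHits, nonvirionHits, iceHits, igeLen) {
  if (nProteins < 1L) stop("element must have at least one protein")
  phage1 <- virionHits >= 1L && nonvirionHits >= 1L
  phage2 <- (virionHits + nonvirionHits) >= 1L
  iceFrac <- iceHits / nProteins
  ice1 <- iceHits >= 7L && iceFrac >= 0.15
  ice2 <- iceHits >= 2L &&
    iceFrac >= (if (igeLen < 10000L) 0.12 else 0.07)
  list(phage1 = phage1, phage2 = phage2, ice1 = ice1, ice2 = ice2,
       final = finalType(phage1, phage2, ice1, ice2))
}

#' Recall-corrected type composition
#'
#' Divides raw call fractions by the recall measured on positive controls;
#' the remainder is the uncharacterized fraction. If corrections exceed 1 in
#' total they are renormalized (flagged via attribute).
#'
#' @param fractions Named numeric of raw call fractions (e.g.
#'   `c(phage = 0.378, ice = 0.092)`).
#' @param recalls Named numeric of recall rates in (0, 1], matching names.
#' @return Named numeric of corrected fractions plus `unknown`.
#' @export
estimateComposition <- function(fractions, recalls) {
  if (any(recalls <= 0)) stop("recall must be positive")
  corrected <- fractions / recalls[names(fractions)]
  renorm <- FALSE
  if (sum(corrected) > 1) {
    corrected <- corrected / sum(corrected)
    renorm <- TRUE
  }
  out <- c(corrected, unknown = max(0, 1 - sum(corrected)))
  attr(out, "renormalized") <- renorm
  out
}

# standard-code codon table (stops as '*'); codons with ambiguous bases
# translate to 'X'. A lookup table keeps raw-frame translation of the many
# short assay windows cheap.
.CODON_AA <- local({
  b <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(b, b, paste0)))
  codons <- unlist(lapply(b, function(x) paste0(x, codons[1:16])))
  setNames(aas, codons)
})

.translateRaw <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  cod <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .CODON_AA[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.translateFrames <- function(dna) {
  # three forward frames anchored at the sequence start
  lapply(0:2, function(f) .translateRaw(substr(dna, 1L + f, nchar(dna))))
}

.translateFramesEnd <- function(dna) {
  # three frames anchored at the sequence END (codons flush with the final
  # base), so that a join at that end preserves the reading frame of a gene
  # whose codon boundary falls at the junction
  lapply(0:2, function(f) {
    len <- nchar(dna) - f
    start <- len %% 3L + 1L
    if (len - start + 1L < 3L) return("")
    .translateRaw(substr(dna, start, nchar(dna) - f))
  })
}

#' Build attLR and attB peptides for one element
#'
#' A 998-bp window is taken centered at the left element coordinate and
#' likewise at the right; all six reading frames of each give the 12 attLR
#' peptides. The uninterrupted-site (attB) peptides join the chromosomal
#' halves of attL and attR in all nine positive-frame and nine
#' negative-frame combinations (18 peptides); when the reference
#' direct-repeat sequence is available it is inserted at the join so that
#' the reconstruction carries the true attB including one repeat copy.
#'
#' @param repliconSeq Query replicon sequence (character).
#' @param left,right Element termini.
#' @param drSeq Direct-repeat sequence from an uninterrupted reference
#'   (optional; `""` joins the chromosomal halves directly).
#' @param half Half-window size (default 499 bp; windows truncate at
#'   replicon ends, flagged in the `truncated` attribute).
#' @return data.frame with `group` (`attLR`/`attB`), `site`, `strand`,
#'   `frame`, `peptide`, `center` (crossover residue index).
#' @export
buildAttPeptides <- function(repliconSeq, left, right, drSeq = "",
                             half = 499L) {
  n <- nchar(repliconSeq)
  acc <- new.env(parent = emptyenv())
  acc$group <- acc$site <- acc$strand <- character(0)
  acc$frame <- acc$center <- integer(0)
  acc$peptide <- character(0)
  push <- function(group, site, strand, frame, peptide, center) {
    acc$group <- c(acc$group, group); acc$site <- c(acc$site, site)
    acc$strand <- c(acc$strand, strand); acc$frame <- c(acc$frame, frame)
    acc$peptide <- c(acc$peptide, peptide)
    acc$center <- c(acc$center, as.integer(center))
  }
  truncated <- FALSE
  window <- function(center) {
    a <- center - half; b <- center + half - 1L
    a0 <- max(1L, a); b0 <- min(n, b)
    if (a0 != a || b0 != b) truncated <<- TRUE
    list(seq = substr(repliconSeq, a0, b0), centerBase = center - a0 + 1L)
  }
  addSix <- function(w, site) {
    for (str in c("+", "-")) {
      dna <- if (str == "+") w$seq else .revComp(w$seq)
      cb <- if (str == "+") w$centerBase else nchar(w$seq) - w$centerBase + 1L
      peps <- .translateFrames(dna)
      for (f in 0:2) {
        pep <- peps[[f + 1L]]
        if (!nzchar(pep)) next
        center <- max(1L, min(nchar(pep), (cb - 1L - f) %/% 3L + 1L))
        push("attLR", site, str, f, pep, center)
      }
    }
  }
  addSix(window(left), "attL")
  addSix(window(right + 1L), "attR")
  chromL <- substr(repliconSeq, max(1L, left - half), left - 1L)
  chromR <- substr(repliconSeq, right + 1L, min(n, right + half))
  joinHalves <- function(dnaA, dnaB, str) {
    pepsA <- .translateFramesEnd(dnaA)   # codons flush with the junction
    pepsB <- .translateFrames(dnaB)
    for (i in 0:2) for (j in 0:2) {
      pa <- pepsA[[i + 1L]]; pb <- pepsB[[j + 1L]]
      if (!nzchar(pa) && !nzchar(pb)) next
      push("attB", "attB", str, i * 3L + j, paste0(pa, pb),
           max(1L, nchar(pa)))
    }
  }
  joinHalves(chromL, paste0(drSeq, chromR), "+")
  joinHalves(.revComp(chromR), .revComp(paste0(chromL, drSeq)), "-")
  out <- data.frame(group = acc$group, site = acc$site, strand = acc$strand,
                    frame = acc$frame, peptide = acc$peptide,
                    center = acc$center, stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  out
}

#' Fixture HMM scorer keyed by planted domain peptides
#'
#' Returns a scorer conforming to the HMM-scorer contract
#' (`function(peptides) -> data.frame(peptide_idx, pfam, bitscore,
#' env_start, env_end)`). A peptide scores against a registered domain by
#' its longest exact shared substring: bitscore is the domain's full score
#' scaled by the matched fraction, so a domain split at a crossover scores
#' about half from either side and full from an intact reconstruction.
#'
#' @param domains List of `list(pfam, peptide, fullScore)` as produced under
#'   `domains` by [generateFixture()].
#' @param k Seed length in residues (default 6).
#' @return A scorer function.
#' @export
stubHmmScorer <- function(domains, k = 6L) {
  dks <- lapply(domains, function(dm) .kmers(dm$peptide, k))
  function(peptides) {
    pidx <- integer(0); pfam <- character(0); score <- numeric(0)
    envS <- integer(0); envE <- integer(0)
    for (pi in seq_along(peptides)) {
      pep <- peptides[[pi]]
      if (nchar(pep) < k) next
      pk <- .kmers(pep, k)
      for (di in seq_along(domains)) {
        dk <- dks[[di]]
        idx <- which(pk %in% dk)
        if (!length(idx)) next
        dpos <- match(pk[idx], dk)
        dg <- idx - dpos
        bestLen <- 0L; bestEnv <- NULL
        for (d in unique(dg)) {
          pp <- sort(idx[dg == d])
          runs <- split(pp, cumsum(c(1L, diff(pp) != 1L)))
          for (r in runs) {
            len <- r[length(r)] + k - 1L - r[1L] + 1L
            if (len > bestLen) {
              bestLen <- len
              bestEnv <- c(r[1L], r[length(r)] + k - 1L)
            }
          }
        }
        if (bestLen > 0L) {
          dm <- domains[[di]]
          pidx <- c(pidx, pi); pfam <- c(pfam, dm$pfam)
          score <- c(score, dm$fullScore * bestLen / nchar(dm$peptide))
          envS <- c(envS, bestEnv[1L]); envE <- c(envE, bestEnv[2L])
        }
      }
    }
    data.frame(peptide_idx = pidx, pfam = pfam, bitscore = score,
               env_start = envS, env_end = envE, stringsAsFactors = FALSE)
  }
}

#' External hmmsearch adapter
#'
#' Scores peptides against a profile HMM file with the `hmmsearch`
#' executable, returning the shared scorer record (domain bitscores and
#' envelope coordinates). Requires `hmmsearch` on the PATH and an HMM file.
#'
#' @param hmmFile Path to a (multi-)profile HMM file.
#' @return A scorer function.
#' @export
hmmsearchScorer <- function(hmmFile) {
  function(peptides) {
    if (Sys.which("hmmsearch") == "") stop("hmmsearch not found on PATH")
    fa <- tempfile(fileext = ".fa"); tbl <- tempfile()
    on.exit(unlink(c(fa, tbl)))
    writeLines(unlist(lapply(seq_along(peptides), function(i)
      c(sprintf(">p%d", i), gsub("\\*", "X", peptides[[i]])))), fa)
    system2("hmmsearch", c("--domtblout", tbl, "--noali", "-T", "0",
                           "--domT", "0", hmmFile, fa), stdout = FALSE)
    ln <- readLines(tbl)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln))
      return(data.frame(peptide_idx = integer(0), pfam = character(0),
                        bitscore = numeric(0), env_start = integer(0),
                        env_end = integer(0)))
    fields <- strsplit(trimws(ln), "\\s+")
    do.call(rbind, lapply(fields, function(f)
      data.frame(peptide_idx = as.integer(sub("^p", "", f[1L])),
                 pfam = f[4L], bitscore = as.numeric(f[14L]),
                 env_start = as.integer(f[20L]),
                 env_end = as.integer(f[21L]), stringsAsFactors = FALSE)))
  }
}

#' Domain-disruption assay for one element
#'
#' Scores all attLR and attB peptides, keeps hits spanning the crossover
#' residue at or above the bitscore cutoff, takes the best-scoring domain
#' over all peptides, and compares its top attB and attLR scores: attB
#' "wins" (domain disrupted without restoration) when it scores at least
#' `winRatio`-fold higher.
#'
#' @param peptides data.frame from [buildAttPeptides()].
#' @param scorer HMM scorer function.
#' @param spanCutoff Bitscore cutoff for spanning hits (default 20).
#' @param winRatio attB:attLR ratio for a win (default 1.1).
#' @return List: `outcome` (`no_spanning`, `no_attLR`, `no_attB`,
#'   `attLR_win`, `attB_win`), `bestPfam`, `topAttLR`, `topAttB`,
#'   `crossoverPos` (residue offset of the crossover within the winning
#'   domain envelope).
#' @export
disruptionAssay <- function(peptides, scorer, spanCutoff = 20,
                            winRatio = 1.1) {
  hits <- scorer(peptides$peptide)
  none <- list(outcome = "no_spanning", bestPfam = NA_character_,
               topAttLR = NA_real_, topAttB = NA_real_,
               crossoverPos = NA_integer_)
  if (!nrow(hits)) return(none)
  ctr <- peptides$center[hits$peptide_idx]
  # envelopes touching the crossover within one residue count as spanning
  # (a domain cut exactly at the junction ends on the crossover residue)
  hits <- hits[hits$env_start <= ctr + 1L & hits$env_end >= ctr - 1L &
               hits$bitscore >= spanCutoff, , drop = FALSE]
  if (!nrow(hits)) return(none)
  best <- hits$pfam[which.max(hits$bitscore)]
  hits <- hits[hits$pfam == best, , drop = FALSE]
  grp <- peptides$group[hits$peptide_idx]
  lr <- hits[grp == "attLR", , drop = FALSE]
  ab <- hits[grp == "attB", , drop = FALSE]
  topLR <- if (nrow(lr)) max(lr$bitscore) else NA_real_
  topB <- if (nrow(ab)) max(ab$bitscore) else NA_real_
  if (is.na(topLR) || is.na(topB)) {
    win <- if (is.na(topLR)) ab else lr
    wi <- which.max(win$bitscore)
    return(list(outcome = if (is.na(topLR)) "no_attLR" else "no_attB",
                bestPfam = best, topAttLR = topLR, topAttB = topB,
                crossoverPos = peptides$center[win$peptide_idx[wi]] -
                  win$env_start[wi] + 1L))
  }
  attBwin <- topB >= winRatio * topLR
  win <- if (attBwin) ab else lr
  wi <- which.max(win$bitscore)
  list(outcome = if (attBwin) "attB_win" else "attLR_win", bestPfam = best,
       topAttLR = topLR, topAttB = topB,
       crossoverPos = peptides$center[win$peptide_idx[wi]] -
         win$env_start[wi] + 1L)
}

#' Assay report from outcome counts
#'
#' The reporting arithmetic behind the cohort table: percentages of
#' elements with any spanning hit, and of the four outcome classes as
#' percentages of spanning elements, rounded to two decimals.
#'
#' @param nIges Total elements assayed.
#' @param spanning,noAttLR,noAttB,attLRwin,attBwin Outcome counts.
#' @return data.frame with `row`, `count`, `pct`.
#' @export
assayReport <- function(nIges, spanning, noAttLR, noAttB, attLRwin,
                        attBwin) {
  pct <- function(x, d) if (d > 0) round(100 * x / d, 2) else NA_real_
  data.frame(
    row = c("IGEs", "Spanning (% of IGEs)", "No attLR (% of spanning)",
            "No attB (% of spanning)", "attLR win (% of spanning)",
            "attB win (% of spanning)"),
    count = c(nIges, spanning, noAttLR, noAttB, attLRwin, attBwin),
    pct = c(NA, pct(spanning, nIges), pct(noAttLR, spanning),
            pct(noAttB, spanning), pct(attLRwin, spanning),
            pct(attBwin, spanning)),
    stringsAsFactors = FALSE)
}

#' Run the disruption assay over a cohort with mock controls
#'
#' Assays each (non-t(m)RNA-targeted) element and, as a negative control,
#' `mockK` random same-length segments of the same replicon per element.
#'
#' @param calls Call data.frame.
#' @param genome Source [GenomeRecord-class].
#' @param scorer HMM scorer.
#' @param mockK Mock segments per element (default 5).
#' @param seed RNG seed for mock placement.
#' @param spanCutoff,winRatio Passed to [disruptionAssay()].
#' @return List with `real` and `mock` outcome vectors and `table`
#'   (stacked [assayReport()] for both sets).
#' @export
assayCohort <- function(calls, genome, scorer, mockK = 5L, seed = 1L,
                        spanCutoff = 20, winRatio = 1.1) {
  runSet <- function(cs) {
    vapply(seq_len(nrow(cs)), function(i) {
      repSeq <- as.character(replicons(genome)[[cs$replicon[i]]])
      dr <- cs$dr_seq[i]
      pep <- buildAttPeptides(repSeq, cs$left[i], cs$right[i],
                              drSeq = if (is.na(dr)) "" else dr)
      disruptionAssay(pep, scorer, spanCutoff, winRatio)$outcome
    }, "")
  }
  real <- if (nrow(calls)) runSet(calls) else character(0)
  mocks <- generateMockIges(calls, genome, k = mockK, seed = seed)
  mock <- if (nrow(mocks)) runSet(mocks) else character(0)
  mk <- function(oc) {
    sp <- sum(oc != "no_spanning")
    assayReport(length(oc), sp, sum(oc == "no_attLR"),
                sum(oc == "no_attB"), sum(oc == "attLR_win"),
                sum(oc == "attB_win"))
  }
  tab <- rbind(cbind(set = "real", mk(real)), cbind(set = "mock", mk(mock)))
  list(real = real, mock = mock, table = tab)
}
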