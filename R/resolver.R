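# Tandem-array building and resolution. A terminus is identified with its
# att (direct-repeat) block interval; two termini are the same att site iff
# their blocks are the identical interval. Adjacent tandem units then share
# exactly one att site and overlap only by that block, which conflict
# resolution ignores.

.attKeyL <- function(calls)
  paste(calls$replicon, calls$left, calls$left + calls$dr_len - 1L)
.attKeyR <- function(calls)
  paste(calls$replicon, calls$right - calls$dr_len + 1L, calls$right)

#' Group raw calls into tandem arrays
#'
#' Termini are grouped as far as possible into tandems by the calls that
#' connect them pairwise: transitive closure of att-site sharing (exact
#' block identity after variant merging).
#'
#' @param calls Call data.frame.
#' @return List of tandems; each a list with `sites` (data.frame of
#'   `replicon`, `start`, `end`, sorted) and `calls` (the member rows).
#' @export
buildTandems <- function(calls) {
  if (!nrow(calls)) return(list())
  kL <- .attKeyL(calls); kR <- .attKeyR(calls)
  keys <- unique(c(kL, kR))
  parent <- seq_along(keys)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(calls))) {
    a <- find(match(kL[i], keys)); b <- find(match(kR[i], keys))
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(keys), find, 1L)
  lapply(unique(comp), function(cc) {
    ks <- keys[comp == cc]
    rows <- calls[kL %in% ks | kR %in% ks, , drop = FALSE]
    parts <- do.call(rbind, strsplit(ks, " "))
    sites <- data.frame(replicon = parts[, 1L],
                        start = as.integer(parts[, 2L]),
                        end = as.integer(parts[, 3L]),
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    list(sites = sites, calls = rows)
  })
}

# int gene containment test helper
.unitHasInt <- function(left, right, intStarts, intEnds) {
  any(intStarts >= left & intEnds <= right)
}

#' Resolve one tandem array into element units
#'
#' Partitions the tandem span at internal att sites so that every unit
#' contains at least one integrase gene and respects the size limits. Among
#' valid partitions the one maximizing summed support is chosen (ties broken
#' by minimizing summed false-positive score). Units without a directly
#' matching call are emitted with `inferred = TRUE`.
#'
#' @param tandem One tandem from [buildTandems()].
#' @param intFeatures data.frame with `start`, `end` of integrase genes on
#'   the tandem's replicon.
#' @param sizeLimits Length-2 numeric, element size limits in bp.
#' @return Call data.frame of resolved units (possibly the best-supported
#'   de-overlapped calls, flagged via the `unresolved` attribute, when no
#'   valid partition exists).
#' @export
resolveTandem <- function(tandem, intFeatures,
                          sizeLimits = c(2000L, 200000L)) {
  sites <- tandem$sites
  calls <- tandem$calls
  m <- nrow(sites)
  if (m < 2L) return(calls)
  kL <- .attKeyL(calls); kR <- .attKeyR(calls)
  siteKey <- paste(sites$replicon, sites$start, sites$end)
  unitFor <- function(i, j) {   # unit spanning sites i..j
    left <- sites$start[i]
    right <- sites$end[j]
    matches <- which(kL == siteKey[i] & kR == siteKey[j])
    list(left = left, right = right, i = i, j = j,
         support = if (length(matches)) max(calls$support[matches]) else 0L,
         fp = if (length(matches))
           min(c(calls$fp[matches], Inf), na.rm = TRUE) else NA_real_,
         call = if (length(matches))
           matches[which.max(calls$support[matches])] else NA_integer_)
  }
  valid <- function(u) {
    sz <- u$right - u$left + 1L
    sz >= sizeLimits[1L] && sz <= sizeLimits[2L] &&
      .unitHasInt(u$left, u$right, intFeatures$start, intFeatures$end)
  }
  internal <- if (m > 2L) 2:(m - 1L) else integer(0)
  if (length(internal) > 12L)
    stop("tandem too complex to resolve exhaustively")
  best <- NULL; bestScore <- -Inf; bestFp <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    keep <- c(1L, internal[bitwAnd(mask, 2^(seq_along(internal) - 1L)) > 0L], m)
    units <- lapply(seq_len(length(keep) - 1L), function(t)
      unitFor(keep[t], keep[t + 1L]))
    if (!all(vapply(units, valid, TRUE))) next
    score <- sum(vapply(units, function(u) u$support, 0L))
    fpSum <- sum(vapply(units, function(u)
      if (is.na(u$fp) || !is.finite(u$fp)) 0 else u$fp, 0))
    if (score > bestScore || (score == bestScore && fpSum < bestFp)) {
      best <- units; bestScore <- score; bestFp <- fpSum
    }
  }
  if (is.null(best)) {
    out <- deoverlapCalls(calls)
    attr(out, "unresolved") <- TRUE
    return(out)
  }
  rows <- lapply(best, function(u) {
    if (!is.na(u$call)) {
      r <- calls[u$call, , drop = FALSE]
      r$inferred <- FALSE
      return(r)
    }
    r <- calls[1L, , drop = FALSE]   # template for genome/replicon fields
    r$left <- u$left; r$right <- u$right
    r$dr_len <- sites$end[u$i] - sites$start[u$i] + 1L
    r$seed <- NA_character_; r$side <- NA_character_
    r$support <- 0L; r$refs <- ""
    r$q1m_start <- NA_integer_; r$q1m_end <- NA_integer_
    r$q2m_start <- NA_integer_; r$q2m_end <- NA_integer_
    r$dr_seq <- NA_character_; r$attB_context <- NA_character_
    r$inferred <- TRUE
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# do two calls conflict? overlap is tolerated only when it is exactly the
# shared att block of adjacent tandem units
.conflicts <- function(a, b) {
  if (a$replicon != b$replicon) return(FALSE)
  ov <- min(a$right, b$right) - max(a$left, b$left) + 1L
  if (ov <= 0L) return(FALSE)
  sharedAtt <- .attKeyR(a) == .attKeyL(b) || .attKeyR(b) == .attKeyL(a)
  !(sharedAtt && ov <= max(a$dr_len, b$dr_len))
}

#' Remove overlapping calls
#'
#' For each conflicting pair, the call with the lower support is rejected;
#' on a support tie, the one with the worse (higher) false-positive score;
#' on a full tie, the later one. Repeats to a fixpoint, so the result is
#' overlap-free (adjacent tandem units sharing an att block are not
#' conflicts).
#'
#' @param calls Call data.frame with `support` (and ideally `fp`) columns.
#' @return Overlap-free call data.frame.
#' @export
deoverlapCalls <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  repeat {
    drop <- NULL
    n <- nrow(calls)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!.conflicts(calls[i, ], calls[j, ])) next
        si <- calls$support[i]; sj <- calls$support[j]
        if (si != sj) drop <- if (si < sj) i else j
        else {
          fi <- if (is.na(calls$fp[i])) 0 else calls$fp[i]
          fj <- if (is.na(calls$fp[j])) 0 else calls$fp[j]
          drop <- if (fi > fj) i else j
        }
        break
      }
      if (!is.null(drop)) break
    }
    if (is.null(drop)) return(calls)
    calls <- calls[-drop, , drop = FALSE]
  }
}

# drop calls nested inside another call without sharing an att site
.dropNested <- function(calls) {
  if (nrow(calls) <= 1L) return(calls)
  kL <- .attKeyL(calls); kR <- .attKeyR(calls)
  n <- nrow(calls)
  inner <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || inner[i]) next
    if (calls$replicon[i] == calls$replicon[j] &&
        calls$left[i] >= calls$left[j] && calls$right[i] <= calls$right[j] &&
        !(calls$left[i] == calls$left[j] && calls$right[i] == calls$right[j]) &&
        kL[i] != kL[j] && kR[i] != kR[j] && kL[i] != kR[j] && kR[i] != kL[j])
      inner[i] <- TRUE
  }
  calls[!inner, , drop = FALSE]
}

.intFeaturesOf <- function(genome) {
  f <- geneFeatures(genome)
  f <- f[S4Vectors::mcols(f)$klass %in% c("Y-Int", "S-Int", "S-Core")]
  data.frame(start = GenomicRanges::start(f), end = GenomicRanges::end(f),
             replicon = as.character(GenomicRanges::seqnames(f)),
             stringsAsFactors = FALSE)
}

#' Resolve raw calls into a final element set
#'
#' Runs the full resolution procedure in one of three modes. In `combined`
#' mode the Islander-style termini seed the tandem set first, joined only by
#' mapper calls sharing an att site with them; remaining mapper calls then
#' form their own tandems. All tandems are resolved into units, nested raw
#' configurations are disallowed, seeds failing the support-ratio screen are
#' removed with their dependent calls, calls failing the false-positive
#' cutoff are rejected, and the surviving set is made overlap-free.
#'
#' @param calls Raw mapper call data.frame.
#' @param islanderCalls Optional call data.frame of tRNA-targeted calls from
#'   an Islander-style caller (pseudo-support 1 is assigned when absent).
#' @param mode `"mapper"`, `"islander"` or `"combined"`.
#' @param genome Query [GenomeRecord-class] (for integrase features).
#' @param fpModel Optional [FpModel-class]; when supplied together with
#'   `hkTable`/`fgTable`, units failing the cutoff are rejected.
#' @param hkTable,fgTable Enrichment tables for metric computation.
#' @param sizeLimits Element size limits in bp.
#' @param ratioCutoff,overlapCutoff Passed to [supportRatioFilter()].
#' @return Resolved call data.frame with `inferred` and `doubly` columns.
#' @export
resolveCalls <- function(calls, islanderCalls = NULL,
                         mode = c("mapper", "islander", "combined"),
                         genome = NULL, fpModel = NULL, hkTable = NULL,
                         fgTable = NULL, sizeLimits = c(2000L, 200000L),
                         ratioCutoff = 4, overlapCutoff = 5L) {
  mode <- match.arg(mode)
  ints <- if (!is.null(genome)) .intFeaturesOf(genome) else
    data.frame(start = integer(0), end = integer(0), replicon = character(0))
  prep <- function(d) {
    d <- .asCalls(d)
    d$support[is.na(d$support) | d$support < 1L] <- 1L
    d
  }
  if (!is.null(islanderCalls)) islanderCalls <- prep(islanderCalls)
  calls <- .asCalls(calls)
  # seeds subject to non-integrase recombination go first, with their calls
  bad <- supportRatioFilter(calls, ratioCutoff, overlapCutoff)
  calls <- calls[!(calls$seed %in% bad), , drop = FALSE]
  calls <- .dropNested(calls)
  islKeys <- if (!is.null(islanderCalls) && nrow(islanderCalls))
    unique(c(.attKeyL(islanderCalls), .attKeyR(islanderCalls))) else character(0)

  pool <- switch(mode,
    islander = islanderCalls %||% .emptyCalls(),
    mapper = calls,
    combined = {
      if (!length(islKeys)) calls else {
        joins <- .attKeyL(calls) %in% islKeys | .attKeyR(calls) %in% islKeys
        rbind(islanderCalls, calls[joins, , drop = FALSE],
              calls[!joins, , drop = FALSE])
      }
    })
  if (is.null(pool) || !nrow(pool)) return(.emptyCalls())

  units <- list()
  if (mode == "combined" && length(islKeys)) {
    joins <- .attKeyL(calls) %in% islKeys | .attKeyR(calls) %in% islKeys
    mixed <- rbind(islanderCalls, calls[joins, , drop = FALSE])
    for (t in buildTandems(mixed))
      units[[length(units) + 1L]] <-
        resolveTandem(t, ints[ints$replicon %in% t$sites$replicon, ],
                      sizeLimits)
    rest <- calls[!joins, , drop = FALSE]
    for (t in buildTandems(rest))
      units[[length(units) + 1L]] <-
        resolveTandem(t, ints[ints$replicon %in% t$sites$replicon, ],
                      sizeLimits)
  } else {
    for (t in buildTandems(pool))
      units[[length(units) + 1L]] <-
        resolveTandem(t, ints[ints$replicon %in% t$sites$replicon, ],
                      sizeLimits)
  }
  out <- do.call(rbind, c(list(.emptyCalls()), units))
  if (!nrow(out)) return(out)
  # doubly-confirmed: unit att sites seen in both sources
  out$doubly <- FALSE
  if (length(islKeys) && nrow(calls))
    out$doubly <- (.attKeyL(out) %in% islKeys | .attKeyR(out) %in% islKeys) &
      (.attKeyL(out) %in% c(.attKeyL(calls), .attKeyR(calls)) |
       .attKeyR(out) %in% c(.attKeyL(calls), .attKeyR(calls)))
  # false-positive cutoff
  if (!is.null(fpModel) && !is.null(genome) && !is.null(hkTable)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      v <- tryCatch(metricVector(out[i, ], genome, hkTable, fgTable),
                    error = function(e) NULL)
      if (is.null(v) || anyNA(v)) return(TRUE)
      sc <- fpScore(v, fpModel)
      out$fp[i] <<- sc$score
      sc$pass
    }, TRUE)
    out <- out[keep, , drop = FALSE]
  }
  out <- deoverlapCalls(out)
  rownames(out) <- NULL
  out
}

#' Assign the attB target type of a call
#'
#' The direct-repeat block at the att site is intersected with gene
#' features: overlap with two or more genes gives `multi-gene`; a single
#' gene maps by class to `tRNA`, `tmRNA`, `other-RNA` or `CDS`; no gene
#' gives `intergenic`. Reference-genome annotation is preferred when
#' supplied; otherwise the query annotation at attL is used.
#'
#' @param call One-row call data.frame.
#' @param features Query annotation (`GRanges`).
#' @param refFeatures Optional supporting-reference annotation with
#'   coordinates on the reference attB; must carry a `attB_pos` attribute
#'   giving the reference coordinate matching the call's att block.
#' @return List with `target` (type string) and `targetName`.
#' @export
assignTarget <- function(call, features, refFeatures = NULL) {
  f <- if (!is.null(refFeatures)) refFeatures else features
  if (!length(f)) return(list(target = "intergenic", targetName = NA_character_))
  blockStart <- call$left
  blockEnd <- call$left + max(call$dr_len, 1L) - 1L
  onRep <- as.character(GenomicRanges::seqnames(f)) == call$replicon
  hit <- which(onRep & GenomicRanges::start(f) <= blockEnd &
               GenomicRanges::end(f) >= blockStart)
  if (!length(hit)) return(list(target = "intergenic",
                                targetName = NA_character_))
  if (length(hit) >= 2L) return(list(target = "multi-gene",
                                     targetName = NA_character_))
  kl <- S4Vectors::mcols(f)$klass[hit]
  target <- switch(kl, tRNA = "tRNA", tmRNA = "tmRNA",
                   rRNA = "other-RNA", `other-RNA` = "other-RNA", "CDS")
  nm <- S4Vectors::mcols(f)$targetName[hit]
  list(target = target,
       targetName = if (is.null(nm) || is.na(nm)) NA_character_ else nm)
}

#' Name an element
#'
#' Nomenclature `GenomeID.Size.Target`: size in kb, rounded; target from the
#' target gene name when known (e.g. the tRNA isotype), else an abbreviation
#' of the target type.
#'
#' @param call One-row call data.frame (`genome_id`, `left`, `right`).
#' @param target Target type string (as from [assignTarget()]).
#' @param targetName Optional target gene name.
#' @return Character name, e.g. `"Xor4.60.Arg"`.
#' @export
nameIge <- function(call, target = call$target, targetName = NULL) {
  kb <- round((call$right - call$left + 1) / 1000)
  tgt <- if (!is.null(targetName) && !is.na(targetName)) targetName
         else switch(target %||% "Unknown", tRNA = "tRNA", tmRNA = "tmRNA",
                     `other-RNA` = "RNA", CDS = "CDS",
                     `multi-gene` = "multi", intergenic = "IG", "X")
  sprintf("%s.%d.%s", call$genome_id, kb, tgt)
}

#' Finish resolved calls: target assignment and naming
#'
#' @param calls Resolved call data.frame.
#' @param genome Query [GenomeRecord-class].
#' @return Calls with `target` and `name` columns filled.
#' @export
finishCalls <- function(calls, genome) {
  if (!nrow(calls)) return(calls)
  feats <- geneFeatures(genome)
  for (i in seq_len(nrow(calls))) {
    tg <- assignTarget(calls[i, ], feats)
    calls$target[i] <- tg$target
    calls$name[i] <- nameIge(calls[i, ], tg$target, tg$targetName)
  }
  calls
}
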