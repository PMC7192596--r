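---
title: "Mapping integrative genetic elements by two-phase comparative alignment"
author: "IGEmapper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping integrative genetic elements by two-phase comparative alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IGEmapper)
```

## The problem

Integrative genetic elements (IGEs) — prophages, integrative and conjugative
elements (ICEs), and their degraded or satellite relatives — are mobile
multigene DNA units that integrate into a host attachment site (*attB*) via a
tyrosine- or serine-family integrase, leaving the element flanked by two
recombinant sites, *attL* and *attR*, that share a direct-repeat (DR) block.
Composition- and gene-content-based island finders cannot place element
termini at base precision, and tRNA-anchored methods only find the large
t(m)RNA-targeted subclass. Precise, unbiased termini are the prerequisite for
two downstream analyses this package targets: surveys of integrase site
specificity (and its breakdown, site promiscuity), and detection of
*regulated gene integrity* (RGI) — genes switched off by element integration
and back on by excision.

## The mapping model

Two observations drive the mapper. First, the integration module is
cohesive: the integrase gene (*int*) sits close to one element end, next to
the *attP* site it acts on. Second, elements occur sporadically among
related genomes, so some reference genome usually carries the
*uninterrupted* site.

From each integrase gene midpoint, two 15-kb flank queries are taken (`q1L`
ending just left of the midpoint, `q1R` starting just right; they wrap the
origin on circular replicons). Each probes the reference collection.
A reference that carries the same element matches a flank query end to end;
such matches are discarded (within a 10-bp slop, `reachTol`). A reference
with the uninterrupted site instead yields a match that truncates exactly at
the junction between shared chromosome and element. Matches must exceed
500 bp, and the best retained match per reference is the one truncating
closest to the seed.

For each retained phase-I match a 3-kb return query is taken from the
reference, adjacent to the junction and reaching 250 bp back into the
matched region so that it carries the DR block (30 bp in IS mode, where the
repeat is a short target-site duplication). Aligned back to the source
replicon, the return query produces two segments: a proximal one re-finding
the phase-I junction and a distal one landing beyond the element. Their
overlap in return-query coordinates is the DR length; the proximal segment's
end and the distal segment's start, adjusted by that overlap, are the two
element termini (outer edges of the two DR copies). When the two segments
abut with a small unmatched gap instead of overlapping (up to `gapTol`,
20 bp — e.g. a diverged att core), the junction is called with a zero-length
repeat. Among multiple plausible distal segments the smallest element within
the 2–200-kb size limits (5–15 kb in IS mode) that still contains the seed
is chosen, and the call is flagged ambiguous.

Each supporting reference contributes one candidate call; calls whose
termini fluctuate by at most 20 bp (`mergeWindow`) merge onto the
best-supported member, summing distinct supporting references, and identical
calls arising from both flanks collapse without double-counting. The
element's *support* is the number of distinct uninterrupted reference
genomes behind the merged call.

### The insertion-sequence artifact

If an IS sits next to the seed integrase and has transposed elsewhere in a
reference, a flank query can match only the IS, and the return query then
fixes a terminus at the IS's reference locus — a spurious element spanning
tens of kilobases. Calls are therefore screened: if a DDE transposase gene
lies inside the phase-I (or phase-II) match region on the query, the mapper
re-runs in IS mode seeded at that transposase; an IS call containing the
whole match region rejects the element call. Failing that, the match region
is searched against an IS sequence database and rejected when a single IS
record covers essentially the whole region (95%; partial coverage is not
grounds for rejection).

## False-positive scoring

Seven per-call metrics feed a trainable score: G+C bias against the
replicon; dinucleotide bias, the mean absolute difference of the sixteen
dinucleotide relative abundances computed on sequence plus reverse
complement (the genomic-signature convention); housekeeping and foreignness,
mean Pfam enrichment-factor differences between element genes and replicon
genes, with enrichment factors being count ratios between a positive gene
set and all genes; the hypothetical-gene fraction difference; length in bp;
and delta-int, the shortest distance from an internal integrase to a
terminus, set to 1 for integrases overhanging a terminus and floored at 1
elsewhere so log-scaled modelling stays safe.

Training standardizes the metrics, projects onto principal components, and
draws a convex hull around mapper-confirmed calls in the PC1–PC3 plane
(these components spread the calls more than PC1–PC2; the plane is
configurable). Hull membership labels all calls, and a logistic-link linear
model on the raw metrics is fitted to a random 75% and evaluated by AUROC on
the held-out 25%. The score is oriented so that higher means more likely
false; the pass cutoff maximizes Youden's J on the training split. We fit
the GLM on raw (unstandardized) metrics and standardize only before PCA;
both choices are exposed rather than hard-wired.

A second, independent screen rejects whole seeds: when a seed accumulates
many overlapping raw calls whose top and second-best support values are
close, the signal likely reflects recombination by some other agent (the
classic case is integron cassette shuffling around a superintegron). The
default boundary rejects seeds with at least 5 overlapping calls and a
top:second ratio below 4; both knobs are configurable because the original
boundary was read off data discontinuities rather than printed as a rule.

## Tandem arrays and resolution

Sequential integrations at a restored site produce tandem arrays whose
members share att sites. We identify a terminus with its DR block interval;
two termini are the same att site exactly when their blocks are the same
interval. This makes adjacent tandem units share one att site while
overlapping only by that block — which conflict resolution deliberately
ignores — and keeps the published span convention (both DR copies inside
the element). Tandems are the transitive closure of att-site sharing; each
is resolved by choosing, among all partitions at internal att sites whose
units each contain an integrase and obey the size limits, the partition
maximizing summed support (ties to minimal summed false-positive score).
Units without a directly supporting call are emitted as inferred.
Remaining conflicts resolve by support, then by false-positive score;
element-within-element raw configurations (no shared att site) drop the
inner call. Resolution runs in mapper-only, Islander-only (tRNA-anchored
calls, assigned pseudo-support 1) or combined mode, where Islander termini
seed the tandem set first and mapper calls sharing an att site join them.
Seed-level rejection is applied before tandem building and the
false-positive cutoff to resolved units, in that order. Calls are named
`GenomeID.Size.Target` with size in rounded kb.

## Deduplication and subtyping

Vertically inherited near-copies are collapsed before clade-level analyses:
fragment ANI (500-bp fragments, at least 2 mapped, mapping admission 80%
identity over 60% of the fragment) in both directions, an edge when either
direction exceeds ANI 0.95 and aligned fraction 0.9, unit-weight shortest
paths, and density clustering with radius 1 and minimum 2 — provably
connected components on such a graph, which the test suite asserts against
a union-find oracle. Representatives are chosen by support, then score,
then id.

Subtyping uses curated phage HMM lists split into virion and non-virion
categories and an ICE-protein HMM list: `Phage1` requires one hit from each
phage category, `Phage2` any phage hit, `ICE1` at least 7 ICE hits covering
15% of proteins, `ICE2` at least 2 hits covering 12% (<10 kb) or 7%
(≥10 kb). Double calls resolve as: `Phage1` with ICE becomes `ICE+Phage`;
`Phage2` with ICE becomes `ICE`. Raw fractions divided by the control
recalls (0.982 phage, 0.752 ICE) give the corrected composition.

## The domain-disruption assay

To call gene inactivation *without restoration*, a 998-bp window is taken
centered at each terminus and translated in six frames (12 attLR peptides).
The uninterrupted site is reconstructed by joining the chromosomal halves of
attL and attR in all nine frame pairs per strand (18 attB peptides); the
left half is translated with codons flush against the junction so a gene
whose codon boundary falls there is rejoined in frame, and when the
reference DR sequence is available it is inserted at the join so the
reconstruction carries the true attB with one repeat copy. Hits must exceed
20 bits and span the crossover residue (envelopes touching it within one
residue count — a domain cut exactly at the junction ends on that residue).
For the best domain anywhere among the 30 peptides, the top attB score is
compared with the top attLR score: attB "wins" — the domain is disrupted and
not restored — at a ratio of at least 1.1. Stop codons are kept as `*` and
break envelopes naturally. Mock elements (five random same-length segments
per element, drawn from the same replicon and kept clear of real element
spans as a cleaner negative control) calibrate the false attB-win rate.

RGI candidates are tight (mean pairwise patristic depth ≤ 0.5
substitutions/site by default), high-support (≥50%) integrase clades with at
least two deduplicated members, all attB-winning on the same domain at
crossover positions within 10 residues. Promiscuity screening flags
high-support clades of more than four members (four or fewer cannot fall
below 25% purity) with site purity below 25% and depth at most that of the
large promiscuous IS607 clade; the published figure's triangle geometry is
not specified numerically, so the default boundary is the rectangle with an
optional linear hypotenuse. A single profile score with a 64-bit cutoff
reproduces IS607 membership.

## Synthetic fixtures and the internal engine

The generator plants elements with duplicated DR blocks, an integrase near
the left end (delta-int realism), optional restoring fragments,
domain-bearing target genes, tandem arrays, and transposed-IS scenarios,
with clean, same-element and member-subset references and an i.i.d.
substitution model (no indels) for reference divergence. Where two unrelated
sequences abut at a planted junction, chance identity of the first bases
would genuinely lengthen the repeat and make the truth table ambiguous, so
each planted segment begins and ends with a four-base homopolymer tag chosen
so any two sequences meeting at a junction disagree at all four positions;
this is a property of the generator's truth definition, not of the mapper.
Fixtures used for exact-recovery checks are mutation-free; domain-assay
fixtures skip the tags (they would overwrite target-gene codons) and are not
used for exact mapping.

The internal alignment engine seeds on exact 16-mers (numerically encoded),
extends ungapped along diagonals with +1/−3 scoring, and reports all
maximal-scoring segments above 22 (≥25 bp, ≥75% identity). It handles
substitutions but not indels — sufficient for the fixture regime and fast
enough to keep a 50-fixture end-to-end recovery run around a minute on one
CPU. For real genomes the BLASTN adapter (`blastnEngine()`) plugs into the
same interface, and the test suite asserts that both engines produce
identical calls on exact-flank fixtures. The default problem sizes used by
the test suite and the acceptance script — 36–60-kb replicons, 5–12-kb
elements, 1–3 references, 500 mock segments, 4000 synthetic metric vectors
with a 3.5-sigma planted separation — were chosen as the smallest sizes at
which every behaviour of interest (both flanks, tandem sharing, support
counting, stable GLM coefficients) is exercised.

```{r example}
fx <- generateFixture(fixtureSpec(), seed = 7)
fx$truth[, c("left", "right", "dr_len", "target")]
calls <- mapGenome(fx$query, fx$refs)
calls[, c("left", "right", "dr_len", "support", "side")]
```

## What passing fixtures does and does not show

The fixtures emulate insertion/deletion relationships, repeat-mediated
junctions, tandem sharing, IS transposition and domain splitting — the
geometric core of the method. They do not emulate phylogenetic correlation
among references, indels, assembly error, repeat families beyond the planted
IS, or the composition signal that the gene-content metrics exploit in real
genomes (fixture DNA is i.i.d. random). Exact recovery on fixtures therefore
validates the coordinate logic and filters, not the survey-scale behaviour
of the false-positive formula, whose published coefficients are in any case
not reproduced here (the training pipeline is; its inputs are synthetic).

## Numerical choices and degenerate inputs

Coordinates are 1-based inclusive throughout; origin-spanning queries wrap
on circular replicons, and features may internally extend past the origin.
Replicons under 2 kb skip their seeds with a warning. Ties among equally
supported tandem partitions break toward lower summed false-positive score;
ambiguous distal segments toward the smallest in-limits element. All-N
windows translate to `X` runs and score nothing. Zero mononucleotide
frequencies skip the affected signature terms with a warning. Elements with
no Pfam-called gene have their two content metrics imputed as 0 and flagged.
Gathering cutoffs are used per HMM when supplied, else a global 20-bit
floor. Multi-domain proteins with both tyrosine- and serine-family hits are
classed by the better bitscore and flagged. Whether phase-I matches should
also be filtered by identity (beyond length) is unstated in the method's
description; we filter by length only. Cross-replicon (split-scaffold)
elements and phage-Mu-type transposase seeds are out of scope.
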