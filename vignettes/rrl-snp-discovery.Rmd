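---
title: "SNP discovery from reduced representation libraries: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP discovery from reduced representation libraries: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlsnp)
```

## The method in one paragraph

A reduced representation library (RRL) samples a genome reproducibly: a
cocktail of blunt-end restriction enzymes cuts wherever its recognition
sites occur, and only the 100–150 bp digestion products are sequenced.
Because cutting is sequence-determined, a divergent accession yields
essentially the same fragment set as the reference genotype, so deep
33 bp tag sequencing of the accession can be aligned to the reference
assembly and mismatches called as SNPs. Discovered SNPs then serve as
genetic markers: genotyped on an F5-derived recombinant-inbred-line (RIL)
population they produce a high-resolution linkage map, and the map in
turn anchors assembly scaffolds to linkage groups and orients those whose
markers span enough recombination. `rrlsnp` implements this chain
end-to-end with a seeded simulator in place of the wet lab, so every rule
is testable against planted truth.

## The digest model

Digestion is simulated as *complete*: every occurrence of every
recognition site, on either strand, is cut (the real library was digested
overnight, and size selection — not partial digestion — dominates library
content). Sites are IUPAC patterns; MslI's `CAYNN^NNRTG` is the reason a
plain string search does not suffice. Two deliberate rules:

* **Assembly gaps never match.** A genomic `N` satisfies no IUPAC code,
  not even pattern `N`. Consequently no cut, alignment seed, or flank
  window can sit inside a gap. This mirrors the exclusion of N-containing
  regions throughout the published filter protocols.
* **Banding.** The enzyme cocktail was chosen for the "least banding" in
  the size window, a criterion the protocol states only qualitatively. We
  formalise a *band* as a distinct in-window fragment sequence with copy
  number at least `band_copy_threshold` (default 10): a single-copy
  fragment contributes too little DNA to show on a gel, while a high-copy
  repeat fragment concentrates mass at one apparent size. The threshold is
  a configuration knob, not an estimate of gel physics.

## The read simulator

The simulator is the package's definition of the study conditions, not a
tuning surface:

| parameter | default | meaning |
|---|---|---|
| `snp_rate` | 1/425 per bp | accession divergence (θ ≈ 0.00235) |
| `read_len` | 33 bp | tag length |
| `depth_target` | 10 | mean fold-coverage of sequenced fragment bases |
| `error_rate` | 0.002 per base | independent miscall probability |
| `organelle_fraction` | 0.05 | proportion of reads from organelle sequence |
| `read_start` | `"end"` | reads start at fragment ends |

Reads are drawn from fragment *ends* by default (both ends, both
strands): short-insert libraries sequence fragment ends, and end-sampling
is what makes the same loci recur across genotypes. A uniform-offset mode
exists because the real library's read-start distribution is not
published; both are assumptions and both are exercised by the tests.
Only substitutions are simulated — the downstream callers operate on
strictly ungapped 33-mer alignments, so indels would only create unmapped
reads, not miscalls. Per-base qualities are derived from the error
probability actually used (`q = round(−10·log₁₀ p)`, capped at 40, the
cap of the tag platform's quality scale), so the quality string is
truthful by construction; a linear 3′-decay profile is available. What
the simulator does **not** emulate: position- and cycle-dependent Illumina
error profiles, PCR duplicates, paired ends, partial digestion, and
segregation-distortion biology. Passing tests therefore demonstrate the
*logic* of the pipeline, not its performance on real flow-cell data.

## Occurrence screening

33-mers are counted exactly as sequenced (strand-literal, no
canonicalisation), which is why the occurrence summary's totals equal the
raw read count and every row obeys `bases = 33 × reads`. Tags observed
**300 or more** times are excluded as repetitive or organellar. Ordering
is deliberate: occurrence filtering first, then the organelle screen —
the published account does not fix the order, and this one removes the
bulk (high-copy tags) before the more expensive alignment screen.
"Matches the chloroplast/mitochondrion" is formalised as an ungapped
full-length alignment with at most one mismatch on either strand; the
protocol states no threshold, and one mismatch tolerates a sequencing
error in an otherwise organellar read.

## The aligner and its completeness argument

Reads are placed by seed-and-verify: an 11-mer exact-match index, then
full-length ungapped verification. Correctness: partition a 33 bp query
into `max_mismatch + 1` contiguous blocks; a placement with at most
`max_mismatch` mismatches leaves some block mismatch-free (pigeonhole),
and that block's leading 11-mer is then an exact, indexed seed. At the
default one mismatch the two blocks are 16 and 17 bp, each at least
11 bp, so enumeration is complete — a property the tests verify against
an exhaustive independent matcher. `N` never matches anything, which is
also why unindexed N-containing seeds cannot break completeness: a
mismatch-free block cannot contain one.

The mapping score is this package's replacement for an external aligner's
mapping quality (whose model the published protocol does not define): 37
for a uniquely placed read with no competing placement, minus 10 per
suboptimal competitor (capped), 0 for multiple or unmapped. It is
deterministic and monotone in placement competition, so the published
"mapping score ≥ 30" rule passes exactly the reads with an uncontested
placement, which is that rule's intent.

## Consensus and the filter cascades

The consensus base of a pileup column is the quality-weighted modal base;
its quality is the quality-sum margin over all discordant observations,
floored at 0 and capped at 60. This capped margin stands in for a
Bayesian consensus quality: it is monotone in support and opposition,
which is all the thresholds require. A quality tie yields `N`, which the
ambiguity rule then removes — ties carry no directional evidence.

Four cascades are implemented. GMAP-style: discard reads carrying any
base under quality 10; require unique placement; require all supporting
alignments to agree on one substituted base; eliminate SNPs whose *both*
immediate 25-mer flanks match another genome location with ≤ 2
mismatches; require ≥ 2 supporting reads; forbid `N` in the emitted
context. Maq-style (VMS / VSS / PRODUCTION): eliminate any two candidates
within a 25-base window (read as pairwise distance < 25; positions 100
and 124 go, 100 and 125 stay — the boundary is unit-tested); eliminate
ambiguous consensus; consensus quality ≥ 20 (27 for PRODUCTION);
average read-copy exactly 1.00; mapping score ≥ 30 on every supporting
read; ≥ 2 reads for VMS only; and the flank rules below. Every decision
is recorded in a per-candidate, per-rule ledger so a filtered candidate
can always be explained.

**Flank repetitiveness.** For VMS/VSS the 121 nt centred region must be
N-free and the two *single* 25-mers flanking the SNP are scanned against
the whole genome (ungapped, both strands, ≤ 2 mismatches, the window's
own locus excluded): both repetitive excludes. For PRODUCTION the centred
region is 601 nt and *every* 25-mer window across the 300 nt upstream and
downstream regions is scanned; a window is repetitive at five or more
other hits, and a pooled repetitive fraction above 1/3 excludes. Two open
points were settled as follows: the published results section mentions a
120-base flanking read of this rule while the protocol section specifies
300 nt — the 300 nt protocol is the default, with `flank_len = 120`
available so both readings are runnable; and whether the 1/3 fraction
pools both flanks or is evaluated per flank is unstated — pooled is
implemented. Where the original GMAP run consulted an external aligner's
repeat column, this pipeline substitutes its own repeat evidence: the
occurrence-300 screen upstream plus the flank scans here.

## RIL simulation and two-point mapping

Lines are advanced from a fully heterozygous F1 by single-seed descent —
one selfed offspring per generation, the plant-to-row protocol — with
crossovers placed independently in each adjacent-marker interval at the
Kosambi inverse of the interval's map distance. Expected heterozygosity
at F5 is (1/2)⁴ = 6.25 %, matching the 6.3 % observed in the real
population; lines above 20 % heterozygosity are excluded as outcrosses
(strictly above: a line at exactly 20 % stays).

One estimator choice deserves emphasis. Among inbred lines, recombinants
*accumulate* over the selfing generations: the observed recombinant
fraction between two markers overstates the per-meiosis `r` (approaching
`2r/(1+2r)` at fixation). Mapping software used for the real population
corrects for this; `recombination_fraction()` does too, by inverting the
exact two-locus selfing recurrence (after Haldane and Waddington) for the
stated generation, then converting with Kosambi. Without the correction a
true 10 cM interval would be reported near 17 cM. LOD is the base-10
binomial likelihood ratio at the observed fraction versus free
recombination; linkage requires LOD ≥ 10 and ≤ 50 cM. Multipoint marker
ordering is deliberately not reproduced — marker order is taken from the
simulated truth (or physical order), and two-point statistics are the
linkage test.

## Anchoring and orientation

A scaffold with any mapped marker is anchored; with markers spanning at
least 1 cM (inclusive) it is oriented. The published account orients "by
marker separation" without defining an estimator; we use the sign of the
Spearman rank correlation between physical and genetic positions, which
tolerates a noisy marker better than comparing only the two extremes and
degrades to "unknown" on a tie. Markers of one scaffold mapping to
different linkage groups produce a `conflict` status rather than being
dropped — exactly the signal the real map provided for evaluating
scaffold integrity.

## Numerical and scale choices

Internally all coordinates are 0-based half-open; every user-facing
artefact (VCF, TSVs) is 1-based. All stochastic stages take explicit
seeds, derived in the pipeline from one master seed, and reruns are
byte-identical. Problem sizes in the tests and demo — 10–60 kb genomes,
hundreds to thousands of reads, 100–10,000 RIL lines — were chosen so
the full suite exercises every rule (including the brute-force
equivalence oracles) in well under a minute per file; they are the
package's own testing scale, far below the ~1 Gb genome and 8.7 M reads
of the real study. The demo's genetic-to-physical scale
(`ril_cm_per_kb = 0.5`) is likewise a demonstration convenience: real
maps are orders of magnitude denser in bp per cM, and the parameter only
affects the demo's marker map, never an inference.

## Known limitations

Only substitutions are called (no indels, no genotype likelihoods); the
aligner is strictly ungapped by design. The consensus quality and the
mapping score are this package's own deterministic constructions and are
not numerically comparable to external callers' Bayesian scores — only
the threshold *behaviour* of the cascades is reproduced. The banding
criterion and the organelle-match threshold formalise qualitative
statements. The RIL simulator models ideal selfing; observed residual
heterozygosity in a real population can also reflect outcrossing, which
is exactly what the QC filter is for.
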