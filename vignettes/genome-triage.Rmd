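---
title: "Coverage, homology and mitogenome triage of dikaryotic assemblies"
author: "dikaryotriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage, homology and mitogenome triage of dikaryotic assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A dikaryotic fungal mycelium carries two distinct haploid nuclei per cell,
so whole-genome sequencing of untreated mycelium yields data with diploid
character. Assemblers handle the two haplotypes unevenly: where they
diverge enough, each haplotype assembles into its own contig and each
receives roughly the unique (1×) share of reads; where they are identical
or nearly so, both collapse into a single contig that attracts about twice
the reads. The mitochondrial chromosome — strongly AT-rich in
basidiomycetes and present in many copies per cell — and rDNA-like repeats
sit far above both, while contaminant sequence sits below. `dikaryotriage`
exploits these coverage and homology signatures for assembly QC, ploidy
diagnosis, and mitogenome recovery, with a ground-truthed synthetic
generator so every claim is testable.

## Coverage model

The per-contig signal is the **read count** (the y-axis of a contig-length
versus read-count plot), not per-base depth. Under uniform sequencing, a
contig of length $L$ present at copy number $c$ receives approximately
Poisson-distributed reads with mean

$$\lambda = c \cdot L \cdot d / r,$$

where $d$ is the unique-coverage depth (reads per base) and $r$ the read
length. The density $\text{read\_count}/L$ of a single-copy contig
estimates $d/r$.

**Baseline estimator.** The 1× baseline is the *length-weighted lower
median* of density over contigs of at least `min_len` (default 10 kb)
bases. The rationale: organelle and repeat contigs dominate read counts
but not assembly length, and collapsed-haplotype contigs at 2× stay on the
upper side of the median as long as they carry less than half of the
qualifying length. The estimator is deliberately simple and scale-free:
multiplying all counts by a constant rescales the baseline and leaves
every group label unchanged. It has a knife-edge: if unique sequence
carries less than half of the qualifying assembly length (an extreme
collapse scenario), the median can tip into the 2× block. The triage
output always reports the baseline actually used.

**Groups.** Coverage multiples $m = \text{density}/\text{baseline}$ are
binned left-closed, right-open so every contig receives exactly one label:

| group | multiple | interpretation |
|---|---|---|
| I | $m < 0.5$ | low-coverage, usually contamination |
| II | $0.5 \le m < 1.5$ | divergent allelic contigs |
| III | $1.5 \le m < 3$ | collapsed (near-identical) haplotypes |
| IV | $3 \le m < 50$ | over-represented organelle |
| V | $m \ge 50$ | rDNA-like high-copy repeat |

Group I contigs are labelled, never filtered: their origin is a judgement
call for the analyst. Multiples are rounded to nine decimals before
binning so that floating-point division noise cannot push an exactly
boundary multiple (say, 1.5×) across its left-closed edge.

**Diploid call.** The paper-style reasoning is qualitative; the packaged
rule is an explicit, configurable heuristic: diploid character is called
when groups II + III carry at least 80 % of the assembly length *and*
either group III carries at least 5 % or the single-copy-marker
duplication fraction (an independent diagnostic, see below) reaches 0.3.

## Anchored banded alignment

All identity estimates flow through one global affine-gap aligner with a
fixed scoring scheme: match $+1$, mismatch $-1$, gap open $-2$ (charged on
the first gap column), gap extend $-1$, i.e. a gap of length $g$ costs
$-(g+1)$. The scheme is not tuned — the summary statistics, not the score,
are the contract — but it is fixed and documented so results are
reproducible.

Long near-identical inputs are made tractable by anchoring: shared k-mers
(k = 21) that are unique within each sequence are chained to a longest
strictly co-linear chain, and the dynamic programme runs inside a corridor
whose per-row column bounds are linearly interpolated through the chain
with a half-width of 150 bases. When the chain covers less than half of
the shorter sequence the corridor is unreliable; inputs up to 5 kb then
fall back to the unrestricted programme and longer inputs raise an
alignment-infeasible error rather than returning a doubtful answer. The
corridor and the unrestricted reference implementation share scoring and
tie-break conventions (candidate states examined in the order M, gap-in-b,
gap-in-a; a later candidate wins only with a strictly greater score), so
whenever the optimal path lies inside the corridor the two produce
identical column traces — a property the test suite checks across 500
random mutation settings on inputs up to 2 kb.

**Summary conventions.** An alignment summary partitions columns exactly
into identical, mismatch and gap columns; a gap column counts once
regardless of which sequence carries the gap, and a run of $g$ gap columns
contributes $g$. Identity is

$$\text{identity} = \lfloor 10^4 \cdot \text{identical} / \text{columns} \rfloor / 100,$$

**truncated**, not rounded, to two decimals — computed with exact integer
floor division. Truncation is deliberate: it is the only rule under which
a printed triple (identical positions, alignment length, identity
percentage) stays self-consistent for values such as 40,259 / 40,405 →
99.63 %, where rounding would print 99.64 %.

## Allelic contig pairs

Every unordered contig pair is scanned once for homologous blocks:
unique–unique shared 21-mers are chained, the chain is split where
consecutive anchors lie more than `max_gap` (default 2 kb) apart in either
sequence, and segments spanning at least `min_block` (default 1 kb — the
conventional lower bound for calling two contigs allelic) in both
sequences are verified by corridor alignment. The 1-kb span threshold is
the only block criterion inherited from practice; no identity floor is
imposed by default, and the reported `identity_pct` lets the analyst apply
one (the anchoring regime itself effectively restricts hits to roughly
≥ 90 % identity).

Strand handling defaults to forward-only: allelic contigs from one
assembler run are usually co-oriented. `both_strands = TRUE` additionally
scans the reverse complement and reports such blocks with orientation
`"-"` and coordinates mapped back to the forward strand. All coordinates
are 0-based half-open.

**Divergence profiles** bin differences along the block alignment into
windows of alignment columns (default 1 kb, minimum 100). Mismatch columns
count one each; each gap run counts once at its opening column, so indel
length does not dominate the hotspot signal. Uniform divergence produces
Poisson-dispersed window counts; planted or real hotspots stand out as
over-dispersion.

## Mitogenome identification, bisection and comparison

Candidacy requires both of two criteria: GC content at least 10 percentage
points away from the length-weighted median assembly GC (a 27 % mitogenome
against a 49 % nuclear genome clears this with wide margin), and coverage
group IV. With no coverage classification available only the GC criterion
applies and the result is flagged provisional.

A tandem-duplicated mitogenome contig — two consecutive near-identical
units assembled as one linear contig — is detected from its k-mer
self-match offsets: k-mers occurring exactly twice vote for their offset;
a dominant offset band (width 200 bases, absorbing the offset shift an
inter-unit indel introduces) near half the contig length, supported by
anchors covering at least 60 % of unit positions, calls the duplication.
The contig is cut at the first band anchor and at that anchor shifted by
its local offset, producing two units whose lengths sum to the contig
length.

Both units are circular chromosomes, so each is reported at its
lexicographically minimal rotation (Booth's algorithm) for deterministic
output. Because the two canonical rotations need not be in phase — and a
rotation point could split an indel — the un-rotated, in-phase pair is
kept on the bisection object and used by `compare_mito_units()` for the
end-to-end unit alignment. Alignment of circular sequences is standardized
on a single global end-to-end pass of the in-phase linearisation; no
circular-alignment search is attempted.

The package reports evidence (two units, their length difference, edit
counts, identity) and deliberately does not adjudicate between the
biological interpretations of a duplicated mitogenome — a genuinely
doubled chromosome, heteroplasmy, or a chimeric mycelium — which coverage
and sequence alone cannot distinguish.

## Marker duplication and pan-genome accounting

The marker assessment is a deliberate mechanistic simplification of a
BUSCO-style analysis: supplied marker proteins are searched by global
alignment rather than profile HMMs. A protein is a qualifying hit at
identity ≥ 90 % over aligned columns covering ≥ 70 % of the marker length;
two or more qualifying hits mark a marker *duplicated* (diverged allelic
copies), exactly one *single*, a best qualifying-identity hit covering
only 30–70 % *fragmented* (the band is this package's convention), else
*missing*. The duplicated fraction duplicated/(single + duplicated) is the
ploidy diagnostic: in a dikaryon, markers on diverged haplotype segments
appear twice, markers on collapsed segments once.

Orthology between two species' protein sets uses reciprocal best matches
(best identity, ties broken by longer alignment then lexicographic id;
shared-hexamer prefiltering skips unrelated pairs). Pan-genome accounting
collapses within-set paralogs (single-linkage at the same identity
threshold) before counting singletons, so paralogous genes are not
counted, and enforces pan = core + singletons~A~ + singletons~B~ at
construction.

## Terpene-synthase motif screen

Class I terpene synthases (ionization-dependent) carry DDXX(D/E) ("1a")
and/or (N/D)DXX(S/T)XXXE ("1b"); class II (protonation-dependent) carry
DXDD ("2"); bifunctional enzymes carry both. Matching is exact positional
residue-class comparison, case-insensitive, with no substitution
tolerance — the motifs are treated as literal conserved signatures. The
ambiguity residue X in an input sequence matches nothing, including
wildcard positions: a conservative rule that avoids spurious calls on
low-quality translations. Overlapping and nested hits are all reported;
classification uses presence only, so overlap policy cannot change
categories.

## The synthetic dikaryon generator

`simulate_dikaryon()` emulates the structural features the pipeline relies
on, with one RNG stream per scenario consumed in fixed order so a seed
determines every output byte. Defaults (the study conditions of the test
suite and acceptance script):

* 8 nuclear haplotype loci of 30–60 kb at GC 0.494; 30 % of each locus has
  zero haplotype divergence and is emitted once at copy 2 (collapsed); the
  remainder is emitted as a contig pair at copy 1 with a substitution rate
  drawn from 0.5–3 % and indels at $10^{-4}$ events/base (geometric
  lengths, p = 0.5, capped at 100 bases). Within divergent regions the
  substitution rate alternates between 0.2× and 1.8× the regional rate in
  2-kb windows, planting the non-uniformity the divergence profiler is
  meant to detect.
* a mitogenome unit of 40 kb at GC 0.27 and copy 20, emitted by default as
  one tandem-duplicated contig whose second unit differs by 40
  substitutions and one 91-bp insertion — mirroring a real mitogenome pair
  whose lengths differ by 91 bases;
* an 8-kb rDNA-like contig at copy 100 and a 20-kb contaminant at GC 0.55
  and copy 0.2;
* read counts drawn Poisson with mean $c L d / r$ at depth 30 reads/base
  and read length 10 kb (an optional PAF emitter writes one primary record
  per counted read for ingestion round-trips);
* 40 marker proteins of 200–400 residues; half are present as two copies
  differing at 2 % of residues (diverged allelic loci), half as one exact
  copy, plus 10 unrelated decoy proteins.

Generator conventions worth knowing: mitogenome edits are placed interior
to the unit — nothing in the first 100 bases, the insertion within the
middle 80 %, and substitutions at least 25 bases clear of the insertion
site. The margin matters: a substitution within gap-sliding range of a
random insertion can be absorbed by an equally long but higher-scoring gap
placement, in which case the optimal alignment genuinely contains fewer
mismatches than were planted. Exact edit-count recovery is therefore only
promised (and only tested) for non-interacting edits.

What the generator does **not** emulate: sequencing error and base-caller
artifacts, real read placement (counts are drawn directly from the Poisson
model), repeat families within haplotypes, GC-dependent coverage bias, and
structural rearrangements between haplotypes. Passing tests therefore
demonstrate correct recovery of the modelled structure, not robustness to
every artifact of real data.

## Numerical choices and degenerate inputs

* Weighted medians (baseline, assembly GC) use the lower-median
  convention: the smallest value whose cumulative weight reaches half the
  total.
* N50 is the length of the contig closing the smallest descending-sorted
  prefix reaching half the total length; ties at the boundary resolve to
  that closing contig. The reported GC percentage is length-weighted,
  rounded half-up to one decimal, with the full-precision value kept as an
  attribute.
* GC excludes N bases from numerator and denominator; an all-N sequence
  yields `NA` rather than a number.
* Empty sequences, empty marker sets, zero-length contigs, non-positive
  baselines, many-to-one orthology tables and non-duplicated bisection
  requests raise errors naming the offending record where possible, rather
  than propagating nonsense.
* Alignment tie-breaks are fixed (state priority M, then gap-in-first,
  then gap-in-second) so outputs are platform-independent.

## Problem sizes used by the test suite

The suite verifies the corridor aligner against the unrestricted reference
on 500 random mutation settings (inputs up to 2 kb), the motif scanner
against a regex-engine oracle on 10,000 random proteins (50–1000
residues), and N50/GC against brute-force recomputation on 1,000 random
assemblies — these run at full size. Scenario-based suites use 20 seeds
each: coverage-group recovery on 20 contigs ≥ 50 kb at planted multiples
{0.2, 1, 2, 20, 100}; tandem-mitogenome recovery with 5-kb units (the
contig-level mechanics are unit-length-independent and the default 40-kb
units are exercised separately); marker-duplication recovery with 30
markers of 150–250 residues. These sizes are the package's own choice of
test conditions, small enough to run everywhere while keeping the
estimators' error bounds meaningful.

## Known limitations

* The baseline estimator assumes unique sequence dominates the qualifying
  assembly length; heavily collapsed assemblies can tip it to 2×.
* Marker matching is identity-based, not HMM-based; highly diverged but
  homologous markers that a profile search would find can be reported
  missing.
* The forward-strand default misses inverted allelic segments unless
  `both_strands = TRUE` is set.
* The aligner refuses, rather than attempts, long low-identity alignments;
  it targets the ≥ 95 %-identity allelic regime.
* Coverage groups are descriptive bins, not a mixture model; multiples
  near the boundaries (e.g. a collapsed contig sampled low) can land one
  bin off, which is why group fractions, not individual labels, drive the
  diploid call.
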