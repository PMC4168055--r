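---
title: "Methods: small-RNA classification, discovery and integration in srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA classification, discovery and integration in srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

## The analysis

`srnapipe` reimplements, as a tested and reusable pipeline, the standard
computational analysis of plant small-RNA (sRNA) sequencing libraries from a
two-condition experiment — here, maize seedlings mock-inoculated (CT) versus
inoculated with an endophytic diazotrophic bacterium such as *Herbaspirillum
seropedicae* (Hs). The pipeline classifies sequenced tags into known
(conserved) miRNAs, novel class-I miRNAs and siRNA candidates, quantifies
differential abundance between conditions, predicts miRNA targets, and
co-locates siRNA hotspots on coding sequences with DNA-methylation context
levels and transcript coverage.

Every stage is a plain exported function; `run_pipeline()` orchestrates them
from a single config. A synthetic-data module generates genomes, references,
read libraries and epigenomic tracks with fully recorded planted truth, so
the whole pipeline is testable without any external download.

## Preprocessing

Reads are trimmed at the leftmost occurrence of the 3' adapter
(`CTGTAGGCACCATCAAT` by default) or of an adapter prefix of at least 8 nt
ending at the read's 3' end. Reads without a detectable adapter are discarded
by default — the insert is then presumed longer than the read, so its true
3' end is unknown; this is configurable because sequencing protocols differ.
Trimmed reads are discarded when they contain N, fall outside the 18–28 nt
window, are low-complexity (dominant mononucleotide fraction ≥ 0.8, a
DUST-like proxy), or lie within 1 mismatch of a subsequence of a supplied
t/rRNA contaminant reference. The retained reads collapse into a
non-redundant tag → count library; bookkeeping is exact (every raw read lands
in exactly one summary category), which the tests assert as an invariant.

The 18–28 nt window is the profiling-tool setting for this assay type; a
narrower 18–26 nt window is sometimes quoted for the same protocol, and the
bounds are parameters.

## RNA folding and hairpin statistics

Secondary structure is predicted by Zuker-style dynamic programming under a
nearest-neighbor model shipped as a documented TSV
(`inst/extdata/nn_energy_params.tsv`): stacking free energies for the six
canonical pairs (including G:U wobble), linear hairpin/bulge/internal-loop
penalties, and an affine multiloop term. Structures are pseudoknot-free,
hairpin loops have at least 3 unpaired bases, interior loops are capped at 20
total unpaired nucleotides, and there is no lonely-pair prohibition. The
empty structure has energy 0, so the reported MFE is always ≤ 0.

The stack table starts from standard Turner-style RNA stacking values and is
symmetrized exactly, so a helix reads the same energy from either strand —
a property the tests check directly. The model is *declared*, not a clone of
any external folding engine: acceptance is defined against the shipped table
plus a brute-force structure-enumeration oracle (`structure_energy()` is an
independent loop-decomposition evaluator, and the test suite enumerates all
structures of short RNAs and verifies the DP attains the minimum).

Numerical choices: co-optimal structures are resolved by a fixed
deterministic traceback preference order (stacking first, then interior
loops by increasing loop size, then multiloops, pairing the leftmost
position first in the exterior). This makes the output deterministic; it
approximates but does not guarantee the lexicographically smallest
dot-bracket among all co-optima, which is why structure comparisons in the
oracle tests are on energy.

Hairpin quality statistics follow the standard definitions: AMFE =
|MFE|/length × 100 and MFEI = AMFE / GC%. MFEI is reported for every
candidate and never used as a rejection gate — reported novel-candidate
catalogues retain entries with MFEI well below the classic 0.7 threshold, so
the fraction above 0.7 is a summary statistic, not a filter.

Folding significance uses the randfold-style randomization test:
`dinucleotide_shuffle()` is an Altschul–Erickson Eulerian-walk shuffle that
preserves exact mono- and dinucleotide counts and the terminal bases; with
`n` shuffles the add-one estimator gives p = (k+1)/(n+1) where k counts
shuffles folding at least as stably as the native sequence. With the default
n = 100 the attainable p-values are exactly k/101 (floor 0.009901), which is
also the granularity observed in published novel-miRNA tables produced with
this test.

## Known-miRNA profiling and differential abundance

Tags are matched against a mature miRNA reference (miRBase-style FASTA) with
at most 1 mismatch; equal-length Hamming matching is the primary rule, with
a ±2 nt end-overhang tolerance mirroring isomiR reality (configurable off).
Matches collapse to families (`zma-miR156a-5p` → `miR156`); a tag matching
several members of one family increments the family once, because family
abundance is defined as the sum over member abundances, not over matches. A
tag tied between different families is flagged ambiguous and counted in each
tied family, a documented choice where the convention is genuinely open.

Counts are normalized to RPM over the library's total filtered redundant
reads. The per-family statistic is the replicate-free two-sided Fisher exact
test on (count, total − count) per condition, with Bonferroni correction
over the families actually tested. The two-sided p is the minimum-likelihood
summation over the hypergeometric support, with a 1e-12 relative tolerance
for probability ties; the tests sweep every 2×2 table with margins ≤ 12
against a full-enumeration oracle and cross-check `stats::fisher.test`.
Dispersion-based count models are deliberately out of scope: the pipeline
reproduces the replicate-free Fisher statistic as such.

## Novel class-I miRNA discovery

Discovery maps tags exactly (0 mismatches) to the genome — the candidate and
its star must be literal genome substrings for duplex logic — clusters
mapped positions per chromosome by single linkage with a 100 nt gap, and
takes the most abundant member of each locus as the candidate mature read.
Tags hitting more than 20 loci are flagged repetitive and skipped. Gap and
ceiling are invented defaults (the corresponding published tool does not
document its internals) and are both configurable and logged.

Around each candidate, precursor windows of 75, 150 and 250 nt are proposed
with the read placed on either arm. A window is accepted when the folded
structure leaves the mature read entirely on one arm (no loop straddling,
no self-pairing), at most 4 mature bases unpaired, and a star sequence can
be computed from the pairing partners with the 2-nt 3' overhang of Dicer
geometry. Windows are evaluated shortest-first and the first accepted
hairpin that also passes the class-I gate (star observed with count ≥ 1 in
the same library) and the randomization gate (p ≤ 0.1 with 100 shuffles) is
kept — the reported precursor is therefore the shortest window that explains
the duplex, consistent with a fixed 75-nt flanking-window protocol while
still allowing the longer precursors (75–232 nt) that real candidate tables
contain. Candidates within 1 mismatch of a known mature are excluded; the
same mature arising from multiple precursors is reported once per precursor
with letter suffixes.

## Target prediction

Targets are scored with the seed-weighted complementarity scheme underlying
plant target servers: optimal gapped alignment of the miRNA against the
site with penalties mismatch 1.0, G:U wobble 0.5, gap 2.0, doubled at miRNA
positions 2–13; the expectation is the total penalty and sites score below a
strict cutoff of 3.0. A site with at least one mismatch or gap at miRNA
positions 9–11 is classified as translational inhibition, otherwise
cleavage (wobbles do not count as central mismatches). The DP equals a
bounded brute-force search over all ≤2-gap alignments in the tests. Target
accessibility (opening-energy) filtering is recorded in the configuration
surface but is off by default: the published parameterisation of that step
belongs to an external server and is not reproducible from its description.

## siRNA classification, hotspots and integration

Tags not assigned to known or novel miRNA are siRNA candidates. They are
aligned, substitution-only and on both strands, against a repeat reference
(Repbase `id#Class` headers) and a CDS reference with up to 3 mismatches,
keeping only each tag's minimal-mismatch hits (best-hit policy, matching the
ungapped default of the short-read aligners used for this task). Each tag
counts once toward the class of its best hit; cross-class ties keep the
lexicographically smallest class as deterministic primary and are flagged.
Per-class tallies, shared/exclusive tag sets between conditions, and
per-class length histograms are reported for both unique tags and redundant
reads, since either convention appears in published summaries.

Per-CDS profiles record unique-siRNA counts, redundant RPM and a
per-position unique-coverage vector; selection uses the strict thresholds
"more than 50" unique siRNAs (and "more than 1000" for the high-density
flag). The hotspot of a CDS is the maximal-density 50-nt window (step 10)
of unique coverage, labelled 5'/3' when its midpoint falls in the terminal
20% of the CDS.

Integration compares, inside the hotspot versus equal-length flanks within
the CDS, the unweighted mean methylation level per context (CG/CHG/CHH; the
input track carries levels only, so no coverage weighting is possible), and
the RPM-normalized transcript coverage ratio Hs/CT. The verdict is
"concordant" exactly when CG and CHG hotspot means exceed their flank means
and the transcript log2 ratio is negative — mirroring the descriptive claim
that siRNA-enriched gene regions are CG/CHG-methylated with reduced
transcription. This is a qualitative surrogate: the methylation track of
the motivating system comes from a reference genotype rather than the
treated plants, so nothing stronger than concordance is asserted.

## The synthetic-data generator

The generator defines the study conditions for all recovery tests:

* 50,000 reads per library, read length 36, 3' adapter appended, N
  substitutions at rate 0.002;
* insert-length distribution peaking at 0.45 for 24 nt (the
  heterochromatic-siRNA signature of maize libraries), with 21–23 nt
  shoulders;
* five conserved families planted at Hs/CT RPM ratios 1.39, 0.24, 1.67,
  13.24 and 9.32 — the magnitudes of the reference catalogue, including
  the two strong copper-miRNA inductions and one repression;
* ten novel class-I hairpin loci: designed perfect stems (mature arm +
  loop + reverse-complement arm, GC ≈ 45%) whose star follows the 2-nt
  3'-overhang geometry, so they validate under any reasonable
  nearest-neighbor model — decoupling discovery tests from exact energy
  parameters; star reads at 5% of mature abundance;
* repeat- and CDS-derived siRNA tags with planted shared/exclusive
  structure per class and a 3'-biased CDS hotspot at positions 520–570 of
  a 600-nt CDS;
* methylation sites on a regular 4-nt grid with cycling contexts (so
  every context is represented in any region wider than three grid
  steps and regional context means are always defined), baseline 0.2
  elevated by 0.5 in CG/CHG inside hotspots; transcript coverage
  Poisson(3) per base with the inoculated condition suppressed to 0.75×
  inside silenced hotspots (matching the observed scale of transcript
  reduction).

Background reads are drawn from 150 discrete 300-nt background loci rather
than uniformly from the genome: sRNA in real tissue arises from discrete
loci, and discreteness keeps single-linkage locus clustering well defined,
so precision accounting against planted truth is exact. What the generator
does **not** emulate: sequencing error beyond uniform N injection, PCR
duplication, isomiR end-heterogeneity, multi-chromosome genomes, and
genuinely hard decoy hairpins (near-miRNA repeats). Passing recovery tests
therefore demonstrates correctness of the pipeline's logic under realistic
signal structure, not robustness to every artefact of real libraries.

## Problem sizes and runtime choices

The default recovery scenario (10 hairpins, 5 families, 50k reads per
library over a 100 kb genome) runs the full preprocess → profile → discover
path in about two minutes on one core; the folding-oracle property test
enumerates all structures for 200 random RNAs of length ≤ 18; the Fisher
oracle sweep covers all 2×2 tables with margins ≤ 12. These sizes were
chosen so the complete test suite exercises every stage end-to-end while
staying comfortably inside a routine CI run.

## Known limitations

* The energy model is intentionally compact; absolute MFE values differ
  from full Turner-2004 engines, so published MFE columns are treated as
  inputs, not regeneration targets.
* Fisher p-values of published family tables depend on unpublished raw
  counts and are not bit-reproducible; the pipeline verifies the
  downstream arithmetic (RPM, log2, ratios) and its own statistic instead.
* Class II/III novel-miRNA tiers, phased siRNA loci, nat-siRNA pairing and
  genome-wide siRNA locus calling are out of scope.
* Reads are assumed sense-strand as sequenced; deposited-strand conventions
  of external datasets are not auto-detected.
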