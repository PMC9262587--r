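---
title: "Calling genome-instability events in hybrid diploid yeast: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling genome-instability events in hybrid diploid yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridLOH)
```

## Scope

`hybridLOH` analyzes diploid yeast genomes formed by mating two diverged
haploids, so that essentially every kilobase carries a marker
distinguishing the two parental haplotypes (labelled `W` and `Y`
throughout, for the W303-1A and YJM789 backgrounds such hybrids are
typically built from). Everything downstream — loss-of-heterozygosity
(LOH) calling, uniparental disomy (UPD) and aneuploidy detection,
large-CNV and translocation-signature analysis, mutation annotation, and
the rate/enrichment statistics — consumes the per-marker allele-specific
read counts (or microarray ratios) of such a hybrid. The package does not
align reads or call variants from raw sequencing; its inputs begin at the
count table.

## The marker model and the RC statistic

Each heterozygous marker has one allele per haplotype. The ratio of
coverage for an allele is its read count divided by the genome-wide mean
per-site total count, giving the anchors 0.5 (one copy), 1.0 (two
copies) and 0 (absent). This normalization makes copy number legible:
a trisomic chromosome at 2:1 shows RC ≈ (1.0, 0.5).

Zygosity classification, however, deliberately does **not** use raw RC.
At realistic depths the per-site total is itself Poisson-distributed, so
raw RC at an unaltered het site fluctuates with depth as well as with
allele sampling; band-classifying raw RC at depth 30 would leave roughly
a third of markers unclassifiable. Instead each site's RC pair is
renormalized to fractions (`rc / (rc_W + rc_Y)`), which cancels the
depth term; at normal copy number the fraction and the RC coincide, so
the published band anchors carry over unchanged. Raw RC remains the
copy-number signal used by the windowed profile.

## Segmentation and event classification

* **Bands** (defaults): het when both fractions lie in [0.35, 0.65];
  homozygous when the retained allele ≥ 0.8 and the lost allele ≤ 0.15.
  Sites in neither band are unclassified; if they exceed 20% of markers
  the input fails quality control with the offending sites listed.
  Ties at shared band edges resolve toward heterozygosity — conservative
  calling, since a spurious het site merely shortens an event while a
  spurious hom site could fabricate one.
* **min_run = 2**: a state change must be supported by two consecutive
  concordant markers. An isolated homozygous marker is reported
  separately as a flagged single-SNP candidate — the class of event that
  sequencing can detect but that is too small for segmental calling —
  rather than breaking a segment.
* **Event typing**: a homozygous segment containing a chromosome's
  terminal marker is T-LOH; an interior segment is I-LOH. Events
  separated by fewer than `merge_gap = 10` heterozygous markers merge
  into one complex event (`CON/CON` interior, `CO/CON` when the group
  touches a telomere). The merge gap is a design choice: complex events
  are described qualitatively in the field ("multiple transitions
  between heterozygosity and homozygosity") without a quantitative merge
  rule, and ten markers (~10 kb at 1 kb spacing) keeps independently
  planted events at typical spacing separate while merging the
  transition clusters a single repair event produces.
* **CO/BIR**: terminal events are reported jointly as crossover-or-BIR.
  A single surviving colony cannot distinguish the two mechanisms —
  that requires the reciprocal product — so the caller does not guess.
* **Recipient**: the haplotype whose alleles were lost. This is the
  homolog that carried the recombination-initiating lesion, which is the
  biologically meaningful direction (information flows from the intact
  donor into the broken recipient).
* **Breakpoints**: each transition is reported as the interval from the
  last heterozygous to the first homozygous marker, labelled half-open,
  with its midpoint used for plotting and enrichment. An event starting
  at the first marker of an arm has its interval clipped to the arm
  start and flagged. For a left-arm terminal event the primary
  breakpoint is the right-hand transition (the one adjacent to
  heterozygosity).

UPD is distinguished from terminal LOH and from monosomy by combining
whole-chromosome homozygosity with the windowed copy-number profile:
homozygous at total copy ≈ 2 is UPD; at ≈ 1 it is monosomy. Windows are
1 kb (matching marker spacing) and normalized by the genome-wide median
window total, which is robust to a handful of large CNVs. Large CNV
calls require ≥ 5 kb of contiguous aberrant windows; translocation-size
prediction adds the centromere-containing retained portion of the
deleted chromosome to the duplicated terminal segment of the partner
chromosome and refuses to predict unless both breakpoints lie within
2 kb of an annotated dispersed repeat (Ty/delta) — "near a repeat" is
stated only qualitatively in the literature, and 2 kb spans a full Ty
element plus mapping slop at 1 kb marker resolution.

## The synthetic hybrid diploid

The generator is first-class, tested code, and its defaults are the
study conditions rather than tunable knobs:

* 16 chromosomes with reference-like *S. cerevisiae* lengths (total
  ≈ 12.07 Mb, smallest 230 kb) and standard centromere positions;
* marker spacing 218 bp in sequencing mode (~55,000 SNPs) or 928 bp in
  array mode (~13,000 probes, about 1 kb apart);
* an rDNA locus on chrXII with 123 `W` and 72 `Y` repeats (the counts
  measured in an untreated control diploid);
* G+C content 0.38; ribonucleotide density 1 per 500 bp per strand;
* conversion tract lengths lognormal with median 10 kb
  (crossover-associated) or 3 kb (unassociated) and shape σ = 0.9 — the
  literature reports only the medians, and a lognormal is the standard
  heavy-tailed model for tract lengths; σ = 0.9 puts ~90% of
  unassociated tracts between 0.7 and 13 kb, matching the reported
  variability qualitatively;
* allele counts binomial (beta-binomial available through an
  overdispersion parameter, default 0 — no dispersion model is reported
  for the data this emulates);
* random event positions uniform per bp (observed breakpoints show no
  pronounced hotspots); coordinates are 1-based inclusive everywhere in
  memory, and every writer states this in its header. BED interchange
  (0-based half-open on disk) is converted — and tested — via
  rtracklayer.

Events are planted directly rather than grown through a lineage tree:
colony population dynamics are not modelled, and the ~25 divisions per
colony enter only the rate arithmetic. The generator also does not
simulate reads (no FASTQ), replication mechanics, or meiosis.

What passing tests on this simulator do show: the caller's segmentation,
classification, recipient assignment and breakpoint bracketing are
correct against a known truth under binomial sampling noise, and the
estimators (rDNA repeat counts, CNV sizes, enrichment calibration) are
unbiased and calibrated under the stated noise model. What they do not
show: robustness to alignment artifacts, mapping bias between the two
haplotypes, GC-dependent coverage waves, or contamination — real-data
pathologies outside the generator's scope.

## Mutation annotation

Haplotype linkage requires a heterozygous marker within 300 bp (the
informative span of short-read pairs) and at least two concordant
co-observations with none discordant; with 1 kb marker spacing and a
300 bp window on either side, about 60% of mutations are expected to be
linkable, and the package's simulation test recovers that fraction.
The 5′-context analysis counts each mutation's 5′ flank in both strand
orientations (denominator = 2 × mutations), comparing the observed 5′C
fraction to a configurable expected fraction by a 1-df chi-square. The
expected value defaults to 35% — the random-association figure quoted
for a 38% G+C genome — and is a parameter rather than a derived
quantity, because no unambiguous derivation from the G+C content exists
(per-orientation C frequency would be 19%; an at-least-one-orientation
reading gives ≈ 34%, but conflicts with the doubled denominator).
Substitutions collapse into the six complementary classes; spectrum
comparisons use Fisher's exact test for small tables and fall back to
chi-square above 400 total counts, with the choice logged. A 2 bp
deletion is flagged as a dinucleotide-run deletion when the deleted unit
matches flanking tandem copies (≥ 2 counting the deleted one) — the
signature of topoisomerase-mediated ribonucleotide removal. Clonality
in a haploid requires the mutant base in strictly more than 70% of
reads; at exactly the threshold a mutation is classed mixed.

## Statistics

Rates are plain event counts per isolate per division; folds are
reported both raw and rounded to two significant figures, the convention
used for all headline numbers. Breakpoint–element enrichment tests each
annotation class with a one-sided Fisher 2×2 comparing breakpoints
in/out of the class's tolerance-expanded, merged footprint against
genome kilobases in/out of it (the genome discretised at the 1 kb marker
spacing, i.e. one control trial per kb); a permutation null (uniform
re-placement of the breakpoints) is available as the calibration oracle,
and correction across classes is Bonferroni by default
(Benjamini–Hochberg by flag) — "corrected for multiple comparisons" is
all the source literature specifies, and Bonferroni is the conservative
choice for 18 classes. Tandem repeats are found by a per-period scan
(region ≥ 24 bp, unit 1–1998 bp, ≥ 2 copies), verified against a
brute-force all-units oracle. The locus-LOH expectation reports both a
1-df binomial chi-square and an exact Poisson test; the exact
construction behind the published chi-square for that comparison is not
stated, so no claim is made to reproduce its p-value.

## Gel densitometry

Lane profiles are row-wise means over lane columns minus the mean of the
flanking gap windows (half a lane width each side), clipped at zero.
The migration model is linear in log10(size) — the standard
electrophoresis approximation, and the same model the synthetic gel
generator uses, which keeps round-trips well-posed. Ladder peaks are
local maxima above 3× the profile's median absolute deviation and must
match the supplied sizes one-to-one; the fit extrapolates linearly
beyond the ladder and must be monotone. Fragments deposit mass
(intensity ∝ length) at their mapped row with Gaussian spread, so total
profile intensity is conserved and peak ratios track mass ratios.
Normalization defaults to the lane's global maximum = 1 (per-peak
normalization is available; the published description is ambiguous
between the two).

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible.
The test suite runs the full pipeline on array-mode genomes (~13,000
markers) and a three-chromosome miniature for per-operation tests;
Monte-Carlo checks use 10,000+ draws where a distributional claim is
made, 100 replicates for unbiasedness, and 100 seeds for enrichment
calibration. These sizes were chosen to give stable statistics at
interactive runtimes.

## Known limitations

* CO vs BIR is never resolved for terminal events (by design).
* Complex-event classification exposes only the four-way vocabulary
  (`CON`, `CON/CON`, `CO/CON`, `CO/BIR`); finer subclassifications used
  in some datasets are not reproduced.
* Whole-chromosome events appear both as chromosome-length T-LOH events
  and in `detect_upd`; consumers counting segmental events should
  exclude chromosomes with UPD/monosomy calls.
* The enrichment Fisher construction treats kilobases as control
  trials; it is intentionally conservative, and the permutation test is
  the reference when calibration matters.
* The gel model has no band-compression, diffusion-time or
  pulsed-field physics; it is a quantification tool, not a simulator of
  gel artifacts.
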