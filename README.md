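# hybridLOH

Genome-instability analysis for hybrid diploid yeast from allele-specific
SNP coverage.

## The problem

When two diverged *Saccharomyces cerevisiae* haploids (e.g. W303-1A and
YJM789) are mated, the resulting diploid is heterozygous at roughly 55,000
single-nucleotide polymorphisms spread about one per kilobase over the
~12 Mb genome. Recombinogenic DNA lesions — such as the double-strand
breaks produced when active RNase H2 suddenly meets a genome densely
seeded with misincorporated ribonucleotides ("ribodysgenesis") — leave
footprints in this marker map: tracts of **loss of heterozygosity** (LOH),
whole-chromosome **uniparental disomy** (UPD), aneuploidy, large
deletions/duplications, and coupled terminal deletion/duplication patterns
diagnostic of translocations. `hybridLOH` calls and classifies all of
these from per-SNP allele-specific read counts (or two-channel microarray
ratios), annotates de novo point mutations and small in/dels, and computes
the associated rate, fold-change, expectation and enrichment statistics.
A synthetic hybrid-diploid generator with a ground-truth event ledger
makes every caller testable without any external data, and a small gel
densitometry toolkit quantifies alkaline-gel lane profiles used to measure
genomic ribonucleotide density.

## The model

The central statistic is the **ratio of coverage** (RC): at each marker,

```
RC_allele = (reads supporting the allele) / (genome-wide mean per-site total reads)
```

so an unaltered heterozygous site has RC ≈ 0.5 per allele, a duplicated
allele approaches 1.0 and a lost allele approaches 0. Zygosity states are
segmented from band membership of the site-normalized allele fractions
(het ∈ [0.35, 0.65]; homozygous when the retained allele ≥ 0.8 and the
lost allele ≤ 0.15), with a minimum run of 2 concordant markers to open a
segment. Homozygous segments become events:

* **I-LOH** (interstitial; gene conversion, class `CON`, or `CON/CON`
  when complex) — flanked by heterozygous segments;
* **T-LOH** (terminal; reciprocal crossover or break-induced replication,
  class `CO/BIR`, or `CO/CON` when associated with a nearby I-LOH) —
  extends to a chromosome end.

The *recipient* of each event is the haplotype whose alleles were lost —
the homolog that carried the initiating lesion. Each event carries a
breakpoint interval `(last het marker, first hom marker]` presumed to
contain the lesion. Copy-number profiles (1 kb windows, median-normalized)
separate UPD (homozygous at total copy 2) from monosomy (copy 1), detect
\>5 kb deletions/duplications, and predict translocation sizes as
(centromere-retained portion of the deleted chromosome) + (duplicated
terminal segment). rDNA repeat number is estimated per homolog as
2 × (rDNA coverage / single-copy coverage), split by haplotype-diagnostic
read fractions.

## Worked example

```r
library(hybridLOH)

cfg <- hybrid_genome_config(mode = "array", seed = 3)   # ~13,000 markers
g   <- build_hybrid_genome(cfg)
plan <- event_plan(kind  = c("conversion", "crossover", "UPD"),
                   chrom = c("chrIX", "chrIV", "chrVIII"),
                   start = c(200000, 900000, NA), end = c(205000, NA, NA),
                   recipient = "W")
res <- apply_events(g, plan, seed = 7)
cnt <- simulate_allele_counts(res$genome, mean_depth = 40, seed = 11)
ev  <- call_loh(cnt, cfg$chrom_lengths, cfg$centromeres)
ev[, c("chrom", "type", "class", "retained", "bp1_start", "bp1_end")]
#>     chrom  type  class retained bp1_start bp1_end
#> 1   chrIV T-LOH CO/BIR        Y    898304  900160
#> 2 chrVIII T-LOH CO/BIR        Y         1     928
#> 3   chrIX I-LOH    CON        Y    199520  200448
```

The conversion on chrIX is recovered as a simple interstitial event
(`CON`) and the crossover on chrIV as a terminal event whose breakpoint
interval (898,304–900,160) brackets the planted breakpoint at 900,000.
The whole-chromosome event on chrVIII is then separated from true
terminal LOH by its copy-number profile:

```r
prof <- copy_number_profile(cnt, cfg$chrom_lengths)
st   <- call_genotype_states(compute_rc(cnt))
detect_upd(st, prof)
#>   kind   chrom retained mean_cn_total
#> 1  UPD chrVIII        Y      1.985568
```

Rate arithmetic works from plain counts:

```r
b <- rate_baselines()
event_rate(120, 12, b$divisions_per_colony)$rate       # 0.4 per division
fold_change(0.4, b$loh_wt)$fold_rounded                 # 87
```

## Layout

* `R/` — simulator (`build_hybrid_genome`, `apply_events`,
  `simulate_*`), LOH caller (`compute_rc`, `call_genotype_states`,
  `segment_to_events`, `compare_event_sets`), structural calls
  (`detect_upd`, `detect_large_cnv`, `predict_translocation`,
  `rdna_copy_number`), mutation annotation (`link_to_haplotype`,
  `five_prime_context`, `classify_substitutions`,
  `indel_run_classifier`, `mixed_read_filter`), statistics
  (`event_rate`, `fold_change`, `element_enrichment`,
  `find_tandem_repeats`, `viability_fisher`), gel densitometry
  (`extract_lane_profile`, `calibrate_ladder`, `fragments_to_gel`,
  `summarize_profile`).
* `vignettes/hybridLOH-methods.Rmd` — the methods vignette: model,
  parameter choices, simulator scope and limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
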