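Package: hybridLOH
Title: Genome Instability Analysis in Hybrid Diploid Yeast from
    Allele-Specific SNP Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies genome-instability events in hybrid
    diploid yeast from allele-specific read depth at heterozygous SNPs:
    interstitial and terminal loss of heterozygosity (gene conversion,
    crossover, break-induced replication), uniparental disomy, aneuploidy,
    large deletions/duplications and coupled terminal
    deletion/duplication patterns diagnostic of translocations, plus
    haplotype-resolved rDNA repeat counting from coverage.  Annotates de
    novo point mutations and small in/dels with haplotype linkage, 5'
    sequence context and dinucleotide-run context, and computes event
    rates, fold changes, locus expectations and breakpoint-element
    enrichment statistics.  Includes a synthetic hybrid-diploid generator
    with a ground-truth event ledger so every caller is testable without
    external data, and a lane densitometry toolkit for alkaline-gel
    quantification of ribonucleotide density.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
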