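# Reference-like S. cerevisiae chromosome lengths (bp); 16 chromosomes,
# total ~12.07 Mb, smallest (chr I) 230 kb.
.yeast_chrom_lengths <- c(
  chrI = 230218L,  chrII = 813184L,  chrIII = 316620L,  chrIV = 1531933L,
  chrV = 576874L,  chrVI = 270161L,  chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L, chrX = 745751L,   chrXI = 666816L,   chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L
)

.yeast_centromeres <- c(
  chrI = 151465L,  chrII = 238207L,  chrIII = 114385L,  chrIV = 449711L,
  chrV = 151987L,  chrVI = 148510L,  chrVII = 496920L,  chrVIII = 105586L,
  chrIX = 355629L, chrX = 436307L,   chrXI = 440129L,   chrXII = 150828L,
  chrXIII = 268031L, chrXIV = 628758L, chrXV = 326584L, chrXVI = 555957L
)

#' Configuration for a synthetic hybrid diploid genome
#'
#' Describes a two-haplotype diploid heterozygous at regularly spaced
#' markers: 16 chromosomes totalling about 12 Mb, a centromere per
#' chromosome, an rDNA locus with per-haplotype repeat counts, and an
#' optional annotation of repeated/functional elements.  Defaults emulate a
#' W303-1A x YJM789-style hybrid: in \code{"sequencing"} mode markers are
#' spaced 218 bp apart (about 55,000 heterozygous SNPs genome-wide); in
#' \code{"array"} mode 928 bp apart (about 13,000 probes, roughly 1 kb
#' spacing).
#'
#' All coordinates are 1-based inclusive.
#'
#' @param mode "sequencing" (~55,000 SNPs) or "array" (~13,000 probes).
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param centromeres named integer vector of centromere positions (bp).
#' @param snp_spacing marker spacing in bp; overrides \code{mode} if given.
#' @param haplotypes two haplotype labels, default \code{c("W","Y")}.
#' @param rdna list with \code{chrom}, \code{start}, \code{end} and
#'   \code{repeats} (named per-haplotype repeat counts).  Default: a locus
#'   on chrXII with 123 "W" and 72 "Y" repeats, the counts measured in the
#'   untreated control diploid.
#' @param elements data.frame with columns \code{class}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive) annotating repeats and
#'   functional elements (Ty, delta, ARS, tRNA, tandem repeat, ...);
#'   may be \code{NULL}.
#' @param gc genomic G+C fraction, default 0.38.
#' @param rnmp_density ribonucleotides per bp per strand, default 1/500.
#' @param seed integer random seed.
#' @return object of class \code{hybrid_genome_config}.
#' @export
hybrid_genome_config <- function(mode = c("sequencing", "array"),
                                 chrom_lengths = .yeast_chrom_lengths,
                                 centromeres = .yeast_centromeres,
                                 snp_spacing = NULL,
                                 haplotypes = c("W", "Y"),
                                 rdna = list(chrom = "chrXII",
                                             start = 451000L, end = 468000L,
                                             repeats = c(W = 123L, Y = 72L)),
                                 elements = NULL,
                                 gc = 0.38,
                                 rnmp_density = 1 / 500,
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(snp_spacing))
    snp_spacing <- if (mode == "sequencing") 218L else 928L
  stopifnot(length(haplotypes) == 2L, !anyDuplicated(haplotypes))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (gc <= 0 || gc >= 1)
    stop("G+C fraction must lie strictly between 0 and 1")
  if (snp_spacing < 1)
    stop("snp_spacing must be >= 1 bp")
  if (rnmp_density < 0)
    stop("rnmp_density must be >= 0")
  if (!all(names(centromeres) %in% names(chrom_lengths)))
    stop("centromere names must match chromosome names")
  if (any(centromeres > chrom_lengths[names(centromeres)]))
    stop("centromere positions outside chromosome bounds")
  if (!is.null(rdna)) {
    if (!rdna$chrom %in% names(chrom_lengths))
      stop("rDNA chromosome not in chrom_lengths")
    if (rdna$start < 1 || rdna$end > chrom_lengths[[rdna$chrom]] ||
        rdna$start > rdna$end)
      stop("rDNA interval outside chromosome bounds")
    if (any(rdna$repeats < 0)) stop("rDNA repeat counts must be >= 0")
  }
  if (!is.null(elements)) {
    elements <- as.data.frame(elements)
    need <- c("class", "chrom", "start", "end")
    if (!all(need %in% names(elements)))
      stop("elements must have columns class, chrom, start, end")
    if (!all(elements$chrom %in% names(chrom_lengths)))
      stop("element chromosome not in chrom_lengths")
    lim <- chrom_lengths[elements$chrom]
    if (any(elements$start < 1) || any(elements$end > lim) ||
        any(elements$start > elements$end))
      stop("element intervals outside chromosome bounds")
  }
  structure(list(mode = mode,
                 chrom_lengths = chrom_lengths,
                 centromeres = centromeres,
                 snp_spacing = as.integer(snp_spacing),
                 haplotypes = haplotypes,
                 rdna = rdna,
                 elements = elements,
                 gc = gc,
                 rnmp_density = rnmp_density,
                 seed = as.integer(seed)),
            class = "hybrid_genome_config")
}

.sample_base <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Build a hybrid diploid genome with a heterozygous SNP map
#'
#' Places markers every \code{snp_spacing} bp on every chromosome and
#' assigns each marker two distinct alleles, one per haplotype, drawn with
#' the configured G+C content.  Every site starts heterozygous with one
#' copy per haplotype; instability events are planted afterwards with
#' \code{\link{apply_events}}.
#'
#' @param config a \code{\link{hybrid_genome_config}}.
#' @return object of class \code{hybrid_genome}: a list with the config and
#'   a \code{snps} data.frame (chrom, pos, allele_W/allele_Y named after the
#'   configured haplotypes, and integer per-haplotype copy numbers
#'   \code{cn_W}/\code{cn_Y}, both 1 at construction).
#' @export
build_hybrid_genome <- function(config) {
  stopifnot(inherits(config, "hybrid_genome_config"))
  set.seed(config$seed)
  sp <- config$snp_spacing
  chroms <- names(config$chrom_lengths)
  pos_list <- lapply(chroms, function(ch) {
    L <- config$chrom_lengths[[ch]]
    seq.int(sp, L, by = sp)
  })
  n_per <- vapply(pos_list, length, integer(1))
  pos <- unlist(pos_list, use.names = FALSE)
  n <- length(pos)
  a1 <- .sample_base(n, config$gc)
  # second allele differs from the first at every marker
  others <- list(A = c("T", "G", "C"), T = c("A", "G", "C"),
                 G = c("A", "T", "C"), C = c("A", "T", "G"))
  pick <- ceiling(stats::runif(n) * 3)
  a2 <- vapply(seq_len(n), function(i) others[[a1[i]]][pick[i]], character(1))
  snps <- data.frame(chrom = rep(chroms, n_per),
                     pos = pos,
                     allele_1 = a1, allele_2 = a2,
                     cn_1 = 1L, cn_2 = 1L,
                     stringsAsFactors = FALSE)
  hap <- config$haplotypes
  names(snps) <- c("chrom", "pos",
                   paste0("allele_", hap[1]), paste0("allele_", hap[2]),
                   paste0("cn_", hap[1]), paste0("cn_", hap[2]))
  structure(list(config = config, snps = snps,
                 rdna_repeats = if (is.null(config$rdna)) NULL
                                else config$rdna$repeats),
            class = "hybrid_genome")
}

#' @export
print.hybrid_genome <- function(x, ...) {
  cat("hybrid diploid genome:",
      length(x$config$chrom_lengths), "chromosomes,",
      format(sum(x$config$chrom_lengths), big.mark = ","), "bp,",
      nrow(x$snps), "heterozygous markers\n")
  invisible(x)
}

# internal accessors for per-haplotype columns
.cn_cols <- function(genome) paste0("cn_", genome$config$haplotypes)
.allele_cols <- function(genome) paste0("allele_", genome$config$haplotypes)

#' Simulate random chromosome sequences at a given G+C content
#'
#' Used for sequence-context analyses (5' flanks, dinucleotide runs,
#' tandem repeats) where only base composition matters.
#'
#' @param lengths named vector of sequence lengths (bp).
#' @param gc G+C fraction (default 0.38).
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
simulate_genome_sequence <- function(lengths, gc = 0.38, seed = 1L) {
  set.seed(seed)
  out <- vapply(lengths, function(L)
    paste(.sample_base(L, gc), collapse = ""), character(1))
  names(out) <- names(lengths)
  out
}
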