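# Small three-chromosome genome for fast tests (1 kb marker spacing).
small_config <- function(seed = 1L, spacing = 1000L, rdna = NULL,
                         elements = NULL) {
  hybrid_genome_config(
    chrom_lengths = c(chrA = 300000L, chrB = 400000L, chrC = 250000L),
    centromeres = c(chrA = 150000L, chrB = 100000L, chrC = 120000L),
    snp_spacing = spacing, rdna = rdna, elements = elements, seed = seed)
}

# Random element annotation: n_classes classes, n_per intervals each,
# interval width w bp.
random_elements <- function(chrom_lengths, n_classes = 6L, n_per = 15L,
                            w = 300L, seed = 1L,
                            classes = paste0("class", seq_len(n_classes))) {
  set.seed(seed)
  rows <- list()
  for (cl in classes) {
    ch <- sample(names(chrom_lengths), n_per, replace = TRUE,
                 prob = as.numeric(chrom_lengths))
    st <- vapply(ch, function(c_)
      sample.int(chrom_lengths[[c_]] - w, 1L), integer(1))
    rows[[cl]] <- data.frame(class = cl, chrom = ch, start = st,
                             end = st + w - 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Independent per-marker zygosity oracle: recompute the expected state of
# every marker directly from the genome's per-haplotype copy numbers.
zygosity_oracle <- function(genome) {
  haps <- genome$config$haplotypes
  cn1 <- genome$snps[[paste0("cn_", haps[1])]]
  cn2 <- genome$snps[[paste0("cn_", haps[2])]]
  ifelse(cn1 >= 1 & cn2 >= 1, "het",
         ifelse(cn1 >= 1 & cn2 == 0, paste0("hom_", haps[1]),
                ifelse(cn2 >= 1 & cn1 == 0, paste0("hom_", haps[2]),
                       "absent")))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher exact
# p-value for a 2x2 table with fixed margins (independent of
# stats::fisher.test's internals).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n_ <- c_ + d; k <- a + c_
  ks <- max(0, k - n_):min(k, m)
  probs <- exp(lchoose(m, ks) + lchoose(n_, k - ks) - lchoose(m + n_, k))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plant a grid of non-overlapping conversions (and optional crossovers)
# across a genome; returns the plan.
grid_plan <- function(config, conversions_per_chrom = 3L,
                      tract = 4000L, crossover_chroms = character(0),
                      recipient = "W") {
  cl <- config$chrom_lengths
  cen <- config$centromeres
  rows <- list()
  for (ch in names(cl)) {
    lim <- min(cen[[ch]], cl[[ch]]) - 20000L
    starts <- seq.int(10000L, by = tract + 12000L,
                      length.out = conversions_per_chrom)
    starts <- starts[starts + tract < lim]
    for (s in starts)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "conversion", chrom = ch, start = s, end = s + tract - 1L,
        stringsAsFactors = FALSE)
    if (ch %in% crossover_chroms) {
      p <- cen[[ch]] + round(0.6 * (cl[[ch]] - cen[[ch]]))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "crossover", chrom = ch, start = p, end = NA,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  event_plan(kind = df$kind, chrom = df$chrom, start = df$start,
             end = df$end, recipient = recipient)
}
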