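test_that("genome construction matches the configured marker density", {
  cfg <- small_config(spacing = 1000L)
  g <- build_hybrid_genome(cfg)
  # ~1 marker per kb over 950 kb
  expect_equal(nrow(g$snps), sum(floor(cfg$chrom_lengths / 1000)))
  # default full-genome configs: ~12 Mb with a 230 kb smallest chromosome
  full <- hybrid_genome_config()
  expect_equal(min(full$chrom_lengths), 230218L)
  expect_gt(sum(full$chrom_lengths), 11.9e6)
  expect_lt(sum(full$chrom_lengths), 12.3e6)
  # sequencing mode lands near 55,000 markers, array mode near 13,000
  expect_equal(round(sum(full$chrom_lengths) / full$snp_spacing, -3), 55000)
  arr <- hybrid_genome_config(mode = "array")
  expect_equal(round(sum(arr$chrom_lengths) / arr$snp_spacing, -3), 13000)
})

test_that("every marker is heterozygous with one copy per haplotype", {
  g <- build_hybrid_genome(small_config())
  expect_true(all(g$snps$cn_W == 1L))
  expect_true(all(g$snps$cn_Y == 1L))
  expect_true(all(g$snps$allele_W != g$snps$allele_Y))
  expect_true(all(diff(g$snps$pos[g$snps$chrom == "chrA"]) > 0))
})

test_that("genome construction is deterministic under a fixed seed", {
  g1 <- build_hybrid_genome(small_config(seed = 42L))
  g2 <- build_hybrid_genome(small_config(seed = 42L))
  expect_identical(g1$snps, g2$snps)
  g3 <- build_hybrid_genome(small_config(seed = 43L))
  expect_false(identical(g1$snps, g3$snps))
})

test_that("invalid configurations are rejected", {
  expect_error(hybrid_genome_config(gc = 1.2), "G\\+C")
  expect_error(hybrid_genome_config(rnmp_density = -1), "rnmp")
  expect_error(small_config(elements = data.frame(
    class = "Ty", chrom = "chrA", start = 1, end = 999999)),
    "outside chromosome bounds")
  expect_error(hybrid_genome_config(
    rdna = list(chrom = "chrXII", start = -5, end = 100,
                repeats = c(W = 1, Y = 1))), "rDNA")
})

test_that("an empty plan leaves the genome unchanged with an empty ledger", {
  g <- build_hybrid_genome(small_config())
  res <- apply_events(g, event_plan(kind = character(0)))
  expect_identical(res$genome$snps, g$snps)
  expect_equal(nrow(res$ledger), 0L)
})

test_that("conversion homozygoses the tract and leaves flanks heterozygous", {
  g <- build_hybrid_genome(small_config())
  # tract covering exactly 5 markers (positions 100000..104000)
  plan <- event_plan("conversion", chrom = "chrA",
                     start = 99500L, end = 104500L, recipient = "W")
  res <- apply_events(g, plan)
  s <- res$genome$snps
  inside <- s$chrom == "chrA" & s$pos >= 99500 & s$pos <= 104500
  expect_equal(sum(inside), 5L)
  expect_true(all(s$cn_W[inside] == 0L & s$cn_Y[inside] == 2L))
  expect_true(all(s$cn_W[!inside] == 1L & s$cn_Y[!inside] == 1L))
})

test_that("crossover homozygoses all distal markers (zygosity oracle)", {
  g <- build_hybrid_genome(small_config())
  p <- 220000L  # right arm of chrA (cen at 150 kb)
  res <- apply_events(g, event_plan("crossover", chrom = "chrA", start = p,
                                    recipient = "W"))
  st <- zygosity_oracle(res$genome)
  s <- res$genome$snps
  on_a <- s$chrom == "chrA"
  expect_true(all(st[on_a & s$pos >= p] == "hom_Y"))
  expect_true(all(st[on_a & s$pos < p] == "het"))
  expect_true(all(st[!on_a] == "het"))
})

test_that("UPD keeps total copy number at two; aneuploidy changes it", {
  g <- build_hybrid_genome(small_config())
  res <- apply_events(g, event_plan(
    kind = c("UPD", "monosomy", "trisomy"),
    chrom = c("chrA", "chrB", "chrC"),
    recipient = c("W", "W", "Y")))
  s <- res$genome$snps
  tot <- s$cn_W + s$cn_Y
  expect_true(all(tot[s$chrom == "chrA"] == 2L))
  expect_true(all(s$cn_Y[s$chrom == "chrA"] == 2L))
  expect_true(all(tot[s$chrom == "chrB"] == 1L))
  expect_true(all(tot[s$chrom == "chrC"] == 3L))
  expect_true(all(tot >= 0))
})

test_that("truth ledger replay reproduces the modified genome exactly", {
  cfg <- small_config(elements = data.frame(
    class = "Ty",
    chrom = c("chrA", "chrB"), start = c(219000L, 59500L),
    end = c(221000L, 61000L), stringsAsFactors = FALSE))
  g <- build_hybrid_genome(cfg)
  plan <- event_plan(
    kind = c("conversion", "crossover", "UPD", "deletion", "translocation",
             "SNV"),
    chrom = c("chrA", "chrB", "chrC", "chrB", "chrA", "chrC"),
    start = c(50000L, 350000L, NA, 200000L, 220000L, 12345L),
    end = c(58000L, NA, NA, 215000L, NA, NA),
    chrom2 = c(NA, NA, NA, NA, "chrB", NA),
    start2 = c(NA, NA, NA, NA, 60000L, NA),
    recipient = "W")
  res <- apply_events(g, plan, seed = 5L)
  expect_equal(nrow(res$ledger), 6L)  # every planted event, exactly once
  fresh <- build_hybrid_genome(cfg)
  replay <- apply_ledger(fresh, res$ledger)
  expect_identical(replay$snps, res$genome$snps)
})

test_that("translocation without a compatible repeat element is refused", {
  g <- build_hybrid_genome(small_config())  # no annotation at all
  expect_error(apply_events(g, event_plan(
    "translocation", chrom = "chrA", start = 220000L,
    chrom2 = "chrB", start2 = 60000L)), "repeat element")
})

test_that("allele counts follow the analytic expectations", {
  g <- build_hybrid_genome(small_config())
  # heterozygous genome: allele fraction 0.5
  cnt <- simulate_allele_counts(g, mean_depth = 30, seed = 2L)
  frac <- sum(cnt$count_W) / sum(cnt$count_W + cnt$count_Y)
  expect_lt(abs(frac - 0.5), 0.01)
  # LOH region: fractions 1 and 0
  res <- apply_events(g, event_plan("UPD", chrom = "chrA", recipient = "W"))
  cnt2 <- simulate_allele_counts(res$genome, mean_depth = 30, seed = 2L)
  on_a <- cnt2$chrom == "chrA"
  expect_true(all(cnt2$count_W[on_a] == 0L))
  expect_gt(mean(cnt2$count_Y[on_a]), 25)
  # trisomy 2:1 -> fraction 2/3, Monte-Carlo against the analytic mean
  res3 <- apply_events(g, event_plan("trisomy", chrom = "chrB",
                                     recipient = "W"))
  cnt3 <- simulate_allele_counts(res3$genome, mean_depth = 30, seed = 3L)
  on_b <- cnt3$chrom == "chrB"
  n_reads <- sum(cnt3$count_W[on_b] + cnt3$count_Y[on_b])
  phat <- sum(cnt3$count_W[on_b]) / n_reads
  se <- sqrt((2 / 3) * (1 / 3) / n_reads)
  expect_lt(abs(phat - 2 / 3), 3 * se)
  # determinism
  expect_identical(cnt, simulate_allele_counts(g, mean_depth = 30, seed = 2L))
  expect_error(simulate_allele_counts(g, 30, overdispersion = -0.1),
               "overdispersion")
})

test_that("microarray ratios are centered at exactly 1 and track copy number", {
  g <- build_hybrid_genome(small_config())
  pr <- simulate_microarray_ratios(g, noise_sd = 0, seed = 1L)
  expect_equal(mean(pr$rm), 1)
  expect_true(all(abs(pr$rm - 1) < 1e-12))  # all-het, zero noise
  # deleted allele inside a terminal LOH: expectation 0 before centering
  res <- apply_events(g, event_plan("crossover", chrom = "chrA",
                                    start = 220000L, recipient = "W"))
  pr2 <- simulate_microarray_ratios(res$genome, noise_sd = 0, seed = 1L)
  lost <- pr2$chrom == "chrA" & pr2$pos >= 220000 & pr2$haplotype == "W"
  expect_true(all(pr2$rm[lost] == 0))
  expect_equal(mean(pr2$rm), 1)
})

test_that("alkaline fragmentation behaves as a Poisson cleavage process", {
  expect_equal(simulate_alkaline_fragments(1e6, 0, n_molecules = 3),
               rep(1e6, 3))
  frags <- simulate_alkaline_fragments(1e6, 1 / 500, n_molecules = 5,
                                       seed = 9L)
  m <- mean(frags)
  se <- stats::sd(frags) / sqrt(length(frags))
  expect_lt(abs(m - 500), 3 * se)
  # distribution shape: exponential with rate = density
  ks <- suppressWarnings(stats::ks.test(
    sample(frags, min(10000, length(frags))), "pexp", rate = 1 / 500))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_alkaline_fragments(-5, 1 / 500), "molecule_length")
})
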