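test_that("RC values hit the 0.5 / 1.0 / 0 anchors", {
  g <- build_hybrid_genome(small_config())
  cnt <- simulate_allele_counts(g, mean_depth = 30, noise = "none")
  rc <- compute_rc(cnt)
  expect_true(all(rc$rc_W == 0.5))
  expect_true(all(rc$rc_Y == 0.5))
  # LOH region at matched depth: RC (1.0, 0)
  res <- apply_events(g, event_plan("conversion", chrom = "chrA",
                                    start = 50000L, end = 80000L,
                                    recipient = "W"))
  rc2 <- compute_rc(simulate_allele_counts(res$genome, 30, noise = "none"))
  inside <- rc2$chrom == "chrA" & rc2$pos >= 50000 & rc2$pos <= 80000
  expect_true(all(abs(rc2$rc_Y[inside] - 1.0) < 0.05))
  expect_true(all(rc2$rc_W[inside] == 0))
  # trisomy 2:1 -> RC ~ (1.0, 0.5); a full-size genome so the trisomic
  # chromosome barely moves the genome-wide normalizer
  gf <- build_hybrid_genome(hybrid_genome_config(mode = "array"))
  res3 <- apply_events(gf, event_plan("trisomy", chrom = "chrII",
                                      recipient = "W"))
  rc3 <- compute_rc(simulate_allele_counts(res3$genome, 30, noise = "none"))
  on_b <- rc3$chrom == "chrII"
  expect_lt(abs(mean(rc3$rc_W[on_b]) - 1.0), 0.1)
  expect_lt(abs(mean(rc3$rc_Y[on_b]) - 0.5), 0.1)
  expect_error(compute_rc(within(cnt, {count_W <- 0L; count_Y <- 0L})),
               "all counts are zero")
})

test_that("noise-free heterozygous genome yields one het segment per chromosome", {
  g <- build_hybrid_genome(small_config())
  st <- call_genotype_states(compute_rc(
    simulate_allele_counts(g, 30, noise = "none")))
  expect_equal(nrow(st$segments), 3L)
  expect_true(all(st$segments$state == "het"))
  expect_equal(nrow(st$single_snp_candidates), 0L)
})

test_that("a planted 5-marker conversion segments exactly", {
  g <- build_hybrid_genome(small_config())
  res <- apply_events(g, event_plan("conversion", chrom = "chrA",
                                    start = 99500L, end = 104500L,
                                    recipient = "W"))
  st <- call_genotype_states(compute_rc(
    simulate_allele_counts(res$genome, 30, noise = "none")))
  seg <- st$segments[st$segments$chrom == "chrA", ]
  expect_equal(seg$state, c("het", "hom_Y", "het"))
  expect_equal(seg$n_snps[2], 5L)
  expect_equal(seg$start_pos[2], 100000)
  expect_equal(seg$end_pos[2], 104000)
})

test_that("an isolated aberrant marker becomes a flagged single-SNP candidate", {
  g <- build_hybrid_genome(small_config())
  cnt <- simulate_allele_counts(g, 30, noise = "none")
  i <- which(cnt$chrom == "chrB" & cnt$pos == 200000)
  cnt$count_W[i] <- 0L; cnt$count_Y[i] <- 30L
  st <- call_genotype_states(compute_rc(cnt))
  expect_equal(nrow(st$single_snp_candidates), 1L)
  expect_equal(st$single_snp_candidates$pos, 200000)
  expect_equal(st$single_snp_candidates$state, "hom_Y")
  # not a segment break
  expect_true(all(st$segments$state[st$segments$chrom == "chrB"] == "het"))
})

test_that("segmentation partitions chromosomes; adjacent segments differ", {
  g <- build_hybrid_genome(small_config())
  plan <- grid_plan(g$config, conversions_per_chrom = 3L,
                    crossover_chroms = "chrB")
  res <- apply_events(g, plan)
  st <- call_genotype_states(compute_rc(
    simulate_allele_counts(res$genome, 30, noise = "none")))
  for (ch in unique(st$segments$chrom)) {
    seg <- st$segments[st$segments$chrom == ch, ]
    expect_true(all(diff(seg$start_idx) > 0))
    expect_true(all(seg$start_idx[-1] > seg$end_idx[-nrow(seg)]))
    expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
  }
})

test_that("excessive unclassifiable markers trigger a quality failure", {
  g <- build_hybrid_genome(small_config())
  cnt <- simulate_allele_counts(g, 30, noise = "none")
  bad <- seq_len(floor(nrow(cnt) * 0.25))
  cnt$count_W[bad] <- 21L; cnt$count_Y[bad] <- 9L  # fraction 0.7: no band
  expect_error(call_genotype_states(compute_rc(cnt)), "quality failure")
})

test_that("terminal and interstitial events classify by the standard vocabulary", {
  cfg <- small_config()
  g <- build_hybrid_genome(cfg)
  plan <- event_plan(
    kind = c("crossover", "conversion", "conversion", "crossover"),
    chrom = c("chrA", "chrB", "chrC", "chrC"),
    start = c(220000L, 200000L, 201000L, 50000L),
    end = c(NA, 210000L, 209000L, NA),
    recipient = "W")
  res <- apply_events(g, plan)
  ev <- call_loh(simulate_allele_counts(res$genome, 30, noise = "none"),
                 cfg$chrom_lengths, cfg$centromeres)
  a <- ev[ev$chrom == "chrA", ]
  expect_equal(a$type, "T-LOH")
  expect_equal(a$class, "CO/BIR")
  expect_equal(a$retained, "Y")
  expect_equal(a$recipient, "W")
  b <- ev[ev$chrom == "chrB", ]
  expect_equal(b$type, "I-LOH")
  expect_equal(b$class, "CON")
  expect_equal(b$complexity, "simple")
  # chrC: left-arm crossover (cen at 120 kb, breakpoint at 50 kb) plus an
  # interior conversion -> two separate events
  cc <- ev[ev$chrom == "chrC", ]
  expect_setequal(cc$type, c("T-LOH", "I-LOH"))
})

test_that("a T-LOH with a nearby I-LOH within the merge gap becomes CO/CON", {
  cfg <- small_config()
  g <- build_hybrid_genome(cfg)
  # conversion ending 5 het markers before a crossover: merge gap 10
  plan <- event_plan(kind = c("conversion", "crossover"),
                     chrom = "chrA",
                     start = c(200000L, 210500L), end = c(204500L, NA),
                     recipient = "W")
  res <- apply_events(g, plan)
  ev <- call_loh(simulate_allele_counts(res$genome, 30, noise = "none"),
                 cfg$chrom_lengths, cfg$centromeres)
  expect_equal(nrow(ev[ev$chrom == "chrA", ]), 1L)
  expect_equal(ev$class[ev$chrom == "chrA"], "CO/CON")
  expect_equal(ev$type[ev$chrom == "chrA"], "T-LOH")
  expect_equal(ev$complexity[ev$chrom == "chrA"], "complex")
  # with a smaller merge gap the two events stay separate
  ev2 <- call_loh(simulate_allele_counts(res$genome, 30, noise = "none"),
                  cfg$chrom_lengths, cfg$centromeres, merge_gap = 3L)
  expect_equal(nrow(ev2[ev2$chrom == "chrA", ]), 2L)
  # two interior blocks merged -> complex I-LOH (CON/CON)
  plan3 <- event_plan(kind = c("conversion", "conversion"),
                      chrom = "chrB", start = c(200000L, 208000L),
                      end = c(203000L, 212000L), recipient = "W")
  res3 <- apply_events(build_hybrid_genome(cfg), plan3)
  ev3 <- call_loh(simulate_allele_counts(res3$genome, 30, noise = "none"),
                  cfg$chrom_lengths, cfg$centromeres)
  expect_equal(ev3$class[ev3$chrom == "chrB"], "CON/CON")
  expect_equal(ev3$complexity[ev3$chrom == "chrB"], "complex")
})

test_that("breakpoint intervals bracket the planted lesion", {
  expect_equal(breakpoint_interval(100000, 101000),
               list(start = 100000, end = 101000, midpoint = 100500,
                    clipped = FALSE))
  bp <- breakpoint_interval(NA, 928)
  expect_true(bp$clipped)
  expect_equal(bp$start, 1)
  # containment over many simulated events (noise-free)
  cfg <- small_config()
  set.seed(77)
  n_checked <- 0L
  for (rep in 1:20) {
    g <- build_hybrid_genome(cfg)
    starts <- sort(sample(seq(20000L, 120000L, by = 1000L), 3L)) +
      sample(0:999, 3L)
    chroms <- c("chrA", "chrB", "chrC")
    plan <- event_plan("conversion", chrom = chroms, start = starts,
                       end = starts + 5000L, recipient = "W")
    res <- apply_events(g, plan)
    ev <- call_loh(simulate_allele_counts(res$genome, 30, noise = "none"),
                   cfg$chrom_lengths, cfg$centromeres)
    for (k in seq_len(nrow(res$ledger))) {
      led <- res$ledger[k, ]
      hit <- ev[ev$chrom == led$chrom, ]
      expect_equal(nrow(hit), 1L)
      expect_true(hit$bp1_start <= led$breakpoint &&
                  led$breakpoint <= hit$bp1_end)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 60L)
})

test_that("event-set comparison matches shared and private events", {
  cfg <- small_config()
  g <- build_hybrid_genome(cfg)
  plan_a <- event_plan("conversion", chrom = c("chrA", "chrB"),
                       start = c(50000L, 200000L),
                       end = c(55000L, 206000L), recipient = "W")
  res_a <- apply_events(g, plan_a)
  ev_a <- call_loh(simulate_allele_counts(res_a$genome, 30, noise = "none"),
                   cfg$chrom_lengths, cfg$centromeres)
  # identical sets -> all shared
  cmp <- compare_event_sets(ev_a, ev_a)
  expect_equal(unname(cmp$counts), c(2L, 0L, 0L))
  # B = A plus one extra T-LOH -> one B-only event
  plan_b <- event_plan(kind = c("conversion", "conversion", "crossover"),
                       chrom = c("chrA", "chrB", "chrC"),
                       start = c(50000L, 200000L, 180000L),
                       end = c(55000L, 206000L, NA), recipient = "W")
  res_b <- apply_events(build_hybrid_genome(cfg), plan_b)
  ev_b <- call_loh(simulate_allele_counts(res_b$genome, 30, noise = "none"),
                   cfg$chrom_lengths, cfg$centromeres)
  cmp2 <- compare_event_sets(ev_a, ev_b)
  expect_equal(unname(cmp2$counts), c(2L, 0L, 1L))
  expect_equal(ev_b$type[cmp2$b_only], "T-LOH")
  # disjoint sets -> zero shared
  cmp3 <- compare_event_sets(ev_a[1, ], ev_b[3, , drop = FALSE])
  expect_equal(unname(cmp3$counts[["shared"]]), 0L)
})

test_that("false positives are rare on an event-free genome at depth 30", {
  cfg <- small_config()
  g <- build_hybrid_genome(cfg)
  fp <- 0L
  for (s in 1:10) {
    ev <- call_loh(simulate_allele_counts(g, 30, seed = 1000L + s),
                   cfg$chrom_lengths, cfg$centromeres)
    fp <- fp + nrow(ev)
  }
  expect_lt(fp, 1L + 1e-9)  # < 1 event across 10 simulated genomes
})
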