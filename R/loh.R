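#' Compute ratio-of-coverage (RC) values from allele-specific counts
#'
#' RC for an allele at a marker is its read count divided by the
#' genome-wide mean per-site total count, so that at an unaltered
#' heterozygous site each allele has expectation 0.5, a duplicated allele
#' approaches 1.0 and a lost allele approaches 0.
#'
#' @param counts data.frame from \code{\link{simulate_allele_counts}} (or
#'   the same layout read from disk): chrom, pos and two \code{count_*}
#'   columns named after the haplotypes.
#' @return the input with added numeric columns \code{rc_<hap>} for each
#'   haplotype, plus attribute \code{haplotypes}.
#' @export
compute_rc <- function(counts) {
  cc <- grep("^count_", names(counts), value = TRUE)
  if (length(cc) != 2L)
    stop("counts must have exactly two count_<haplotype> columns")
  haps <- sub("^count_", "", cc)
  tot <- counts[[cc[1]]] + counts[[cc[2]]]
  if (all(tot == 0)) stop("all counts are zero")
  denom <- mean(tot)
  if (nrow(counts) < 100L)
    warning("fewer than 100 markers; RC normalization may be unstable")
  counts[[paste0("rc_", haps[1])]] <- counts[[cc[1]]] / denom
  counts[[paste0("rc_", haps[2])]] <- counts[[cc[2]]] / denom
  attr(counts, "haplotypes") <- haps
  counts
}

#' Classify markers into zygosity states and segment chromosomes
#'
#' Each marker is assigned het / hom_<hap> / unclassified by band
#' membership of its site-normalized allele fractions (each haplotype's RC
#' divided by the marker's total RC, which cancels per-site depth
#' fluctuation; at normal copy number the fraction and the RC coincide, so
#' the band anchors 0.5 / 1.0 / 0 are unchanged).  Per-chromosome runs are
#' then consolidated: a state change
#' requires at least \code{min_run} consecutive concordant markers.
#' Shorter runs are absorbed into the flanking state; an absorbed isolated
#' homozygous marker is reported as a flagged single-SNP candidate (the
#' class of event detectable by sequencing but too small for segmental
#' calling).  Band-edge ties resolve toward heterozygosity.
#'
#' @param rc_table output of \code{\link{compute_rc}}.
#' @param het_band RC interval (both alleles) for heterozygosity, default
#'   \code{c(0.35, 0.65)}.
#' @param hom_high minimum RC of the retained allele for homozygosity,
#'   default 0.8.
#' @param hom_low maximum RC of the lost allele, default 0.15.
#' @param min_run minimum consecutive concordant markers to open a
#'   segment, default 2.
#' @param max_unclassified maximum tolerated fraction of unclassifiable
#'   markers, default 0.2.
#' @return list with \code{segments} (data.frame: chrom, start_idx,
#'   end_idx, start_pos, end_pos, state, n_snps, mean RC per haplotype) and
#'   \code{single_snp_candidates} (data.frame of flagged isolated
#'   markers).
#' @export
call_genotype_states <- function(rc_table,
                                 het_band = c(0.35, 0.65),
                                 hom_high = 0.8, hom_low = 0.15,
                                 min_run = 2L,
                                 max_unclassified = 0.2) {
  haps <- attr(rc_table, "haplotypes")
  if (is.null(haps))
    haps <- sub("^rc_", "", grep("^rc_", names(rc_table), value = TRUE))
  if (length(haps) != 2L) stop("need two rc_<haplotype> columns")
  if (het_band[2] > hom_high || hom_low > het_band[1])
    stop("het and hom RC bands must be disjoint")
  rc1 <- rc_table[[paste0("rc_", haps[1])]]
  rc2 <- rc_table[[paste0("rc_", haps[2])]]
  tot <- rc1 + rc2
  f1 <- ifelse(tot > 0, rc1 / tot, NA_real_)   # site-normalized fractions
  f2 <- ifelse(tot > 0, rc2 / tot, NA_real_)
  # het checked first: ties at shared band edges resolve to heterozygosity
  state <- rep(NA_character_, nrow(rc_table))
  is_het <- !is.na(f1) & f1 >= het_band[1] & f1 <= het_band[2] &
            f2 >= het_band[1] & f2 <= het_band[2]
  is_h1 <- !is.na(f1) & !is_het & f1 >= hom_high & f2 <= hom_low
  is_h2 <- !is.na(f1) & !is_het & f2 >= hom_high & f1 <= hom_low
  state[is_het] <- "het"
  state[is_h1] <- paste0("hom_", haps[1])
  state[is_h2] <- paste0("hom_", haps[2])
  frac_na <- mean(is.na(state))
  if (frac_na > max_unclassified) {
    bad <- which(is.na(state))
    stop(sprintf(
      "quality failure: %.1f%% of markers unclassifiable (first offenders: %s)",
      100 * frac_na,
      paste(utils::head(paste0(rc_table$chrom[bad], ":",
                               rc_table$pos[bad]), 5), collapse = ", ")))
  }
  segs <- list(); cands <- list()
  for (ch in unique(rc_table$chrom)) {
    idx <- which(rc_table$chrom == ch)
    st <- state[idx]
    cls <- which(!is.na(st))           # classified markers only
    if (length(cls) == 0L) next
    s <- st[cls]
    r <- rle(s)
    # absorb runs shorter than min_run into the flanking state
    if (length(r$lengths) > 1L) {
      repeat {
        short <- which(r$lengths < min_run)
        if (length(short) == 0L || length(r$lengths) == 1L) break
        j <- short[1]
        absorbed_state <- r$values[j]
        into <- if (j == 1L) r$values[2] else r$values[j - 1]
        if (r$lengths[j] == 1L && grepl("^hom_", absorbed_state) &&
            into == "het") {
          k <- cls[sum(r$lengths[seq_len(j - 1)]) + 1L]
          cands[[length(cands) + 1L]] <- data.frame(
            chrom = ch, pos = rc_table$pos[idx[k]],
            state = absorbed_state, stringsAsFactors = FALSE)
        }
        r$values[j] <- into
        r <- rle(inverse.rle(r))
      }
    }
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in seq_along(r$values)) {
      ii <- idx[cls[starts[k]:ends[k]]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch,
        start_idx = ii[1], end_idx = ii[length(ii)],
        start_pos = rc_table$pos[ii[1]],
        end_pos = rc_table$pos[ii[length(ii)]],
        state = r$values[k], n_snps = length(ii),
        mean_rc_1 = mean(rc1[ii]), mean_rc_2 = mean(rc2[ii]),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  names(segments)[names(segments) == "mean_rc_1"] <- paste0("mean_rc_", haps[1])
  names(segments)[names(segments) == "mean_rc_2"] <- paste0("mean_rc_", haps[2])
  single <- if (length(cands)) do.call(rbind, cands) else
    data.frame(chrom = character(0), pos = integer(0),
               state = character(0), stringsAsFactors = FALSE)
  list(segments = segments, single_snp_candidates = single,
       haplotypes = haps)
}

#' Breakpoint interval between a flanking het marker and the first hom marker
#'
#' The recombination-initiating lesion presumably lies between the last
#' heterozygous marker and the first homozygous marker of the transition;
#' the interval is reported half-open, \code{(het_pos, hom_pos]}, with its
#' midpoint for plotting and enrichment.  When no proximal het marker
#' exists (the event reaches the first marker of the arm) the interval is
#' clipped to the arm start and flagged.
#'
#' @param het_pos position of the last heterozygous marker (or NA).
#' @param hom_pos position of the first homozygous marker.
#' @return list with \code{start}, \code{end}, \code{midpoint},
#'   \code{clipped}.
#' @export
breakpoint_interval <- function(het_pos, hom_pos) {
  if (is.na(het_pos)) {
    list(start = 1, end = hom_pos, midpoint = (1 + hom_pos) / 2,
         clipped = TRUE)
  } else {
    list(start = het_pos, end = hom_pos,
         midpoint = (het_pos + hom_pos) / 2, clipped = FALSE)
  }
}

#' Convert genotype segments into classified LOH events
#'
#' Homozygous segments become events: a segment containing the terminal
#' marker of a chromosome is a terminal (T-LOH) event, an interior segment
#' an interstitial (I-LOH) event.  Events on the same chromosome separated
#' by fewer than \code{merge_gap} heterozygous markers are merged into one
#' complex event; the merged class vocabulary follows the standard color
#' code: CON (simple I-LOH), CON/CON (complex I-LOH), CO/CON (T-LOH with an
#' associated I-LOH), CO/BIR (T-LOH; crossover and BIR cannot be
#' distinguished in a single colony without the reciprocal product, so the
#' class is reported jointly).  The recipient is the haplotype whose
#' alleles were lost (the lesion carrier).
#'
#' @param states output of \code{\link{call_genotype_states}}.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param centromeres named centromere positions (bp) (currently carried
#'   through for annotation).
#' @param merge_gap events separated by fewer than this many het markers
#'   merge into one complex event (default 10).
#' @return data.frame of events: chrom, type (I-LOH/T-LOH), class,
#'   complexity, retained, recipient, start_pos, end_pos, n_snps,
#'   breakpoint intervals (bp1_*/bp2_*) and midpoints.
#' @export
segment_to_events <- function(states, chrom_lengths, centromeres = NULL,
                              merge_gap = 10L) {
  segments <- states$segments
  haps <- states$haplotypes
  out <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start_idx), , drop = FALSE]
    hom <- which(seg$state != "het")
    if (length(hom) == 0L) next
    first_idx <- seg$start_idx[1]
    last_idx <- seg$end_idx[nrow(seg)]
    # group hom segments separated by < merge_gap het markers
    grp <- integer(length(hom)); g <- 1L; grp[1] <- 1L
    if (length(hom) > 1L) {
      for (k in 2:length(hom)) {
        between <- seg[(hom[k - 1] + 1):(hom[k] - 1), , drop = FALSE]
        gap_snps <- sum(between$n_snps[between$state == "het"])
        if (gap_snps >= merge_gap) g <- g + 1L
        grp[k] <- g
      }
    }
    for (gg in unique(grp)) {
      members <- seg[hom[grp == gg], , drop = FALSE]
      terminal <- any(members$start_idx == first_idx |
                      members$end_idx == last_idx)
      n_blocks <- nrow(members)
      type <- if (terminal) "T-LOH" else "I-LOH"
      class <- if (terminal && n_blocks > 1L) "CO/CON"
               else if (terminal) "CO/BIR"
               else if (n_blocks > 1L) "CON/CON"
               else "CON"
      complexity <- if (n_blocks > 1L) "complex" else "simple"
      retained_states <- sub("^hom_", "", members$state)
      retained <- names(sort(table(retained_states), decreasing = TRUE))[1]
      recipient <- haps[haps != retained]
      s_pos <- min(members$start_pos); e_pos <- max(members$end_pos)
      left_terminal <- any(members$start_idx == first_idx)
      right_terminal <- any(members$end_idx == last_idx)
      rows <- hom[grp == gg]
      # left-side transition: last het marker of the segment preceding the
      # event in the ordered segment frame (unclassified markers between
      # segments do not break adjacency)
      prev_row <- min(rows) - 1L
      bp1 <- breakpoint_interval(
        if (prev_row >= 1L && seg$state[prev_row] == "het")
          seg$end_pos[prev_row] else NA, s_pos)
      # right-side transition: first het marker after the event; interval
      # [last hom, first het), midpoint analogous
      nxt_row <- max(rows) + 1L
      nxt <- if (nxt_row <= nrow(seg) && seg$state[nxt_row] == "het")
        seg[nxt_row, , drop = FALSE] else seg[0, , drop = FALSE]
      bp2 <- if (nrow(nxt))
        list(start = e_pos, end = nxt$start_pos[1],
             midpoint = (e_pos + nxt$start_pos[1]) / 2, clipped = FALSE)
      else list(start = NA_real_, end = NA_real_, midpoint = NA_real_,
                clipped = NA)
      # primary breakpoint: the transition adjacent to heterozygosity on
      # the centromere-proximal side; for a left-arm terminal event that is
      # the right-side transition
      bp_mid <- if (left_terminal && !right_terminal && !is.na(bp2$midpoint))
        bp2$midpoint else bp1$midpoint
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, type = type, class = class, complexity = complexity,
        retained = retained, recipient = recipient,
        start_pos = s_pos, end_pos = e_pos,
        n_snps = sum(members$n_snps),
        bp1_start = bp1$start, bp1_end = bp1$end,
        bp1_mid = bp1$midpoint, bp1_clipped = bp1$clipped,
        bp2_start = bp2$start, bp2_end = bp2$end, bp2_mid = bp2$midpoint,
        bp_mid = bp_mid,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), type = character(0),
                      class = character(0), complexity = character(0),
                      retained = character(0), recipient = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_snps = integer(0), bp1_start = numeric(0),
                      bp1_end = numeric(0), bp1_mid = numeric(0),
                      bp1_clipped = logical(0), bp2_start = numeric(0),
                      bp2_end = numeric(0), bp2_mid = numeric(0),
                      bp_mid = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call LOH events from an allele-specific count table
#'
#' Convenience pipeline: \code{\link{compute_rc}} then
#' \code{\link{call_genotype_states}} then \code{\link{segment_to_events}}.
#'
#' @param counts allele-specific count table.
#' @param chrom_lengths,centromeres genome annotation.
#' @param ... passed to \code{\link{call_genotype_states}} and
#'   \code{merge_gap} to \code{\link{segment_to_events}}.
#' @param merge_gap see \code{\link{segment_to_events}}.
#' @return event data.frame (see \code{\link{segment_to_events}}).
#' @export
call_loh <- function(counts, chrom_lengths, centromeres = NULL,
                     merge_gap = 10L, ...) {
  rc <- compute_rc(counts)
  st <- call_genotype_states(rc, ...)
  segment_to_events(st, chrom_lengths, centromeres, merge_gap = merge_gap)
}

#' Compare two event sets (e.g. subclones of one zygote colony)
#'
#' Events match when they lie on the same chromosome, have the same type
#' and retained haplotype, and their proximal breakpoint midpoints are
#' within \code{tol} bp.  Matching is greedy by increasing midpoint
#' distance; each event matches at most once.
#'
#' @param a,b event data.frames from \code{\link{segment_to_events}}.
#' @param tol midpoint tolerance in bp (default 10000).
#' @return list with \code{shared} (data.frame of index pairs),
#'   \code{a_only}, \code{b_only} (row indices) and \code{counts}.
#' @export
compare_event_sets <- function(a, b, tol = 10000) {
  used_b <- rep(FALSE, nrow(b))
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    cand <- which(!used_b & b$chrom == a$chrom[i] & b$type == a$type[i] &
                  b$retained == a$retained[i] &
                  abs(b$bp_mid - a$bp_mid[i]) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(b$bp_mid[cand] - a$bp_mid[i]))]
      used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  shared <- if (length(pairs))
    as.data.frame(do.call(rbind, pairs)) else
    data.frame(V1 = integer(0), V2 = integer(0))
  names(shared) <- c("a_idx", "b_idx")
  a_only <- setdiff(seq_len(nrow(a)), shared$a_idx)
  b_only <- which(!used_b)
  list(shared = shared, a_only = a_only, b_only = b_only,
       counts = c(shared = nrow(shared), a_only = length(a_only),
                  b_only = length(b_only)))
}
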