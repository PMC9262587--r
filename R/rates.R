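#' Baseline rates used for fold-change comparisons
#'
#' Wild-type per-division rates measured in isogenic unperturbed diploids,
#' the divisions needed to grow a colony from one cell, and the estimated
#' ratio of sister-chromatid to inter-homolog double-strand-break repair.
#'
#' @param loh_wt wild-type LOH rate per cell division (default 4.6e-3).
#' @param upd_wt wild-type UPD rate per cell division (default 4e-6).
#' @param divisions_per_colony cell divisions to form a colony (default
#'   25).
#' @param sister_ratio sister-chromatid : inter-homolog repair ratio
#'   (default 20).
#' @return list of class \code{rate_baselines}.
#' @export
rate_baselines <- function(loh_wt = 4.6e-3, upd_wt = 4e-6,
                           divisions_per_colony = 25,
                           sister_ratio = 20) {
  stopifnot(loh_wt > 0, upd_wt > 0, divisions_per_colony > 0,
            sister_ratio >= 0)
  structure(list(loh_wt = loh_wt, upd_wt = upd_wt,
                 divisions_per_colony = divisions_per_colony,
                 sister_ratio = sister_ratio),
            class = "rate_baselines")
}

#' Event rate per cell division
#'
#' rate = n_events / (n_isolates x divisions).  Under the colony
#' assumption divisions is the ~25 divisions needed to form a colony;
#' under the first-division assumption divisions = 1.
#'
#' @param n_events total events observed across isolates (>= 0).
#' @param n_isolates number of independent isolates (> 0).
#' @param divisions cell divisions per isolate (> 0).
#' @return list with \code{rate} (raw) and \code{rate_rounded} (two
#'   significant figures, the reporting convention used throughout).
#' @export
event_rate <- function(n_events, n_isolates, divisions) {
  if (n_isolates <= 0 || divisions <= 0)
    stop("n_isolates and divisions must be > 0")
  if (n_events < 0) stop("n_events must be >= 0")
  r <- n_events / (n_isolates * divisions)
  list(rate = r, rate_rounded = signif(r, 2))
}

#' Fold change of a rate over a baseline
#'
#' @param rate observed rate.
#' @param baseline baseline rate (> 0).
#' @return list with \code{fold} (raw) and \code{fold_rounded} (two
#'   significant figures).
#' @export
fold_change <- function(rate, baseline) {
  if (baseline <= 0) stop("baseline must be > 0")
  f <- rate / baseline
  list(fold = f, fold_rounded = signif(f, 2))
}

#' Extrapolate total DSBs per isolate from inter-homolog events
#'
#' Inter-homolog recombination reveals only a fraction of double-strand
#' breaks because most are repaired invisibly off the sister chromatid;
#' the total is extrapolated as observed events x the sister:homolog
#' repair ratio.
#'
#' @param events_per_isolate observed inter-homolog events per isolate.
#' @param sister_ratio sister:homolog repair ratio (default 20).
#' @return estimated DSBs per isolate.
#' @export
dsb_extrapolation <- function(events_per_isolate, sister_ratio = 20) {
  if (sister_ratio < 0) stop("sister_ratio must be >= 0")
  events_per_isolate * sister_ratio
}

#' Expected LOH events at a locus from its genome fraction
#'
#' Under a uniform breakpoint model the expected number of terminal LOH
#' events homozygosing a locus equals the total T-LOH count times the
#' genome fraction of the centromere-to-locus interval.  Reported with a
#' 1-df binomial chi-square and an exact Poisson alternative.
#'
#' @param n_tloh total T-LOH events observed.
#' @param genome_fraction fraction of the genome in the interval, in
#'   [0, 1].
#' @param observed observed events at the locus (optional; enables the
#'   tests).
#' @return list with \code{expected}, \code{expected_rounded} and, when
#'   \code{observed} is given, \code{chisq}, \code{p_chisq},
#'   \code{p_poisson}.
#' @export
locus_loh_expectation <- function(n_tloh, genome_fraction,
                                  observed = NULL) {
  if (genome_fraction < 0 || genome_fraction > 1)
    stop("genome_fraction must be in [0, 1]")
  expected <- n_tloh * genome_fraction
  out <- list(expected = expected, expected_rounded = round(expected))
  if (!is.null(observed)) {
    if (expected > 0 && expected < n_tloh) {
      e <- c(expected, n_tloh - expected)
      o <- c(observed, n_tloh - observed)
      out$chisq <- sum((o - e)^2 / e)
      out$p_chisq <- stats::pchisq(out$chisq, df = 1, lower.tail = FALSE)
    } else {
      out$chisq <- if (observed == expected) 0 else Inf
      out$p_chisq <- if (observed == expected) 1 else 0
    }
    out$p_poisson <- if (expected > 0)
      stats::poisson.test(observed, r = expected)$p.value
    else as.numeric(observed == 0)
  }
  out
}

# merge overlapping/adjacent intervals; m is a 2-col matrix (start, end)
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i] }
  }
  cbind(c(outs, ms), c(oute, me))
}

# number of breakpoint midpoints falling in the tol-expanded, merged
# footprint of a class; also returns the footprint size in bp
.class_overlap <- function(mids, elements, chrom_lengths, tol) {
  hits <- 0L; foot <- 0
  for (ch in unique(elements$chrom)) {
    L <- chrom_lengths[[ch]]
    e <- elements[elements$chrom == ch, , drop = FALSE]
    m <- .merge_intervals(pmax(1, e$start - tol), pmin(L, e$end + tol))
    foot <- foot + sum(m[, 2] - m[, 1] + 1)
    pm <- mids$pos[mids$chrom == ch]
    if (length(pm))
      hits <- hits + sum(vapply(pm, function(p)
        any(p >= m[, 1] & p <= m[, 2]), logical(1)))
  }
  list(hits = hits, footprint = foot)
}

#' Breakpoint enrichment at annotated chromosome elements
#'
#' For each element class, counts LOH breakpoint midpoints falling within
#' \code{tol} bp of a class interval and tests enrichment against the
#' class's genomic footprint.  The primary test is a Fisher 2x2 comparing
#' breakpoints in/out of the footprint with genome kilobases in/out of the
#' footprint (the genome discretised at the ~1 kb marker spacing); an
#' optional permutation test (uniform re-placement of the breakpoints)
#' serves as a calibration oracle.  P-values are corrected across classes
#' (Bonferroni by default).
#'
#' @param breakpoints data.frame with \code{chrom}, \code{pos} (midpoints).
#' @param elements annotation data.frame: \code{class}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param chrom_lengths named chromosome lengths.
#' @param tol overlap tolerance in bp (default 1000, one marker spacing).
#' @param correction \code{p.adjust} method (default "bonferroni"; "BH"
#'   available).
#' @param n_perm permutations for the permutation p-value (0 = skip).
#' @param seed seed for the permutation null.
#' @return data.frame per class: observed, expected, footprint_bp,
#'   p_fisher, p_perm (NA if skipped), p_adj, significant (at alpha =
#'   0.05 after correction).  Classes with zero footprint are skipped with
#'   a warning.
#' @export
element_enrichment <- function(breakpoints, elements, chrom_lengths,
                               tol = 1000, correction = "bonferroni",
                               n_perm = 0L, seed = 1L) {
  if (nrow(breakpoints) == 0L) stop("empty breakpoint list")
  classes <- unique(elements$class)
  if (length(classes) == 0L) stop("no element classes")
  n <- nrow(breakpoints)
  genome_bp <- sum(as.numeric(chrom_lengths))
  kb <- 1000
  rows <- list()
  perm_hits <- NULL
  if (n_perm > 0L) {
    set.seed(seed)
    cum <- cumsum(as.numeric(chrom_lengths))
    perm_sets <- lapply(seq_len(n_perm), function(k) {
      u <- stats::runif(n, 0, genome_bp)
      ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      data.frame(chrom = names(chrom_lengths)[ci],
                 pos = u - c(0, cum)[ci], stringsAsFactors = FALSE)
    })
  }
  for (cl in classes) {
    e <- elements[elements$class == cl, , drop = FALSE]
    e <- e[e$end >= e$start, , drop = FALSE]
    if (nrow(e) == 0L || sum(e$end - e$start + 1) <= 0) {
      warning("class '", cl, "' has zero genomic footprint; skipped")
      next
    }
    ov <- .class_overlap(breakpoints, e, chrom_lengths, tol)
    p_class <- ov$footprint / genome_bp
    expected <- n * p_class
    tab <- rbind(c(ov$hits, n - ov$hits),
                 pmax(1, round(c(ov$footprint, genome_bp - ov$footprint) / kb)))
    p_fisher <- stats::fisher.test(tab, alternative = "greater")$p.value
    p_perm <- NA_real_
    if (n_perm > 0L) {
      null_hits <- vapply(perm_sets, function(ps)
        .class_overlap(ps, e, chrom_lengths, tol)$hits, integer(1))
      p_perm <- (1 + sum(null_hits >= ov$hits)) / (1 + n_perm)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, observed = ov$hits, expected = expected,
      footprint_bp = ov$footprint, p_fisher = p_fisher, p_perm = p_perm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_fisher, method = correction)
  res$significant <- res$p_adj < 0.05
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher exact test on a 2x2 viability table
#'
#' @param tab 2x2 matrix of non-negative integer counts (e.g. viable /
#'   inviable by genotype).
#' @return list with \code{odds_ratio} and \code{p}.
#' @export
viability_fisher <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero margin")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Find tandem-repeat regions in a sequence
#'
#' Reports maximal regions of length >= \code{min_len} bp consisting of at
#' least two adjacent copies (the final copy may be partial) of a unit
#' whose size lies within \code{unit_range}.  For each unit size u the
#' scan marks positions where the base u steps back is identical; a
#' maximal run of L such matches starting at i is a region of length
#' L + u with L/u + 1 copies.  Regions are reported per unit size;
#' \code{dedupe = TRUE} keeps, among regions with identical spans, the one
#' with the smallest unit.
#'
#' @param sequence a character string (or DNAString).
#' @param min_len minimum region length in bp (default 24).
#' @param unit_range allowed unit sizes, default \code{c(1, 1998)}.
#' @param dedupe drop same-span duplicates with larger units (default
#'   TRUE).
#' @return data.frame: start, end, length, unit_size, unit, copies.
#' @export
find_tandem_repeats <- function(sequence, min_len = 24,
                                unit_range = c(1, 1998), dedupe = TRUE) {
  s <- as.character(sequence)
  if (nchar(s) == 0L) stop("empty sequence")
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  umax <- min(unit_range[2], floor(n / 2))
  rows <- list()
  for (u in seq.int(max(1, unit_range[1]), umax)) {
    eq <- x[(1 + u):n] == x[1:(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      L <- r$lengths[k]
      if (L < u) next                      # fewer than 2 copies
      reg_len <- L + u
      if (reg_len < min_len) next
      i <- starts[k]
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, end = i + reg_len - 1L, length = reg_len,
        unit_size = u, unit = substr(s, i, i + u - 1L),
        copies = reg_len / u, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), unit_size = integer(0),
                      unit = character(0), copies = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  if (dedupe) {
    res <- res[order(res$start, res$end, res$unit_size), , drop = FALSE]
    res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
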