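#' Plan genome-instability events for the simulator
#'
#' An event plan is a data.frame with one row per requested event.  Columns
#' that are \code{NA} are resolved by sampling when the plan is applied:
#' chromosomes are drawn weighted by length, positions uniformly per bp
#' (the observed breakpoints show no pronounced hotspots), and conversion
#' tract lengths from a lognormal whose median is 10 kb for
#' crossover-associated conversions and 3 kb for unassociated ones.
#'
#' @param kind character vector of event kinds; each must be one of
#'   "conversion", "crossover", "BIR", "UPD", "monosomy", "trisomy",
#'   "deletion", "duplication", "translocation", "SNV", "indel",
#'   "rdna_resize".
#' @param chrom,start,end optional explicit coordinates (1-based
#'   inclusive); \code{NA} entries are sampled.
#' @param recipient haplotype carrying the recombination-initiating lesion
#'   (the haplotype whose alleles are lost); \code{NA} = use
#'   \code{default_recipient} of \code{\link{apply_events}}.
#' @param tract_median,tract_sigma lognormal tract parameters for
#'   conversions (bp); defaults 3000 and 0.9 (\code{tract_median} is
#'   ignored for non-conversions).
#' @param chrom2,start2,end2 second locus for translocations
#'   (terminal-duplication side).
#' @param ref,alt,read_frac mutation fields for SNV/indel rows.
#' @return data.frame of class \code{event_plan}.
#' @export
event_plan <- function(kind, chrom = NA, start = NA, end = NA,
                       recipient = NA,
                       tract_median = NA, tract_sigma = 0.9,
                       chrom2 = NA, start2 = NA, end2 = NA,
                       ref = NA, alt = NA, read_frac = NA) {
  kinds <- c("conversion", "crossover", "BIR", "UPD", "monosomy", "trisomy",
             "deletion", "duplication", "translocation", "SNV", "indel",
             "rdna_resize")
  if (!all(kind %in% kinds))
    stop("unknown event kind(s): ",
         paste(setdiff(kind, kinds), collapse = ", "))
  if (length(kind) == 0L) {
    out <- data.frame(kind = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      recipient = character(0), tract_median = numeric(0),
                      tract_sigma = numeric(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      ref = character(0), alt = character(0),
                      read_frac = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("event_plan", "data.frame")
    return(out)
  }
  out <- data.frame(kind = kind, chrom = chrom, start = start, end = end,
                    recipient = recipient,
                    tract_median = tract_median, tract_sigma = tract_sigma,
                    chrom2 = chrom2, start2 = start2, end2 = end2,
                    ref = ref, alt = alt, read_frac = read_frac,
                    stringsAsFactors = FALSE)
  class(out) <- c("event_plan", "data.frame")
  out
}

.empty_ledger <- function(haps) {
  data.frame(event_id = integer(0), kind = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             recipient = character(0), retained = character(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             breakpoint = integer(0),
             ref = character(0), alt = character(0),
             read_frac = numeric(0),
             stringsAsFactors = FALSE)
}

# lognormal with a given median: meanlog = log(median)
.rtract <- function(median_bp, sigma) {
  max(1L, as.integer(round(stats::rlnorm(1, meanlog = log(median_bp),
                                         sdlog = sigma))))
}

.other_hap <- function(h, haps) haps[haps != h]

# set per-haplotype copy number over an interval of one chromosome
.set_cn <- function(genome, chrom, start, end, hap, value) {
  col <- paste0("cn_", hap)
  i <- genome$snps$chrom == chrom & genome$snps$pos >= start &
       genome$snps$pos <= end
  genome$snps[[col]][i] <- as.integer(value)
  genome
}

#' Plant instability events into a hybrid genome
#'
#' Applies each planned event, sampling any unresolved coordinates, and
#' returns the modified genome together with a ground-truth ledger whose
#' rows carry fully resolved coordinates.  Replaying the ledger on a fresh
#' copy of the same genome (\code{\link{apply_ledger}}) reproduces the
#' modified genome exactly.
#'
#' Marker-level semantics (copy numbers of the two haplotype alleles):
#' \itemize{
#'   \item conversion: recipient alleles replaced by donor alleles over the
#'     tract (0/2), flanks untouched;
#'   \item crossover / BIR: all markers distal to the breakpoint (toward
#'     the telomere of the arm containing it) become homozygous for the
#'     donor haplotype;
#'   \item UPD: whole chromosome set to two copies of the retained
#'     haplotype (total stays 2);
#'   \item monosomy / trisomy: one haplotype dropped to 0 / raised to 2;
#'   \item deletion / duplication: one haplotype's copy set to 0 / 2 over
#'     the interval;
#'   \item translocation: coupled terminal deletion on \code{chrom} distal
#'     to \code{start} and terminal duplication on \code{chrom2} of the
#'     terminal segment bounded by \code{start2}; both breakpoints must lie
#'     within \code{repeat_tol} of an annotated repeat element;
#'   \item SNV / indel / rdna_resize: recorded in the ledger (and, for
#'     rdna_resize, in the genome's repeat counts) without touching the
#'     marker map.
#' }
#'
#' @param genome a \code{\link{build_hybrid_genome}} result.
#' @param plan an \code{\link{event_plan}}.
#' @param seed integer seed for coordinate sampling.
#' @param default_recipient haplotype used when a row has no recipient
#'   (default: first haplotype, the lesion-carrying parent).
#' @param repeat_classes element classes acceptable as translocation
#'   breakpoints.
#' @param repeat_tol max distance (bp) from a translocation breakpoint to a
#'   repeat element.
#' @return list with \code{genome} (modified) and \code{ledger}
#'   (data.frame, one row per realized event).
#' @export
apply_events <- function(genome, plan, seed = 1L,
                         default_recipient = NULL,
                         repeat_classes = c("Ty", "delta"),
                         repeat_tol = 2000) {
  stopifnot(inherits(genome, "hybrid_genome"))
  haps <- genome$config$haplotypes
  if (is.null(default_recipient)) default_recipient <- haps[1]
  set.seed(seed)
  cl <- genome$config$chrom_lengths
  cen <- genome$config$centromeres
  ledger <- .empty_ledger(haps)
  if (nrow(plan) == 0L)
    return(list(genome = genome, ledger = ledger))
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    kind <- ev$kind
    recip <- if (is.na(ev$recipient)) default_recipient else ev$recipient
    if (!recip %in% haps) stop("unknown recipient haplotype: ", recip)
    donor <- .other_hap(recip, haps)
    chrom <- ev$chrom
    if (is.na(chrom) && !kind %in% c("rdna_resize"))
      chrom <- sample(names(cl), 1, prob = as.numeric(cl))
    if (!is.na(chrom) && !chrom %in% names(cl))
      stop("event references unknown chromosome: ", chrom)
    row <- data.frame(event_id = i, kind = kind, chrom = NA, start = NA,
                      end = NA, recipient = recip, retained = donor,
                      chrom2 = NA, start2 = NA, end2 = NA, breakpoint = NA,
                      ref = NA, alt = NA, read_frac = NA,
                      stringsAsFactors = FALSE)
    if (kind == "conversion") {
      med <- if (is.na(ev$tract_median)) 3000 else ev$tract_median
      if (is.na(ev$start)) {
        len <- .rtract(med, ev$tract_sigma)
        s <- sample.int(max(1L, cl[[chrom]] - len), 1)
        e <- min(cl[[chrom]], s + len - 1L)
      } else {
        s <- ev$start
        e <- if (is.na(ev$end)) min(cl[[chrom]],
                                    ev$start + .rtract(med, ev$tract_sigma) - 1L)
             else ev$end
      }
      if (e < s) stop("conversion tract has non-positive length")
      genome <- .set_cn(genome, chrom, s, e, recip, 0L)
      genome <- .set_cn(genome, chrom, s, e, donor, 2L)
      row$chrom <- chrom; row$start <- s; row$end <- e; row$breakpoint <- s
    } else if (kind %in% c("crossover", "BIR")) {
      p <- if (is.na(ev$start)) sample.int(cl[[chrom]], 1) else ev$start
      # LOH extends from the breakpoint to the telomere of the arm
      if (p > cen[[chrom]]) { s <- p; e <- cl[[chrom]] }
      else                  { s <- 1L; e <- p }
      genome <- .set_cn(genome, chrom, s, e, recip, 0L)
      genome <- .set_cn(genome, chrom, s, e, donor, 2L)
      row$chrom <- chrom; row$start <- s; row$end <- e; row$breakpoint <- p
    } else if (kind == "UPD") {
      genome <- .set_cn(genome, chrom, 1L, cl[[chrom]], recip, 0L)
      genome <- .set_cn(genome, chrom, 1L, cl[[chrom]], donor, 2L)
      row$chrom <- chrom; row$start <- 1L; row$end <- cl[[chrom]]
    } else if (kind == "monosomy") {
      genome <- .set_cn(genome, chrom, 1L, cl[[chrom]], recip, 0L)
      row$chrom <- chrom; row$start <- 1L; row$end <- cl[[chrom]]
      row$retained <- donor
    } else if (kind == "trisomy") {
      gained <- if (is.na(ev$recipient)) haps[2] else ev$recipient
      genome <- .set_cn(genome, chrom, 1L, cl[[chrom]], gained, 2L)
      row$chrom <- chrom; row$start <- 1L; row$end <- cl[[chrom]]
      row$recipient <- gained; row$retained <- gained
    } else if (kind %in% c("deletion", "duplication")) {
      if (is.na(ev$start) || is.na(ev$end))
        stop(kind, " events require explicit start/end")
      val <- if (kind == "deletion") 0L else 2L
      genome <- .set_cn(genome, chrom, ev$start, ev$end, recip, val)
      row$chrom <- chrom; row$start <- ev$start; row$end <- ev$end
      row$retained <- recip
    } else if (kind == "translocation") {
      if (is.na(ev$start) || is.na(ev$chrom2) || is.na(ev$start2))
        stop("translocation events require chrom/start and chrom2/start2")
      els <- genome$config$elements
      .near_repeat <- function(ch, p) {
        if (is.null(els)) return(FALSE)
        sel <- els$class %in% repeat_classes & els$chrom == ch
        any(sel & p >= els$start - repeat_tol & p <= els$end + repeat_tol)
      }
      if (!.near_repeat(chrom, ev$start) ||
          !.near_repeat(ev$chrom2, ev$start2))
        stop("translocation breakpoints are not within ", repeat_tol,
             " bp of an annotated repeat element (",
             paste(repeat_classes, collapse = "/"), ")")
      # terminal deletion distal to start on chrom
      if (ev$start > cen[[chrom]]) { s <- ev$start; e <- cl[[chrom]] }
      else                         { s <- 1L; e <- ev$start }
      genome <- .set_cn(genome, chrom, s, e, recip, 0L)
      # terminal duplication of the segment beyond start2 on chrom2
      if (ev$start2 > cen[[ev$chrom2]]) { s2 <- ev$start2; e2 <- cl[[ev$chrom2]] }
      else                              { s2 <- 1L; e2 <- ev$start2 }
      genome <- .set_cn(genome, ev$chrom2, s2, e2, recip, 2L)
      row$chrom <- chrom; row$start <- s; row$end <- e
      row$chrom2 <- ev$chrom2; row$start2 <- s2; row$end2 <- e2
      row$breakpoint <- ev$start
    } else if (kind %in% c("SNV", "indel")) {
      p <- if (is.na(ev$start)) sample.int(cl[[chrom]], 1) else ev$start
      row$chrom <- chrom; row$start <- p; row$end <- p
      row$ref <- if (is.na(ev$ref)) .sample_base(1, genome$config$gc)
                 else ev$ref
      row$alt <- if (is.na(ev$alt)) {
        if (kind == "SNV") sample(setdiff(c("A","C","G","T"), row$ref), 1)
        else ""  # deletion of ref
      } else ev$alt
      row$read_frac <- if (is.na(ev$read_frac)) 1.0 else ev$read_frac
      row$retained <- NA
    } else if (kind == "rdna_resize") {
      if (is.null(genome$rdna_repeats)) stop("genome has no rDNA locus")
      genome$rdna_repeats[recip] <- as.integer(ev$start)
      row$chrom <- genome$config$rdna$chrom
      row$start <- as.integer(ev$start)
      row$retained <- recip
    }
    ledger <- rbind(ledger, row)
  }
  for (col in c("kind", "chrom", "recipient", "retained", "chrom2",
                "ref", "alt"))
    ledger[[col]] <- as.character(ledger[[col]])
  for (col in c("event_id", "start", "end", "start2", "end2", "breakpoint"))
    ledger[[col]] <- as.integer(ledger[[col]])
  ledger$read_frac <- as.numeric(ledger$read_frac)
  rownames(ledger) <- NULL
  class(ledger) <- c("truth_ledger", "data.frame")
  list(genome = genome, ledger = ledger)
}

#' Replay a truth ledger onto a fresh genome
#'
#' Deterministically re-applies the realized events recorded in a ledger.
#' Used to verify that the ledger is a complete description of the
#' modifications.
#'
#' @param genome a fresh \code{\link{build_hybrid_genome}} result built
#'   from the same configuration.
#' @param ledger a truth ledger from \code{\link{apply_events}}.
#' @return the modified genome.
#' @export
apply_ledger <- function(genome, ledger) {
  haps <- genome$config$haplotypes
  cl <- genome$config$chrom_lengths
  for (i in seq_len(nrow(ledger))) {
    ev <- ledger[i, ]
    if (ev$kind %in% c("conversion", "crossover", "BIR", "UPD")) {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$recipient, 0L)
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$retained, 2L)
    } else if (ev$kind == "monosomy") {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$recipient, 0L)
    } else if (ev$kind == "trisomy") {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$retained, 2L)
    } else if (ev$kind == "deletion") {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$recipient, 0L)
    } else if (ev$kind == "duplication") {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$recipient, 2L)
    } else if (ev$kind == "translocation") {
      genome <- .set_cn(genome, ev$chrom, ev$start, ev$end, ev$recipient, 0L)
      genome <- .set_cn(genome, ev$chrom2, ev$start2, ev$end2,
                        ev$recipient, 2L)
    } else if (ev$kind == "rdna_resize") {
      genome$rdna_repeats[ev$retained] <- as.integer(ev$start)
    }
    # SNV/indel rows do not modify the marker map
  }
  genome
}
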