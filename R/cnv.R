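#' Windowed copy-number profile from allele-specific counts
#'
#' Tiles every chromosome with non-overlapping windows (default 1 kb, the
#' marker spacing) and converts window read counts into per-haplotype and
#' total copy-number estimates.  Normalization uses the genome-wide median
#' window total, which is robust to a few large CNVs: a disomic window has
#' total copy 2 and each haplotype copy 1.
#'
#' @param counts allele-specific count table (chrom, pos, count_<hap>).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param window window size in bp (default 1000).
#' @return object of class \code{copy_number_profile}: data.frame with
#'   chrom, start, end, n_snps, cn_<hap1>, cn_<hap2>, cn_total plus a
#'   per-chromosome summary in attribute \code{chrom_means}.
#' @export
copy_number_profile <- function(counts, chrom_lengths, window = 1000L) {
  cc <- grep("^count_", names(counts), value = TRUE)
  stopifnot(length(cc) == 2L)
  haps <- sub("^count_", "", cc)
  res <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    sel <- counts$chrom == ch
    if (!any(sel)) next
    bin <- findInterval(counts$pos[sel], starts)
    c1 <- tapply(counts[[cc[1]]][sel], factor(bin, levels = seq_along(starts)),
                 sum, default = NA_real_)
    c2 <- tapply(counts[[cc[2]]][sel], factor(bin, levels = seq_along(starts)),
                 sum, default = NA_real_)
    n <- tapply(rep(1L, sum(sel)), factor(bin, levels = seq_along(starts)),
                sum, default = 0L)
    res[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_snps = as.integer(n),
                            raw_1 = as.numeric(c1), raw_2 = as.numeric(c2),
                            stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, res)
  rownames(prof) <- NULL
  covered <- prof$n_snps > 0
  # per-marker rates so windows with different marker counts are comparable
  r1 <- prof$raw_1 / pmax(prof$n_snps, 1L)
  r2 <- prof$raw_2 / pmax(prof$n_snps, 1L)
  med_tot <- stats::median((r1 + r2)[covered])
  if (!is.finite(med_tot) || med_tot <= 0)
    stop("cannot normalize: zero median window coverage")
  prof[[paste0("cn_", haps[1])]] <- ifelse(covered, 2 * r1 / med_tot, NA_real_)
  prof[[paste0("cn_", haps[2])]] <- ifelse(covered, 2 * r2 / med_tot, NA_real_)
  prof$cn_total <- prof[[paste0("cn_", haps[1])]] +
    prof[[paste0("cn_", haps[2])]]
  prof$raw_1 <- NULL; prof$raw_2 <- NULL
  cm <- do.call(rbind, lapply(split(prof[covered, ], prof$chrom[covered]),
    function(d) data.frame(chrom = d$chrom[1],
                           mean_cn_total = mean(d$cn_total),
                           mean_cn_1 = mean(d[[paste0("cn_", haps[1])]]),
                           mean_cn_2 = mean(d[[paste0("cn_", haps[2])]]),
                           stringsAsFactors = FALSE)))
  names(cm)[3:4] <- paste0("mean_cn_", haps)
  attr(prof, "chrom_means") <- cm
  attr(prof, "haplotypes") <- haps
  attr(prof, "window") <- window
  class(prof) <- c("copy_number_profile", "data.frame")
  prof
}

#' Detect uniparental disomy and monosomy
#'
#' A chromosome that is homozygous end-to-end is a UPD candidate; the call
#' is UPD only when the total copy number stays at ~2 (loss of one homolog
#' followed by duplication of the other).  Whole-chromosome homozygosity at
#' copy ~1 is monosomy, not UPD.
#'
#' @param states genotype states from \code{\link{call_genotype_states}}.
#' @param profile a \code{\link{copy_number_profile}}.
#' @param cn_tol tolerance around the integer copy number (default 0.4).
#' @return data.frame of calls: kind ("UPD"/"monosomy"), chrom, retained
#'   haplotype, mean total copy number.
#' @export
detect_upd <- function(states, profile, cn_tol = 0.4) {
  segments <- states$segments
  cm <- attr(profile, "chrom_means")
  out <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (any(seg$state == "het")) next
    ret <- unique(sub("^hom_", "", seg$state))
    if (length(ret) != 1L) next   # mixed homozygosity, not whole-chrom UPD
    mt <- cm$mean_cn_total[cm$chrom == ch]
    if (length(mt) == 0L) next
    kind <- if (abs(mt - 2) <= cn_tol) "UPD"
            else if (abs(mt - 1) <= cn_tol) "monosomy"
            else NA_character_
    if (is.na(kind)) next
    out[[length(out) + 1L]] <- data.frame(
      kind = kind, chrom = ch, retained = ret, mean_cn_total = mt,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(0), chrom = character(0),
                      retained = character(0), mean_cn_total = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect large (default >= 5 kb) deletions and duplications
#'
#' Scans each haplotype's windowed copy number for contiguous runs near 0
#' (deletion of that haplotype's copy, i.e. a heterozygous deletion) or
#' near 2 (duplication), merges adjacent aberrant windows and keeps calls
#' spanning at least \code{min_size} bp.  Calls reaching a chromosome end
#' are flagged terminal.
#'
#' @param profile a \code{\link{copy_number_profile}}.
#' @param min_size minimum call size in bp (default 5000).
#' @param del_max window haplotype copy number below which a window is
#'   deleted (default 0.4).
#' @param dup_min window haplotype copy number above which a window is
#'   duplicated (default 1.6).
#' @return data.frame of calls: kind ("deletion"/"duplication"), chrom,
#'   start, end, size, haplotype, terminal.
#' @export
detect_large_cnv <- function(profile, min_size = 5000,
                             del_max = 0.4, dup_min = 1.6) {
  haps <- attr(profile, "haplotypes")
  out <- list()
  for (h in haps) {
    cn <- profile[[paste0("cn_", h)]]
    for (ch in unique(profile$chrom)) {
      sel <- which(profile$chrom == ch & !is.na(cn))
      if (length(sel) == 0L) next
      v <- cn[sel]
      stt <- ifelse(v <= del_max, "deletion",
                    ifelse(v >= dup_min, "duplication", "normal"))
      r <- rle(stt)
      ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
      for (k in seq_along(r$values)) {
        if (r$values[k] == "normal") next
        i1 <- sel[starts[k]]; i2 <- sel[ends[k]]
        size <- profile$end[i2] - profile$start[i1] + 1L
        if (size < min_size) next
        terminal <- starts[k] == 1L || ends[k] == length(sel)
        out[[length(out) + 1L]] <- data.frame(
          kind = r$values[k], chrom = ch,
          start = profile$start[i1], end = profile$end[i2],
          size = size, haplotype = h, terminal = terminal,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      size = integer(0), haplotype = character(0),
                      terminal = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict translocation size from a coupled terminal deletion/duplication
#'
#' A terminal deletion on one chromosome coupled with a terminal
#' duplication on another is the expected signature of a (single recovered
#' product of a) translocation mediated by recombination between dispersed
#' repeats.  The predicted size is the centromere-containing retained
#' portion of the deleted chromosome plus the duplicated terminal segment
#' of the other chromosome.  Both breakpoints must lie within
#' \code{repeat_tol} of an annotated repeat element, otherwise the
#' prediction is refused.
#'
#' @param deletion one-row terminal deletion call (from
#'   \code{\link{detect_large_cnv}} or equivalent fields kind, chrom,
#'   start, end).
#' @param duplication one-row terminal duplication call on a different
#'   chromosome.
#' @param chrom_lengths,centromeres genome annotation (named vectors).
#' @param elements element annotation data.frame (class, chrom, start,
#'   end); classes in \code{repeat_classes} are acceptable breakpoint
#'   partners.
#' @param repeat_classes default \code{c("Ty", "delta")}.
#' @param repeat_tol max breakpoint-to-element distance in bp (default
#'   2000).
#' @return data.frame with the predicted translocation: chromosomes,
#'   retained and duplicated spans, total predicted size, and the repeat
#'   elements at the breakpoints.
#' @export
predict_translocation <- function(deletion, duplication,
                                  chrom_lengths, centromeres, elements,
                                  repeat_classes = c("Ty", "delta"),
                                  repeat_tol = 2000) {
  if (deletion$chrom == duplication$chrom)
    stop("deletion and duplication must be on different chromosomes")
  .bp <- function(call) {
    # internal edge of a terminal call = breakpoint
    L <- chrom_lengths[[call$chrom]]
    if (call$end >= L) call$start else call$end
  }
  .elem <- function(ch, p) {
    sel <- elements$class %in% repeat_classes & elements$chrom == ch &
      p >= elements$start - repeat_tol & p <= elements$end + repeat_tol
    if (!any(sel)) return(NULL)
    elements[which(sel)[1], , drop = FALSE]
  }
  b_del <- .bp(deletion); b_dup <- .bp(duplication)
  e1 <- .elem(deletion$chrom, b_del)
  e2 <- .elem(duplication$chrom, b_dup)
  if (is.null(e1) || is.null(e2))
    stop("no repeat element (", paste(repeat_classes, collapse = "/"),
         ") within ", repeat_tol, " bp of the ",
         if (is.null(e1)) "deletion" else "duplication",
         " breakpoint; refusing to predict a translocation")
  cen_del <- centromeres[[deletion$chrom]]
  L_del <- chrom_lengths[[deletion$chrom]]
  # retained portion of the deleted chromosome = side with the centromere
  retained <- if (b_del >= cen_del) b_del else L_del - b_del + 1L
  L_dup <- chrom_lengths[[duplication$chrom]]
  dup_len <- duplication$end - duplication$start + 1L
  data.frame(kind = "predicted translocation",
             del_chrom = deletion$chrom, dup_chrom = duplication$chrom,
             del_breakpoint = b_del, dup_breakpoint = b_dup,
             retained_bp = as.numeric(retained),
             duplicated_bp = as.numeric(dup_len),
             predicted_size = as.numeric(retained) + as.numeric(dup_len),
             del_element = e1$class, dup_element = e2$class,
             stringsAsFactors = FALSE)
}

#' Haplotype-resolved rDNA repeat number from coverage
#'
#' Total repeats = 2 x (mean rDNA coverage / mean single-copy baseline
#' coverage); the per-haplotype split is proportional to the
#' haplotype-diagnostic read fractions within the locus.
#'
#' @param rdna_coverage per-position coverage inside the rRNA gene array.
#' @param baseline_coverage per-position coverage at disomic single-copy
#'   regions (must be free of CNV calls).
#' @param hap_counts named haplotype-diagnostic read counts within the
#'   array (optional; if missing only the total is returned).
#' @return list with \code{total} and (when split is possible)
#'   \code{per_haplotype} repeat estimates.
#' @export
rdna_copy_number <- function(rdna_coverage, baseline_coverage,
                             hap_counts = NULL) {
  base <- mean(baseline_coverage)
  if (!is.finite(base) || base <= 0)
    stop("baseline coverage is zero; cannot estimate repeat number")
  total <- 2 * mean(rdna_coverage) / base
  out <- list(total = total)
  if (!is.null(hap_counts)) {
    s <- sum(hap_counts)
    frac <- if (s > 0) hap_counts / s else hap_counts * 0
    out$per_haplotype <- total * frac
  }
  out
}
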