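.complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Link de novo mutations to a parental haplotype
#'
#' A mutation is phased to the haplotype whose diagnostic SNP allele
#' co-occurs with the mutant base on reads spanning both sites.  Linkage
#' requires a heterozygous SNP within \code{window} bp (short-read inserts
#' limit informative distance to about 300 bp) and at least
#' \code{min_support} concordant co-observations with no discordant ones;
#' conflicting co-observations yield "unlinked" with a warning.
#'
#' @param mutations data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}.
#' @param snp_map data.frame of phased heterozygous SNPs (chrom, pos).
#' @param coobs co-observation table: columns \code{id} (mutation id),
#'   \code{snp_pos}, \code{haplotype}, \code{n} (reads carrying the mutant
#'   base together with that haplotype's SNP allele).
#' @param window linkage window in bp (default 300).
#' @param min_support minimum concordant co-observations (default 2).
#' @return the mutations data.frame with a \code{linked} column
#'   (haplotype label or "unlinked").
#' @export
link_to_haplotype <- function(mutations, snp_map, coobs,
                              window = 300, min_support = 2L) {
  if (window <= 0) stop("window must be > 0")
  linked <- character(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    near <- snp_map$chrom == m$chrom & abs(snp_map$pos - m$pos) <= window
    if (!any(near)) { linked[i] <- "unlinked"; next }
    ob <- coobs[coobs$id == m$id &
                coobs$snp_pos %in% snp_map$pos[near], , drop = FALSE]
    if (nrow(ob) == 0L) { linked[i] <- "unlinked"; next }
    tab <- tapply(ob$n, ob$haplotype, sum)
    tab <- tab[tab > 0]
    if (length(tab) > 1L) {
      warning("mutation ", m$id,
              ": conflicting haplotype co-observations; left unlinked")
      linked[i] <- "unlinked"
    } else if (length(tab) == 1L && tab[[1]] >= min_support) {
      linked[i] <- names(tab)
    } else linked[i] <- "unlinked"
  }
  mutations$linked <- linked
  mutations
}

#' 5' flanking-base context of single-base mutations
#'
#' Each mutated position contributes its 5'-flanking base in both strand
#' orientations (on the plus strand the base at pos - 1; on the minus
#' strand the complement of the base at pos + 1), so the denominator is
#' twice the number of mutations with both flanks defined.  The observed
#' fraction with a 5' C is compared with an expected fraction by a
#' one-degree-of-freedom chi-square test.  The expected fraction is a
#' parameter (default 0.35, the random-association expectation used for a
#' genome of 38% G+C).
#'
#' @param snvs data.frame with \code{chrom}, \code{pos}.
#' @param sequences named list/vector of chromosome sequences (character
#'   strings, or anything \code{as.character} turns into one, e.g. a
#'   \code{DNAStringSet}).
#' @param expected expected 5'C fraction (default 0.35).
#' @return list: \code{observed} (5'C count), \code{denominator},
#'   \code{observed_pct}, \code{expected_pct}, \code{chisq}, \code{p}, and
#'   \code{skipped} (mutations lacking a flank, logged and excluded from
#'   that orientation).
#' @export
five_prime_context <- function(snvs, sequences, expected = 0.35) {
  sequences <- vapply(sequences, as.character, character(1))
  obs <- 0L; denom <- 0L; skipped <- 0L
  for (i in seq_len(nrow(snvs))) {
    s <- sequences[[snvs$chrom[i]]]
    p <- snvs$pos[i]
    if (p > 1) {
      denom <- denom + 1L
      if (substr(s, p - 1, p - 1) == "C") obs <- obs + 1L
    } else skipped <- skipped + 1L
    if (p < nchar(s)) {
      denom <- denom + 1L
      # 5' base on the minus strand = complement of the plus-strand base 3'
      if (.complement[[substr(s, p + 1, p + 1)]] == "C") obs <- obs + 1L
    } else skipped <- skipped + 1L
  }
  five_prime_context_test(obs, denom, expected, skipped = skipped)
}

#' Chi-square test of an observed 5'C count against an expected fraction
#'
#' Summary-statistic form of \code{\link{five_prime_context}}: a 1-df
#' goodness-of-fit chi-square of (observed, denominator - observed)
#' against the expected split.
#'
#' @param observed number of orientations with a 5' C.
#' @param denominator total orientations counted (2 x mutations with both
#'   flanks).
#' @param expected expected 5'C fraction.
#' @param skipped orientations skipped for missing flanks (bookkeeping).
#' @return list as in \code{\link{five_prime_context}}.
#' @export
five_prime_context_test <- function(observed, denominator, expected = 0.35,
                                    skipped = 0L) {
  if (denominator <= 0) stop("empty denominator")
  e <- denominator * c(expected, 1 - expected)
  o <- c(observed, denominator - observed)
  chisq <- sum((o - e)^2 / e)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(observed = observed, denominator = denominator,
       observed_pct = 100 * observed / denominator,
       expected_pct = 100 * expected,
       chisq = chisq, p = p, skipped = skipped)
}

.six_classes <- c("C:G>A:T", "C:G>G:C", "C:G>T:A",
                  "T:A>A:T", "T:A>C:G", "T:A>G:C")

#' Collapse SNVs into the six complementary substitution classes
#'
#' C>T and G>A (etc.) are the same event read from opposite strands, so
#' substitutions collapse into six classes keyed by the pyrimidine of the
#' reference pair.  Optionally compares the distribution with a reference
#' spectrum: Fisher exact for small tables, chi-square fallback for large
#' ones (total > \code{fisher_max}), with the choice recorded.
#'
#' @param ref,alt character vectors of reference and mutant bases.
#' @param reference_counts optional named counts over the six classes to
#'   test against.
#' @param fisher_max switch to chi-square above this total count (default
#'   400).
#' @return list with \code{counts} (named six-class table) and, when a
#'   reference is supplied, \code{p} and \code{method}.
#' @export
classify_substitutions <- function(ref, alt, reference_counts = NULL,
                                   fisher_max = 400L) {
  if (length(ref) == 0L) stop("empty SNV set")
  stopifnot(length(ref) == length(alt))
  r <- toupper(ref); a <- toupper(alt)
  flip <- r %in% c("G", "A")
  r[flip] <- .complement[r[flip]]
  a[flip] <- .complement[a[flip]]
  key <- ifelse(r == "C",
                paste0("C:G>", a, ":", .complement[a]),
                paste0("T:A>", a, ":", .complement[a]))
  counts <- table(factor(key, levels = .six_classes))
  out <- list(counts = counts)
  if (!is.null(reference_counts)) {
    refc <- reference_counts[.six_classes]
    refc[is.na(refc)] <- 0
    tab <- rbind(as.integer(counts), as.integer(refc))
    if (sum(tab) <= fisher_max) {
      out$method <- "fisher"
      out$p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    } else {
      out$method <- "chisq"
      keep <- colSums(tab) > 0
      out$p <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))$p.value
    }
    message("spectrum comparison used ", out$method, " test")
  }
  out
}

#' Classify an in/del by dinucleotide-run context and size
#'
#' A 2-bp deletion whose removed unit matches a flanking tandem
#' dinucleotide repeat of at least \code{min_units} copies (counting the
#' deleted copy) is flagged as a run deletion -- the signature of
#' topoisomerase-mediated removal of embedded ribonucleotides.  The size
#' class distinguishes 1-3 bp events from larger ones.
#'
#' @param chrom,pos locus of the in/del (pos = first deleted/inserted
#'   base, 1-based).
#' @param ref,alt explicit alleles; a deletion has \code{nchar(ref) >
#'   nchar(alt)}.
#' @param sequences named chromosome sequences.
#' @param min_units minimum tandem copies of the unit (default 2).
#' @return list: \code{kind} ("insertion"/"deletion"), \code{length},
#'   \code{size_class} ("1-3bp"/">3bp"), \code{run} (logical),
#'   \code{unit} (the repeat unit or NA).
#' @export
indel_run_classifier <- function(chrom, pos, ref, alt, sequences,
                                 min_units = 2L) {
  del_len <- nchar(ref) - nchar(alt)
  kind <- if (del_len > 0) "deletion" else "insertion"
  len <- abs(del_len)
  size_class <- if (len <= 3) "1-3bp" else ">3bp"
  run <- FALSE; unit <- NA_character_
  if (kind == "deletion" && len == 2L) {
    s <- as.character(sequences[[chrom]])
    unit_seq <- substr(s, pos, pos + 1L)
    copies <- 1L
    p <- pos - 2L
    while (p >= 1 && substr(s, p, p + 1L) == unit_seq) {
      copies <- copies + 1L; p <- p - 2L
    }
    p <- pos + 2L
    while (p + 1L <= nchar(s) && substr(s, p, p + 1L) == unit_seq) {
      copies <- copies + 1L; p <- p + 2L
    }
    if (copies >= min_units) { run <- TRUE; unit <- unit_seq }
  }
  list(kind = kind, length = len, size_class = size_class,
       run = run, unit = unit)
}

#' Partition mutations into clonal and mixed (subclonal) by read fraction
#'
#' In a haploid context a clonal mutation is expected in essentially all
#' reads; a mutant-read fraction at or below \code{threshold} marks a
#' mixed (subclonal) mutation (clonal requires a strictly greater
#' fraction).  In a diploid context a heterozygous mutation is expected
#' near 0.5, so clonality is judged against a 0.5-centered band instead.
#'
#' @param fractions mutant-read fractions in [0, 1].
#' @param ploidy "haploid" or "diploid".
#' @param threshold haploid clonality threshold (default 0.70).
#' @param het_band diploid heterozygous band (default \code{c(0.35,
#'   0.65)}).
#' @return character vector "clonal"/"mixed".
#' @export
mixed_read_filter <- function(fractions, ploidy = c("haploid", "diploid"),
                              threshold = 0.70, het_band = c(0.35, 0.65)) {
  ploidy <- match.arg(ploidy)
  stopifnot(all(fractions >= 0 & fractions <= 1))
  if (ploidy == "haploid") {
    ifelse(fractions > threshold, "clonal", "mixed")
  } else {
    ifelse(fractions >= het_band[1], "clonal", "mixed")
  }
}
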