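#' Write / read an allele-specific SNP count table
#'
#' Tab-separated with a header comment stating the coordinate convention
#' (1-based inclusive); columns chrom, pos, allele_<hap1>, allele_<hap2>,
#' count_<hap1>, count_<hap2>.
#'
#' @param counts count table.
#' @param path file path.
#' @return \code{read_snp_counts} returns the data.frame;
#'   \code{write_snp_counts} returns \code{path} invisibly.
#' @export
write_snp_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# snp-count-table v1", "# coordinates: 1-based inclusive"),
             con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_counts
#' @export
read_snp_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read a truth ledger
#'
#' Tab-separated with a versioned header; coordinates 1-based inclusive.
#' The round trip is lossless.
#'
#' @param ledger a truth ledger from \code{\link{apply_events}}.
#' @param path file path.
#' @export
write_truth_ledger <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# truth-ledger v1", "# coordinates: 1-based inclusive"),
             con)
  utils::write.table(ledger, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# truth-ledger v1", first))
    stop("not a truth-ledger v1 file: ", path)
  led <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(
                             event_id = "integer", kind = "character",
                             chrom = "character", start = "integer",
                             end = "integer", recipient = "character",
                             retained = "character", chrom2 = "character",
                             start2 = "integer", end2 = "integer",
                             breakpoint = "integer", ref = "character",
                             alt = "character", read_frac = "numeric"))
  class(led) <- c("truth_ledger", "data.frame")
  led
}

#' Read / write element annotation as BED
#'
#' On disk BED is 0-based half-open; in memory the package uses 1-based
#' inclusive coordinates.  The conversion is delegated to rtracklayer.
#' The BED name field carries the element class.
#'
#' @param path BED file path.
#' @param elements data.frame with class, chrom, start, end (1-based
#'   inclusive).
#' @return \code{read_elements_bed} returns a data.frame with columns
#'   class, chrom, start, end (1-based inclusive).
#' @export
read_elements_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(class = if ("name" %in% names(df)) df$name
             else rep(NA_character_, nrow(df)),
             chrom = as.character(df$seqnames),
             start = df$start, end = df$end,
             stringsAsFactors = FALSE)
}

#' @rdname read_elements_bed
#' @export
write_elements_bed <- function(elements, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = elements$chrom,
    ranges = IRanges::IRanges(start = elements$start, end = elements$end),
    name = elements$class)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export LOH events as BED tracks
#'
#' Writes the LOH tracts (one feature per event, name = type/class) and,
#' optionally, the breakpoint midpoints as 1-bp features.
#'
#' @param events event data.frame from \code{\link{segment_to_events}}.
#' @param path output BED path for the tracts.
#' @param midpoint_path optional BED path for breakpoint midpoints.
#' @export
write_events_bed <- function(events, path, midpoint_path = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = events$chrom,
    ranges = IRanges::IRanges(start = events$start_pos,
                              end = events$end_pos),
    name = paste0(events$type, ":", events$class, ":", events$retained))
  rtracklayer::export(gr, path, format = "BED")
  if (!is.null(midpoint_path)) {
    mid <- as.integer(round(events$bp_mid))
    grm <- GenomicRanges::GRanges(
      seqnames = events$chrom,
      ranges = IRanges::IRanges(start = mid, end = mid),
      name = paste0(events$type, ":breakpoint"))
    rtracklayer::export(grm, midpoint_path, format = "BED")
  }
  invisible(path)
}
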