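#' Synthetic gel image from lane fragment samples
#'
#' Builds an intensity matrix (rows = migration axis, top = large
#' fragments; columns = lateral axis) with a ladder lane followed by one
#' lane per fragment sample.  Migration is linear in log10(size): row
#' \code{r(size) = 1 + (nrow - 1) * (log10(max) - log10(size)) /
#' (log10(max) - log10(min))}.  Each fragment deposits intensity
#' proportional to its length (mass weighting) as a Gaussian of standard
#' deviation \code{spread} rows centered on its migration row.  Fragments
#' outside the calibratable size range are clipped to the range edge and
#' counted.
#'
#' @param lane_fragments list of numeric vectors of fragment lengths (bp),
#'   one per sample lane.
#' @param ladder_sizes_kb ladder fragment sizes in kb (descending or any
#'   order).
#' @param nrow image height (default 400 rows).
#' @param lane_width,gap_width lane and inter-lane gap widths in columns.
#' @param spread Gaussian band spread in rows (default 2).
#' @param size_range_kb calibratable size range; default spans the ladder
#'   with 20% margin in log space.
#' @param background constant background intensity added everywhere
#'   (default 0.5).
#' @param seed seed (reserved for future noise models; layout is
#'   deterministic).
#' @return object of class \code{gel_image}: list with \code{intensity}
#'   matrix, \code{lanes} (list of column index vectors; lane 1 is the
#'   ladder), \code{ladder_lane = 1}, \code{size_range_kb},
#'   \code{clipped} count, and the true \code{row_of_kb}/\code{kb_of_row}
#'   mapping functions used to draw it.
#' @export
fragments_to_gel <- function(lane_fragments, ladder_sizes_kb,
                             nrow = 400L, lane_width = 20L, gap_width = 12L,
                             spread = 2, size_range_kb = NULL,
                             background = 0.5, seed = 1L) {
  stopifnot(is.list(lane_fragments), length(ladder_sizes_kb) >= 2L)
  if (is.null(size_range_kb)) {
    lr <- range(log10(ladder_sizes_kb))
    pad <- 0.2 * diff(lr)
    size_range_kb <- 10^(c(lr[1] - pad, lr[2] + pad))
  }
  lmin <- log10(size_range_kb[1]); lmax <- log10(size_range_kb[2])
  row_of_kb <- function(kb) 1 + (nrow - 1) * (lmax - log10(kb)) / (lmax - lmin)
  kb_of_row <- function(r) 10^(lmax - (r - 1) * (lmax - lmin) / (nrow - 1))
  n_lanes <- 1L + length(lane_fragments)
  ncol <- n_lanes * lane_width + (n_lanes + 1L) * gap_width
  img <- matrix(background, nrow = nrow, ncol = ncol)
  lanes <- vector("list", n_lanes)
  clipped <- 0L
  .deposit <- function(img, cols, sizes_kb, masses) {
    kb <- pmin(pmax(sizes_kb, size_range_kb[1]), size_range_kb[2])
    clipped <<- clipped + sum(sizes_kb < size_range_kb[1] |
                              sizes_kb > size_range_kb[2])
    centers <- row_of_kb(kb)
    prof <- numeric(nrow)
    rows <- seq_len(nrow)
    for (i in seq_along(centers)) {
      w <- stats::dnorm(rows, centers[i], spread)
      prof <- prof + masses[i] * w / sum(w)    # conserve mass per fragment
    }
    img[, cols] <- img[, cols] + prof
    img
  }
  for (k in seq_len(n_lanes)) {
    c0 <- gap_width * k + lane_width * (k - 1L) + 1L
    lanes[[k]] <- seq.int(c0, c0 + lane_width - 1L)
  }
  # ladder: equal mass per ladder band
  img <- .deposit(img, lanes[[1]], ladder_sizes_kb,
                  rep(max(unlist(lapply(lane_fragments, sum)), 1) /
                        (10 * length(ladder_sizes_kb)),
                      length(ladder_sizes_kb)))
  for (k in seq_along(lane_fragments)) {
    fr <- lane_fragments[[k]]
    img <- .deposit(img, lanes[[k + 1L]], fr / 1000, fr)
  }
  structure(list(intensity = img, lanes = lanes, ladder_lane = 1L,
                 size_range_kb = size_range_kb, clipped = clipped,
                 row_of_kb = row_of_kb, kb_of_row = kb_of_row),
            class = "gel_image")
}

#' Extract a background-subtracted lane intensity profile
#'
#' The profile is the row-wise mean over the lane's columns minus the
#' row-wise mean of the gap regions flanking the lane (half a lane width
#' on each side by default).  A lane at the image edge falls back to the
#' single available gap with a warning.  Negative values are clipped to 0
#' (the count of clipped rows is attached).
#'
#' @param gel a \code{gel_image} (or a list with \code{intensity} and
#'   \code{lanes}).
#' @param lane lane index.
#' @param gap_frac gap window width as a fraction of the lane width
#'   (default 0.5).
#' @return numeric vector (class \code{lane_profile}) of length
#'   \code{nrow(intensity)} with attribute \code{n_clipped}.
#' @export
extract_lane_profile <- function(gel, lane, gap_frac = 0.5) {
  img <- gel$intensity
  cols <- gel$lanes[[lane]]
  w <- max(1L, floor(length(cols) * gap_frac))
  left <- (min(cols) - w):(min(cols) - 1L)
  right <- (max(cols) + 1L):(max(cols) + w)
  left <- left[left >= 1L]
  right <- right[right <= ncol(img)]
  if (length(left) == 0L && length(right) == 0L)
    stop("no gap space on either side of lane ", lane)
  if (length(left) == 0L || length(right) == 0L)
    warning("lane ", lane,
            " at image edge; using single-sided background")
  bg_cols <- c(left, right)
  prof <- rowMeans(img[, cols, drop = FALSE]) -
    rowMeans(img[, bg_cols, drop = FALSE])
  n_clipped <- sum(prof < 0)
  prof <- pmax(prof, 0)
  attr(prof, "n_clipped") <- n_clipped
  class(prof) <- "lane_profile"
  prof
}

# local maxima above a noise floor (3 x MAD by default)
.find_peaks <- function(profile, floor_mult = 3) {
  p <- as.numeric(profile)
  floor_ <- floor_mult * stats::mad(p)
  n <- length(p)
  cand <- which(p > floor_ &
                p >= c(-Inf, p[-n]) & p >= c(p[-1], -Inf))
  # collapse plateaus / near-duplicates
  if (length(cand) > 1L) {
    keep <- c(TRUE, diff(cand) > 2)
    cand <- cand[keep]
  }
  cand
}

#' Calibrate migration distance to fragment size from a ladder lane
#'
#' Detects ladder peaks as local maxima above a noise floor (3x the
#' profile's median absolute deviation), requires the detected peak count
#' to equal the number of known sizes, and fits log10(size) as a linear
#' function of row with linear extrapolation beyond the ladder range.
#' Monotonicity (size decreasing with migration) is enforced.
#'
#' @param ladder_profile \code{lane_profile} of the ladder lane.
#' @param sizes_kb known ladder sizes in kb, largest first (matched to
#'   peaks top to bottom).
#' @return object of class \code{ladder_calibration}: list with
#'   \code{peak_rows}, \code{sizes_kb}, \code{kb_of_row},
#'   \code{row_of_kb}, and the fit coefficients.
#' @export
calibrate_ladder <- function(ladder_profile, sizes_kb) {
  sizes_kb <- as.numeric(sizes_kb)
  if (is.unsorted(rev(sizes_kb), strictly = TRUE) &&
      is.unsorted(sizes_kb, strictly = TRUE))
    stop("ladder sizes must be strictly monotone")
  sizes_kb <- sort(sizes_kb, decreasing = TRUE)
  peaks <- .find_peaks(ladder_profile)
  if (length(peaks) != length(sizes_kb))
    stop("detected ", length(peaks), " ladder peaks at rows [",
         paste(peaks, collapse = ", "), "] but ", length(sizes_kb),
         " sizes were supplied")
  fit <- stats::lm(log10(sizes_kb) ~ peaks)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("calibration is not monotone decreasing in size along migration")
  a <- unname(stats::coef(fit)[1])
  kb_of_row <- function(r) 10^(a + slope * r)
  row_of_kb <- function(kb) (log10(kb) - a) / slope
  structure(list(peak_rows = peaks, sizes_kb = sizes_kb,
                 intercept = unname(a), slope = unname(slope),
                 kb_of_row = kb_of_row, row_of_kb = row_of_kb),
            class = "ladder_calibration")
}

#' Summarize a calibrated lane profile
#'
#' Modal size = size at the profile's global maximum; mean size =
#' mass-weighted mean over the profile (the profile intensity is already
#' mass per row).  The normalized copy scales the global maximum to 1;
#' per-peak normalization scales each detected peak's neighborhood to its
#' own maximum.
#'
#' @param profile a \code{lane_profile}.
#' @param calibration a \code{ladder_calibration}.
#' @param normalize "lane" (global maximum to 1, default) or "peak".
#' @return list: \code{modal_kb}, \code{mean_kb}, \code{normalized}
#'   (profile), \code{kb} (per-row size axis).
#' @export
summarize_profile <- function(profile, calibration,
                              normalize = c("lane", "peak")) {
  normalize <- match.arg(normalize)
  p <- as.numeric(profile)
  if (all(p == 0)) stop("all-zero profile; summary undefined")
  kb <- calibration$kb_of_row(seq_along(p))
  modal_kb <- kb[which.max(p)]
  mean_kb <- sum(p * kb) / sum(p)
  if (normalize == "lane") {
    norm <- p / max(p)
  } else {
    peaks <- .find_peaks(p)
    norm <- p
    if (length(peaks) >= 1L) {
      bounds <- c(1L, floor((peaks[-1] + peaks[-length(peaks)]) / 2),
                  length(p))
      for (k in seq_along(peaks)) {
        i <- bounds[k]:bounds[k + 1]
        m <- max(p[i])
        if (m > 0) norm[i] <- p[i] / m
      }
    } else norm <- p / max(p)
  }
  list(modal_kb = modal_kb, mean_kb = mean_kb, normalized = norm, kb = kb)
}
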