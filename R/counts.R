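#' Simulate allele-specific read counts at every marker
#'
#' Per-site total depth is Poisson around \code{mean_depth} scaled by local
#' total copy number / 2; per-allele counts are binomial with expected
#' fraction = allele copy / total copy, or beta-binomial when
#' \code{overdispersion > 0} (the intra-class correlation rho of the
#' beta-binomial).  With \code{noise = "none"} counts are the exact
#' expectations rounded to integers, which is useful for oracle tests.
#'
#' @param genome a \code{\link{build_hybrid_genome}} (possibly
#'   event-modified) genome.
#' @param mean_depth mean per-site total read depth at copy number 2.
#' @param overdispersion beta-binomial rho in [0,1); 0 = pure binomial.
#' @param seed integer seed.
#' @param noise "binomial" (default) or "none".
#' @return data.frame with columns chrom, pos, allele_<hap1>, allele_<hap2>,
#'   count_<hap1>, count_<hap2>.
#' @export
simulate_allele_counts <- function(genome, mean_depth = 30,
                                   overdispersion = 0, seed = 1L,
                                   noise = c("binomial", "none")) {
  stopifnot(inherits(genome, "hybrid_genome"))
  noise <- match.arg(noise)
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  if (overdispersion >= 1) stop("overdispersion must be < 1")
  set.seed(seed)
  haps <- genome$config$haplotypes
  cn1 <- genome$snps[[paste0("cn_", haps[1])]]
  cn2 <- genome$snps[[paste0("cn_", haps[2])]]
  tot <- cn1 + cn2
  n <- length(tot)
  lambda <- mean_depth * tot / 2
  if (noise == "none") {
    depth <- as.integer(round(lambda))
    c1 <- as.integer(round(ifelse(tot > 0, depth * cn1 / tot, 0)))
  } else {
    depth <- stats::rpois(n, lambda)
    p <- ifelse(tot > 0, cn1 / tot, 0)
    if (overdispersion > 0) {
      rho <- overdispersion
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      ok <- p > 0 & p < 1
      p[ok] <- stats::rbeta(sum(ok), a[ok], b[ok])
    }
    c1 <- stats::rbinom(n, depth, p)
  }
  out <- genome$snps[, c("chrom", "pos",
                         paste0("allele_", haps[1]),
                         paste0("allele_", haps[2]))]
  out[[paste0("count_", haps[1])]] <- c1
  out[[paste0("count_", haps[2])]] <- depth - c1
  out
}

#' Simulate two-channel microarray probe ratios
#'
#' One probe per marker per haplotype allele.  The raw expectation of a
#' probe's normalized ratio is proportional to the copy number of the
#' targeted allele (1 copy in the control), with Gaussian noise of standard
#' deviation \code{noise_sd}; the output is re-centered by dividing every
#' ratio by the genome-wide mean so that the mean of the centered values is
#' exactly 1.
#'
#' @param genome a hybrid genome.
#' @param noise_sd standard deviation of the multiplicative Gaussian noise
#'   (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns probe_id, chrom, pos, haplotype, rm
#'   (centered normalized ratio).
#' @export
simulate_microarray_ratios <- function(genome, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(genome, "hybrid_genome"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  haps <- genome$config$haplotypes
  s <- genome$snps
  n <- nrow(s)
  long <- data.frame(
    chrom = rep(s$chrom, 2L),
    pos = rep(s$pos, 2L),
    haplotype = rep(haps, each = n),
    cn = c(s[[paste0("cn_", haps[1])]], s[[paste0("cn_", haps[2])]]),
    stringsAsFactors = FALSE)
  raw <- long$cn + stats::rnorm(nrow(long), 0, noise_sd)
  raw <- pmax(raw, 0)
  rm_centered <- raw / mean(raw)
  data.frame(probe_id = paste0(long$chrom, "_", long$pos, "_",
                               long$haplotype),
             chrom = long$chrom, pos = long$pos,
             haplotype = long$haplotype,
             rm = rm_centered, stringsAsFactors = FALSE)
}

#' Simulate alkaline fragmentation of rNMP-containing molecules
#'
#' Alkali cleaves the backbone at embedded ribonucleotides; cleavage sites
#' are placed as a Poisson process at \code{density} sites per bp along
#' each molecule, and the returned fragments are the gaps between adjacent
#' sites (and molecule ends).  Density 0 returns intact molecules.
#'
#' @param molecule_length molecule length in bp (single value).
#' @param density cleavage (rNMP) density per bp, e.g. 1/500.
#' @param n_molecules number of molecules.
#' @param seed integer seed.
#' @return numeric vector of fragment lengths (bp).
#' @export
simulate_alkaline_fragments <- function(molecule_length, density,
                                        n_molecules = 1L, seed = 1L) {
  if (molecule_length <= 0) stop("molecule_length must be > 0")
  if (density < 0) stop("density must be >= 0")
  set.seed(seed)
  if (density == 0) return(rep(molecule_length, n_molecules))
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    k <- stats::rpois(1, density * molecule_length)
    cuts <- sort(stats::runif(k, 0, molecule_length))
    out[[i]] <- diff(c(0, cuts, molecule_length))
  }
  unlist(out)
}

#' Simulate coverage over the rDNA locus and a single-copy baseline
#'
#' Emulates the read-depth signal used to count rRNA-gene repeats: each of
#' \code{n_rdna_sites} positions in the repeat array receives Poisson
#' coverage with mean \code{depth} x (total repeats / 2) (depth is the
#' per-haploid-copy x2 coverage of a disomic single-copy site), and
#' haplotype-diagnostic reads within the array are binomial with success
#' probability equal to the first haplotype's share of repeats.
#'
#' @param repeats named per-haplotype repeat counts, e.g.
#'   \code{c(W = 123, Y = 72)}.
#' @param depth mean depth at a disomic single-copy site.
#' @param n_baseline_sites number of single-copy baseline positions.
#' @param n_rdna_sites number of positions sampled inside the array.
#' @param seed integer seed.
#' @return list with \code{rdna_coverage}, \code{baseline_coverage}
#'   (numeric vectors) and \code{hap_counts} (named total
#'   haplotype-diagnostic read counts within the array).
#' @export
simulate_rdna_coverage <- function(repeats, depth = 50,
                                   n_baseline_sites = 2000L,
                                   n_rdna_sites = 200L, seed = 1L) {
  stopifnot(length(repeats) == 2L, all(repeats >= 0))
  set.seed(seed)
  tot <- sum(repeats)
  base <- stats::rpois(n_baseline_sites, depth)
  rd <- stats::rpois(n_rdna_sites, depth * tot / 2)
  p1 <- if (tot > 0) repeats[[1]] / tot else 0
  h1 <- stats::rbinom(1, sum(rd), p1)
  hap_counts <- c(h1, sum(rd) - h1)
  names(hap_counts) <- names(repeats)
  list(rdna_coverage = rd, baseline_coverage = base,
       hap_counts = hap_counts)
}
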