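# Core per-site and per-window population-genetic statistics.
#
# All statistics share one per-site summary: the alternate-allele count and
# the number of non-missing genotypes among the selected samples.  Missing
# genotypes are handled pairwise-complete per site: each site contributes the
# mean difference over the sample pairs observed there.

.resolveSamples <- function(x, samples) {
  if (is.null(samples)) return(sampleIds(x))
  missing <- setdiff(samples, sampleIds(x))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  samples
}

.siteIdx <- function(x, start, end) {
  which(x@positions >= start & x@positions <= end)
}

# alt-allele count and non-missing count per site for a sample subset
.siteCounts <- function(x, samples, idx) {
  g <- x@genotypes[samples, idx, drop = FALSE]
  list(alt = colSums(g == 1L, na.rm = TRUE), n = colSums(!is.na(g)))
}

# per-site mean pairwise difference (in [0,1]); sites with <2 observed
# genotypes contribute 0
.piSite <- function(alt, n) {
  pairs <- n * (n - 1) / 2
  ifelse(pairs > 0, alt * (n - alt) / pairs, 0)
}

#' Sliding-window grid
#'
#' Windows start at 1, 1+step, ...; the last window is the final full-size
#' window and any shorter tail is dropped, keeping per-window length constant
#' so per-site rates are comparable across windows.  If the genome is shorter
#' than one window, a single clamped window is returned with a warning.
#'
#' @param genomeLength reference length (bp).
#' @param size window size (bp).
#' @param step step between window starts (bp); `0 < step <= size`.
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @examples
#' iterWindows(100000, 50000, 12500)  # 5 windows
#' @export
iterWindows <- function(genomeLength, size, step = size) {
  if (step <= 0 || step > size) stop("need 0 < step <= size")
  if (genomeLength < size) {
    warning("genome shorter than window size; returning one clamped window")
    return(data.frame(start = 1L, end = as.integer(genomeLength)))
  }
  starts <- seq.int(1L, genomeLength - size + 1L, by = step)
  data.frame(start = as.integer(starts), end = as.integer(starts + size - 1L))
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference per site within a sample set over a reference
#' window: at each SNP the mean difference over all observed sample pairs,
#' summed and divided by the window length.  Monomorphic reference positions
#' contribute zero differences, so only SNPs need to be visited.
#'
#' @param x a [SnpAlignment-class].
#' @param samples sample ids (default: all samples).
#' @param start,end window bounds, 1-based inclusive (default: whole genome).
#' @return per-site pi; `NaN` (with a warning) for fewer than 2 samples.
#' @export
nucleotideDiversity <- function(x, samples = NULL, start = 1,
                                end = genomeLength(x)) {
  samples <- .resolveSamples(x, samples)
  if (length(samples) < 2) {
    warning("pi undefined for <2 samples")
    return(NaN)
  }
  sc <- .siteCounts(x, samples, .siteIdx(x, start, end))
  sum(.piSite(sc$alt, sc$n)) / (end - start + 1)
}

#' Segregating sites and Watterson's theta
#'
#' A site segregates when both alleles are observed among the non-missing
#' genotypes of the sample set.  Watterson's estimator divides by
#' `a1 = sum(1/i, i < n)` with `n` the number of selected samples, and by
#' the window length for a per-site rate.
#'
#' @inheritParams nucleotideDiversity
#' @return `segregatingSites`: integer count. `wattersonTheta`: per-site
#'   theta_W.
#' @export
segregatingSites <- function(x, samples = NULL, start = 1,
                             end = genomeLength(x)) {
  samples <- .resolveSamples(x, samples)
  sc <- .siteCounts(x, samples, .siteIdx(x, start, end))
  sum(sc$alt > 0 & sc$alt < sc$n)
}

#' @rdname segregatingSites
#' @export
wattersonTheta <- function(x, samples = NULL, start = 1,
                           end = genomeLength(x)) {
  samples <- .resolveSamples(x, samples)
  n <- length(samples)
  if (n < 2) {
    warning("theta_W undefined for <2 samples")
    return(NaN)
  }
  S <- segregatingSites(x, samples, start, end)
  S / (sum(1 / seq_len(n - 1)) * (end - start + 1))
}

# Tajima (1989) constants for sample size n
.tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from summary statistics; exposed internally for oracle comparisons
.tajimasDFromCounts <- function(n, S, pihat) {
  if (S == 0) return(NaN)
  k <- .tajimaConstants(n)
  (pihat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' `D = (pihat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants for sample size `n`; `pihat` is the mean pairwise difference
#' count (not per site) over the window.  Returns `NaN` when `S = 0` or
#' fewer than 3 samples are available.
#'
#' @inheritParams nucleotideDiversity
#' @return Tajima's D for the window.
#' @export
tajimasD <- function(x, samples = NULL, start = 1, end = genomeLength(x)) {
  samples <- .resolveSamples(x, samples)
  n <- length(samples)
  if (n < 3) return(NaN)
  sc <- .siteCounts(x, samples, .siteIdx(x, start, end))
  S <- sum(sc$alt > 0 & sc$alt < sc$n)
  pihat <- sum(.piSite(sc$alt, sc$n))
  .tajimasDFromCounts(n, S, pihat)
}

# P(K = 1..n) under the Ewens sampling formula given theta, via the
# sequential-construction representation: K = 1 + sum Bernoulli(theta /
# (theta + i - 1)), i = 2..n.  Numerically stable for large n, equivalent to
# |Stirling1(n, k)| theta^k / rising factorial.
.ewensKDistribution <- function(n, theta) {
  pk <- c(1, rep(0, n - 1))  # after first draw: K = 1
  if (n >= 2) for (i in 2:n) {
    p <- theta / (theta + i - 1)
    pk <- c(pk * (1 - p), 0)[seq_len(n)] + p * c(0, pk)[seq_len(n)]
  }
  pk
}

#' Fu's F(S) (and Fu & Li's F*)
#'
#' `type = "Fs"` (default) computes Fu's F_S: with `k` the number of
#' distinct haplotypes in the window and `theta` estimated by the mean
#' pairwise difference, `S' = P(K >= k)` under the Ewens sampling formula and
#' `F_S = ln(S' / (1 - S'))`.  Missing genotypes are treated as a distinct
#' haplotype state.
#'
#' `type = "Fstar"` computes Fu & Li's F* from the total number of
#' segregating sites and the singleton count (variants carried by exactly one
#' sequence, unpolarized).
#'
#' @inheritParams nucleotideDiversity
#' @param type `"Fs"` or `"Fstar"`.
#' @return the statistic; `NaN` when undefined (no variation, or a single
#'   haplotype).
#' @export
fusF <- function(x, samples = NULL, start = 1, end = genomeLength(x),
                 type = c("Fs", "Fstar")) {
  type <- match.arg(type)
  samples <- .resolveSamples(x, samples)
  n <- length(samples)
  if (n < 3) return(NaN)
  idx <- .siteIdx(x, start, end)
  sc <- .siteCounts(x, samples, idx)
  pihat <- sum(.piSite(sc$alt, sc$n))
  if (type == "Fs") {
    g <- x@genotypes[samples, idx, drop = FALSE]
    seg <- sc$alt > 0 & sc$alt < sc$n
    g <- g[, seg, drop = FALSE]
    k <- nrow(unique(g))
    if (pihat == 0 || k == 1) return(NaN)
    pk <- .ewensKDistribution(n, pihat)
    sp <- sum(pk[k:n])
    return(log(sp / (1 - sp)))
  }
  # Fu & Li's F* (Fu & Li 1993 with Simonsen et al. 1995 corrections)
  S <- sum(sc$alt > 0 & sc$alt < sc$n)
  if (S == 0) return(NaN)
  etaS <- sum((sc$alt == 1 | sc$alt == sc$n - 1) & sc$alt > 0 & sc$alt < sc$n)
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
         2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
         (3 * n * (n - 1))) / an - vF
  (pihat - (n - 1) / n * etaS) / sqrt(uF * S + vF * S^2)
}

#' Absolute divergence D_XY
#'
#' Mean per-site pairwise difference between two sample sets:
#' `(1/(nA*nB*L)) * sum over cross pairs of their differences`, with missing
#' genotypes handled pairwise-complete per site.
#'
#' @param x a [SnpAlignment-class].
#' @param samplesA,samplesB sample ids of the two lineages (each non-empty).
#' @param start,end window bounds.
#' @return per-site D_XY.
#' @export
dxy <- function(x, samplesA, samplesB, start = 1, end = genomeLength(x)) {
  if (length(samplesA) < 1 || length(samplesB) < 1)
    stop("both lineages must contain at least one sample")
  samplesA <- .resolveSamples(x, samplesA)
  samplesB <- .resolveSamples(x, samplesB)
  idx <- .siteIdx(x, start, end)
  a <- .siteCounts(x, samplesA, idx)
  b <- .siteCounts(x, samplesB, idx)
  cross <- a$alt * (b$n - b$alt) + b$alt * (a$n - a$alt)
  pairs <- a$n * b$n
  sum(ifelse(pairs > 0, cross / pairs, 0)) / (end - start + 1)
}

#' Hudson's F_ST
#'
#' `F_ST = 1 - Hw/Hb` with `Hw = (pi_A + pi_B)/2` (mean within-lineage
#' diversity) and `Hb = D_XY`.  Returns `NaN` when `Hb = 0` or when a
#' lineage has fewer than 2 samples; negative values are possible and are
#' reported as computed.
#'
#' @inheritParams dxy
#' @return Hudson's F_ST for the window.
#' @export
fstHudson <- function(x, samplesA, samplesB, start = 1,
                      end = genomeLength(x)) {
  if (length(samplesA) < 2 || length(samplesB) < 2) {
    warning("F_ST needs >= 2 samples per lineage")
    return(NaN)
  }
  hw <- (nucleotideDiversity(x, samplesA, start, end) +
         nucleotideDiversity(x, samplesB, start, end)) / 2
  hb <- dxy(x, samplesA, samplesB, start, end)
  if (hb == 0) return(NaN)
  1 - hw / hb
}
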