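# Independent brute-force oracles.  These deliberately take the naive
# O(n^2 * L) route (explicit loops over sample pairs and sites) so they share
# no code path with the package implementation.

oracleSiteStats <- function(g) {
  # per site: discordant pair count and observed pair count, by explicit
  # enumeration of all sample pairs
  n <- nrow(g)
  d <- p <- numeric(ncol(g))
  for (s in seq_len(ncol(g))) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- g[i, s]; b <- g[j, s]
      if (!is.na(a) && !is.na(b)) {
        p[s] <- p[s] + 1
        if (a != b) d[s] <- d[s] + 1
      }
    }
  }
  list(d = d, p = p)
}

oraclePi <- function(aln, samples, start, end) {
  g <- genotypes(aln)[samples, snpPositions(aln) >= start &
                        snpPositions(aln) <= end, drop = FALSE]
  st <- oracleSiteStats(g)
  sum(ifelse(st$p > 0, st$d / st$p, 0)) / (end - start + 1)
}

oraclePihat <- function(aln, samples, start, end) {
  g <- genotypes(aln)[samples, snpPositions(aln) >= start &
                        snpPositions(aln) <= end, drop = FALSE]
  st <- oracleSiteStats(g)
  sum(ifelse(st$p > 0, st$d / st$p, 0))
}

oracleS <- function(aln, samples, start, end) {
  g <- genotypes(aln)[samples, snpPositions(aln) >= start &
                        snpPositions(aln) <= end, drop = FALSE]
  S <- 0
  for (s in seq_len(ncol(g))) {
    v <- g[, s]; v <- v[!is.na(v)]
    if (length(unique(v)) == 2) S <- S + 1
  }
  S
}

# Tajima constants written out independently (Tajima 1989)
oracleTajimaD <- function(aln, samples, start, end) {
  n <- length(samples)
  S <- oracleS(aln, samples, start, end)
  if (S == 0) return(NaN)
  pihat <- oraclePihat(aln, samples, start, end)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracleDxy <- function(aln, sa, sb, start, end) {
  idx <- snpPositions(aln) >= start & snpPositions(aln) <= end
  ga <- genotypes(aln)[sa, idx, drop = FALSE]
  gb <- genotypes(aln)[sb, idx, drop = FALSE]
  tot <- 0
  for (s in seq_len(ncol(ga))) {
    d <- p <- 0
    for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
      a <- ga[i, s]; b <- gb[j, s]
      if (!is.na(a) && !is.na(b)) {
        p <- p + 1
        if (a != b) d <- d + 1
      }
    }
    if (p > 0) tot <- tot + d / p
  }
  tot / (end - start + 1)
}

oracleFst <- function(aln, sa, sb, start, end) {
  hw <- (oraclePi(aln, sa, start, end) + oraclePi(aln, sb, start, end)) / 2
  hb <- oracleDxy(aln, sa, sb, start, end)
  if (hb == 0) return(NaN)
  1 - hw / hb
}

# Ewens sampling formula by unsigned Stirling numbers of the first kind
# (exact enumeration, small n)
oracleStirling1 <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (i in 1:n) for (k in 1:i)
    s[i + 1, k + 1] <- s[i, k] + (i - 1) * s[i, k + 1]
  s[n + 1, 2:(n + 1)]
}

oracleEwensPK <- function(n, theta) {
  st <- oracleStirling1(n)
  rising <- prod(theta + 0:(n - 1))
  st * theta^(1:n) / rising
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
  pobs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Kruskal-Wallis H from the rank formula, tie-corrected
oracleKwH <- function(groups) {
  v <- unlist(groups)
  N <- length(v)
  rk <- rank(v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  ties <- table(v)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Jaccard overlap of two interval sets
jaccardIntervals <- function(aStart, aEnd, bStart, bEnd) {
  a <- IRanges::reduce(IRanges::IRanges(aStart, aEnd))
  b <- IRanges::reduce(IRanges::IRanges(bStart, bEnd))
  inter <- IRanges::intersect(a, b)
  sum(IRanges::width(inter)) /
    sum(IRanges::width(IRanges::reduce(c(a, b))))
}

oracleThetaW <- function(aln, samples, start, end) {
  n <- length(samples)
  S <- oracleS(aln, samples, start, end)
  S / (sum(1 / (1:(n - 1))) * (end - start + 1))
}
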