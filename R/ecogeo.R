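# Isolation-by-distance / isolation-by-environment statistics: distance
# matrices, Mantel tests, phylogenetic signal, nonparametric group tests,
# ANI clustering and HGT normalization.

.EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

#' Great-circle distance matrix (km)
#'
#' Spherical haversine distance with mean Earth radius 6371.0088 km (a
#' documented simplification of the ellipsoidal geodesic; the difference is
#' below 0.5%).
#'
#' @param meta data.frame with `sample_id`, `latitude`, `longitude` (decimal
#'   degrees).
#' @return symmetric matrix of pairwise distances in km, zero diagonal,
#'   sample ids as dimnames.
#' @export
geoDistanceMatrix <- function(meta) {
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180))
    stop("coordinates out of range")
  lat <- meta$latitude * pi / 180
  lon <- meta$longitude * pi / 180
  n <- nrow(meta)
  d <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    a <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * .EARTH_RADIUS_KM * asin(min(1, sqrt(a)))
  }
  d
}

#' Genetic distance from ANI
#'
#' `(100 - ANI) / 100`, i.e. the "1 - ANI" distance with identities given in
#' percent.  Missing pairs stay `NA` and are excluded from downstream
#' distance vectors.
#'
#' @param ani an [AniMatrix-class].
#' @return symmetric distance matrix in `[0, 1]`.
#' @export
aniDistanceMatrix <- function(ani) {
  d <- (100 - aniValues(ani)) / 100
  diag(d) <- 0
  d
}

#' Environmental distance matrix
#'
#' Euclidean distance over the selected variables, z-scored first because
#' environmental variables carry heterogeneous units.
#'
#' @param meta metadata data.frame.
#' @param vars variable columns; default every column prefixed `env_`.
#' @param standardize z-score each variable first (default TRUE).
#' @return symmetric distance matrix with sample-id dimnames.
#' @export
envDistanceMatrix <- function(meta, vars = NULL, standardize = TRUE) {
  if (is.null(vars)) vars <- grep("^env_", names(meta), value = TRUE)
  if (!length(vars)) stop("no environmental variables found")
  m <- as.matrix(meta[vars])
  if (standardize) m <- scale(m)
  d <- as.matrix(dist(m))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; significance by permutation
#' of one matrix's row/column labels, `p = (#{r_perm >= r_obs} + 1) /
#' (n_perm + 1)` for the one-sided `greater` alternative (distance decay is
#' directional; `two.sided` and `less` are available).  Pairs with a missing
#' entry in either matrix are dropped from both vectors.
#'
#' @param d1,d2 symmetric distance matrices with matching sample ids as
#'   dimnames (aligned by name if necessary).
#' @param nPerm number of permutations (>= 99).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return list of class `mantelResult`: `r`, `p`, `n_perm`, `alternative`,
#'   `n`.
#' @export
mantelTest <- function(d1, d2, nPerm = 9999,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (nPerm < 99) stop("need nPerm >= 99")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    common <- intersect(rownames(d1), rownames(d2))
    if (length(common) < 3) stop("fewer than 3 shared samples")
    if (length(common) < nrow(d1) || length(common) < nrow(d2))
      warning("restricting to ", length(common), " shared samples")
    d1 <- d1[common, common]; d2 <- d2[common, common]
  }
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  ok <- !is.na(d1) & !is.na(d2)
  v1 <- d1[lt & ok]; v2 <- d2[lt & ok]
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("zero variance in a distance triangle")
    return(structure(list(r = NaN, p = NA_real_, n_perm = nPerm,
                          alternative = alternative, n = n),
                     class = "mantelResult"))
  }
  robs <- cor(v1, v2)
  rperm <- vapply(seq_len(nPerm), function(i) {
    p <- sample.int(n)
    dp <- d2[p, p]
    suppressWarnings(cor(d1[lt & ok & !is.na(dp)], dp[lt & ok & !is.na(dp)]))
  }, numeric(1))
  p <- switch(alternative,
    greater = (sum(rperm >= robs, na.rm = TRUE) + 1) / (nPerm + 1),
    less = (sum(rperm <= robs, na.rm = TRUE) + 1) / (nPerm + 1),
    two.sided = (sum(abs(rperm) >= abs(robs), na.rm = TRUE) + 1) /
      (nPerm + 1))
  structure(list(r = robs, p = p, n_perm = nPerm,
                 alternative = alternative, n = n),
            class = "mantelResult")
}

#' @export
print.mantelResult <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
              x$r, x$p, x$alternative, x$n_perm, x$n))
  invisible(x)
}

#' Phylogenetic signal: Blomberg's K and Pagel's lambda
#'
#' Both statistics are delegated to [phytools::phylosig()].  `blombergK`
#' reports K with a tip-label permutation p-value; `pagelLambda` reports the
#' maximum-likelihood lambda in `[0, 1]` with a likelihood-ratio test
#' against lambda = 0, using the 50:50 chi-square(0)/chi-square(1) boundary
#' mixture (lambda = 0 sits on the parameter boundary, so the naive
#' chi-square(1) p would be conservative).
#'
#' @param tree `phylo` with tip labels matching `names(trait)`.
#' @param trait named numeric trait vector.
#' @param nPerm permutations for the K test.
#' @return `blombergK`: list `K`, `p`, `n_perm`; `pagelLambda`: list
#'   `lambda`, `loglik`, `loglik0`, `p`.
#' @export
blombergK <- function(tree, trait, nPerm = 999) {
  trait <- trait[tree$tip.label]
  if (any(is.na(trait))) stop("trait missing for some tips")
  if (sd(trait) == 0) {
    warning("zero trait variance; K undefined")
    return(list(K = NaN, p = NA_real_, n_perm = nPerm))
  }
  r <- phytools::phylosig(tree, trait, method = "K", test = TRUE,
                          nsim = nPerm)
  list(K = unname(r$K), p = unname(r$P), n_perm = nPerm)
}

#' @rdname blombergK
#' @export
pagelLambda <- function(tree, trait) {
  trait <- trait[tree$tip.label]
  if (any(is.na(trait))) stop("trait missing for some tips")
  if (sd(trait) == 0) {
    warning("zero trait variance; lambda undefined")
    return(list(lambda = NaN, loglik = NaN, loglik0 = NaN, p = NA_real_))
  }
  r <- phytools::phylosig(tree, trait, method = "lambda", test = TRUE)
  lr <- 2 * (r$logL - r$logL0)
  p <- if (lr <= 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  list(lambda = unname(r$lambda), loglik = unname(r$logL),
       loglik0 = unname(r$logL0), p = p)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square reference distribution (delegated to
#' [stats::kruskal.test()]); the degenerate all-identical case returns
#' `H = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3).
#' @return list `H`, `df`, `p`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  v <- unlist(groups)
  if (length(v) < 3) stop("need total N >= 3")
  if (length(unique(v)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks with the tie correction,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12(N - 1))` over tied groups; two-sided normal
#' p-values multiplied by the number of pairs (Bonferroni), capped at 1.
#' Empty groups are dropped with a warning.
#'
#' @param values numeric vector.
#' @param g grouping vector (same length).
#' @param adjust only `"bonferroni"` is implemented (and `"none"`).
#' @return data.frame: `groupA`, `groupB`, `z`, `p`, `p_adj`.
#' @export
dunnPosthoc <- function(values, g, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- as.character(g)[keep]
  sizes <- table(g)
  if (any(sizes == 0)) warning("dropping empty group(s)")
  N <- length(values)
  rk <- rank(values)
  tieCounts <- table(values)
  tieTerm <- sum(tieCounts^3 - tieCounts) / (12 * (N - 1))
  meanRank <- tapply(rk, g, mean)
  lv <- sort(names(meanRank))
  pr <- utils::combn(lv, 2)
  m <- ncol(pr)
  z <- vapply(seq_len(m), function(i) {
    a <- pr[1, i]; b <- pr[2, i]
    se <- sqrt((N * (N + 1) / 12 - tieTerm) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    dif <- meanRank[[a]] - meanRank[[b]]
    if (se == 0) return(if (dif == 0) 0 else Inf * sign(dif))
    dif / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  padj <- if (adjust == "bonferroni") pmin(1, p * m) else p
  data.frame(groupA = pr[1, ], groupB = pr[2, ], z = z, p = p,
             p_adj = padj)
}

#' Cluster samples by an ANI threshold
#'
#' Single-linkage connected components of the graph whose edges join pairs
#' with ANI at or above the threshold.  Missing pairs are treated as below
#' the threshold (with a warning).
#'
#' @param ani an [AniMatrix-class].
#' @param threshold percent identity in (0, 100); 95 is the conventional
#'   species threshold.
#' @return named integer vector of cluster memberships (numbered by first
#'   appearance).
#' @export
aniCluster <- function(ani, threshold = 95) {
  if (threshold <= 0 || threshold >= 100)
    stop("threshold must lie in (0, 100)")
  v <- aniValues(ani)
  if (any(is.na(v[upper.tri(v)])))
    warning("missing ANI pairs treated as below threshold")
  n <- nrow(v)
  adj <- !is.na(v) & v >= threshold
  diag(adj) <- TRUE
  cluster <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      if (!is.na(cluster[node])) next
      cluster[node] <- cur
      queue <- c(queue, which(adj[node, ] & is.na(cluster)))
    }
  }
  setNames(cluster, rownames(v))
}

#' HGT counts normalized per Mb, with correlation and group tests
#'
#' Normalizes each sample's HGT count by its genome size and reports both
#' Spearman and Pearson correlations of count versus size (the two common
#' choices), plus Kruskal-Wallis and Dunn comparisons of the normalized rate
#' across lineages and across habitats.
#'
#' @param meta metadata with `hgt_count` and `genome_size_mb`.
#' @return list: `rates` (per-sample data.frame), `spearman_rho`,
#'   `spearman_p`, `pearson_r`, `pearson_p`, `by_lineage`, `by_habitat`
#'   (each a list with `kw` and `dunn`).
#' @export
hgtPerMb <- function(meta) {
  if (is.null(meta$hgt_count) || is.null(meta$genome_size_mb))
    stop("metadata must carry hgt_count and genome_size_mb")
  if (any(meta$genome_size_mb <= 0)) stop("genome_size_mb must be positive")
  rate <- meta$hgt_count / meta$genome_size_mb
  rates <- data.frame(sample_id = meta$sample_id, lineage = meta$lineage,
                      habitat = meta$habitat, hgt_count = meta$hgt_count,
                      genome_size_mb = meta$genome_size_mb,
                      hgt_per_mb = rate)
  sp <- suppressWarnings(cor.test(meta$hgt_count, meta$genome_size_mb,
                                  method = "spearman"))
  pe <- cor.test(meta$hgt_count, meta$genome_size_mb, method = "pearson")
  groupTests <- function(col) {
    gs <- split(rate, meta[[col]])
    gs <- gs[lengths(gs) >= 2]
    if (length(gs) < 2) return(NULL)
    sel <- meta[[col]] %in% names(gs)
    list(kw = kruskalWallis(gs),
         dunn = dunnPosthoc(rate[sel], meta[[col]][sel]))
  }
  list(rates = rates, spearman_rho = unname(sp$estimate),
       spearman_p = sp$p.value, pearson_r = unname(pe$estimate),
       pearson_p = pe$p.value, by_lineage = groupTests("lineage"),
       by_habitat = groupTests("habitat"))
}
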