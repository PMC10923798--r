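# Genome-wide windowed scans and divergence-outlier detection.

.lineageMapToList <- function(lineages, ids) {
  if (is.data.frame(lineages)) {
    stopifnot(all(c("sample_id", "lineage") %in% names(lineages)))
    lineages <- setNames(as.character(lineages$lineage),
                         lineages$sample_id)
  }
  miss <- setdiff(ids, names(lineages))
  if (length(miss))
    stop("samples without lineage assignment: ", paste(miss, collapse = ", "))
  split(ids, lineages[ids])
}

#' Windowed genome scan of diversity, neutrality and differentiation
#'
#' Computes, per lineage, nucleotide diversity, segregating sites and
#' Watterson's theta on the diversity window grid (default 50 kb windows,
#' 12.5 kb step) and Tajima's D plus Fu's F(S) on the neutrality grid
#' (default 10 kb windows, 2.5 kb step), and per lineage pair Hudson's F_ST
#' and D_XY on the diversity grid.  Lineages with a single sample are
#' excluded from all population statistics (reported via a message).
#'
#' @param x a [SnpAlignment-class].
#' @param lineages named character vector mapping sample id to lineage, or a
#'   data.frame with columns `sample_id`, `lineage`.
#' @param divSize,divStep diversity/differentiation window size and step (bp).
#' @param neutSize,neutStep neutrality window size and step (bp).
#' @return A [GenomeScan-class].
#' @export
scanGenome <- function(x, lineages, divSize = 50000, divStep = 12500,
                       neutSize = 10000, neutStep = 2500) {
  groups <- .lineageMapToList(lineages, sampleIds(x))
  singletons <- names(groups)[lengths(groups) < 2]
  if (length(singletons)) {
    message("excluding singleton lineage(s) from population statistics: ",
            paste(singletons, collapse = ", "))
    groups <- groups[lengths(groups) >= 2]
  }
  if (length(groups) < 1) stop("no lineage with >= 2 samples")
  lins <- sort(names(groups))
  pos <- x@positions

  # per-site per-lineage summaries, cumulated for O(1) window sums
  persite <- lapply(lins, function(l) {
    sc <- .siteCounts(x, groups[[l]], seq_along(pos))
    list(alt = sc$alt, n = sc$n,
         cpi = cumsum(.piSite(sc$alt, sc$n)),
         cseg = cumsum(as.numeric(sc$alt > 0 & sc$alt < sc$n)))
  })
  names(persite) <- lins

  winSum <- function(cv, lo, hi) {
    if (hi < lo) return(0)
    cv[hi] - if (lo > 1) cv[lo - 1] else 0
  }

  dwin <- iterWindows(genomeLength(x), divSize, divStep)
  nwin <- iterWindows(genomeLength(x), neutSize, neutStep)
  dlo <- findInterval(dwin$start - 0.5, pos) + 1L
  dhi <- findInterval(dwin$end + 0.5, pos)
  nlo <- findInterval(nwin$start - 0.5, pos) + 1L
  nhi <- findInterval(nwin$end + 0.5, pos)

  lineageStats <- do.call(rbind, lapply(lins, function(l) {
    ps <- persite[[l]]
    L <- divSize
    pi <- mapply(function(lo, hi) winSum(ps$cpi, lo, hi), dlo, dhi) / L
    S <- mapply(function(lo, hi) winSum(ps$cseg, lo, hi), dlo, dhi)
    n <- length(groups[[l]])
    data.frame(start = dwin$start, end = dwin$end, lineage = l,
               pi = pi, S = as.integer(S),
               theta_w = S / (sum(1 / seq_len(n - 1)) * L))
  }))

  neutralityStats <- do.call(rbind, lapply(lins, function(l) {
    ps <- persite[[l]]
    n <- length(groups[[l]])
    td <- mapply(function(lo, hi) {
      if (n < 3) return(NaN)
      .tajimasDFromCounts(n, winSum(ps$cseg, lo, hi), winSum(ps$cpi, lo, hi))
    }, nlo, nhi)
    ff <- mapply(function(s, e) fusF(x, groups[[l]], s, e),
                 nwin$start, nwin$end)
    data.frame(start = nwin$start, end = nwin$end, lineage = l,
               tajima_d = td, fu_f = ff)
  }))

  pairStats <- NULL
  if (length(lins) >= 2) {
    pairs <- utils::combn(lins, 2)
    pairStats <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- persite[[pairs[1, i]]]; b <- persite[[pairs[2, i]]]
      cross <- a$alt * (b$n - b$alt) + b$alt * (a$n - a$alt)
      npairs <- a$n * b$n
      ccross <- cumsum(ifelse(npairs > 0, cross / npairs, 0))
      dxyv <- mapply(function(lo, hi) winSum(ccross, lo, hi), dlo, dhi) /
        divSize
      hw <- (mapply(function(lo, hi) winSum(a$cpi, lo, hi), dlo, dhi) +
             mapply(function(lo, hi) winSum(b$cpi, lo, hi), dlo, dhi)) /
        (2 * divSize)
      data.frame(start = dwin$start, end = dwin$end,
                 lineageA = pairs[1, i], lineageB = pairs[2, i],
                 fst = ifelse(dxyv == 0, NaN, 1 - hw / dxyv), dxy = dxyv)
    }))
  } else {
    pairStats <- data.frame(start = integer(), end = integer(),
                            lineageA = character(), lineageB = character(),
                            fst = numeric(), dxy = numeric())
  }

  new("GenomeScan", lineageStats = lineageStats, pairStats = pairStats,
      neutralityStats = neutralityStats, genomeLength = genomeLength(x),
      windowSpecs = list(diversity = c(size = divSize, step = divStep),
                         neutrality = c(size = neutSize, step = neutStep)))
}

#' One-sample t-test for departure of a neutrality statistic from zero
#'
#' Two-sided one-sample t-test of per-window values against 0.  `NaN`
#' windows are dropped (the count is reported); all-NaN input is an error,
#' and zero variance yields `NaN` t and p with a flag.
#'
#' @param values numeric vector of per-window statistic values for one
#'   lineage.
#' @return list with `mean`, `t`, `p`, `n_windows`, `n_dropped`.
#' @export
neutralityDepartureTest <- function(values) {
  keep <- values[!is.na(values)]
  if (length(keep) < 2)
    stop("need at least 2 non-NaN window values")
  if (sd(keep) == 0) {
    warning("zero variance across windows; t-test undefined")
    return(list(mean = mean(keep), t = NaN, p = NaN,
                n_windows = length(keep),
                n_dropped = length(values) - length(keep)))
  }
  tt <- t.test(keep, mu = 0)
  list(mean = mean(keep), t = unname(tt$statistic), p = tt$p.value,
       n_windows = length(keep), n_dropped = length(values) - length(keep))
}

#' @rdname neutralityDepartureTest
#' @param scan a [GenomeScan-class]; the data.frame method summarizes both
#'   neutrality statistics for every lineage.
#' @return `neutralityDeparture`: data.frame with one row per lineage and
#'   statistic.
#' @export
neutralityDeparture <- function(scan) {
  ns <- neutralityStats(scan)
  do.call(rbind, lapply(split(ns, ns$lineage), function(d) {
    do.call(rbind, lapply(c("tajima_d", "fu_f"), function(st) {
      r <- tryCatch(neutralityDepartureTest(d[[st]]),
                    error = function(e) list(mean = NaN, t = NaN, p = NaN,
                                             n_windows = 0, n_dropped = nrow(d)))
      data.frame(lineage = d$lineage[1], statistic = st, mean = r$mean,
                 t = r$t, p = r$p, n_windows = r$n_windows)
    }))
  }))
}

#' Dual-percentile divergence-outlier regions
#'
#' Aggregates F_ST and D_XY per window across lineage pairs (default: the
#' mean over pairs), selects windows at or above the `q` quantile
#' (linear-interpolation quantile; ties included) in *both* metrics, merges
#' overlapping or adjacent selected windows, and attaches genes overlapping
#' each merged region by at least 1 bp.
#'
#' With `mode = "per-pair"` thresholds are computed within each lineage pair
#' and a window is selected when it exceeds both thresholds for at least one
#' pair.
#'
#' @param scan a [GenomeScan-class].
#' @param q quantile in (0, 1); default 0.99.  Fewer than 100 windows
#'   triggers a warning.
#' @param genes optional `GRanges` of gene models (metadata column
#'   `gene_id`).
#' @param mode `"mean"` (default) or `"per-pair"`.
#' @return `GRanges` of merged outlier regions with metadata columns
#'   `n_windows`, `mean_fst`, `mean_dxy` and (if `genes` given) `gene_ids`
#'   (CharacterList).
#' @export
outlierRegions <- function(scan, q = 0.99, genes = NULL,
                           mode = c("mean", "per-pair")) {
  mode <- match.arg(mode)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ps <- pairStats(scan)
  if (!nrow(ps)) stop("scan contains no lineage pairs")
  key <- paste(ps$start, ps$end)
  wins <- unique(ps[c("start", "end")])
  if (nrow(wins) < 100)
    warning("fewer than 100 windows; quantile q = ", q, " is coarse")

  if (mode == "mean") {
    fst <- tapply(ps$fst, key, mean, na.rm = TRUE)[paste(wins$start, wins$end)]
    dxyv <- tapply(ps$dxy, key, mean, na.rm = TRUE)[paste(wins$start, wins$end)]
    okf <- !is.na(fst); okd <- !is.na(dxyv)
    tf <- quantile(fst[okf], q, type = 7)
    td <- quantile(dxyv[okd], q, type = 7)
    sel <- okf & okd & fst >= tf & dxyv >= td
    selFst <- fst; selDxy <- dxyv
  } else {
    sel <- rep(FALSE, nrow(wins))
    for (pp in split(ps, paste(ps$lineageA, ps$lineageB))) {
      tf <- quantile(pp$fst[!is.na(pp$fst)], q, type = 7)
      td <- quantile(pp$dxy[!is.na(pp$dxy)], q, type = 7)
      hit <- !is.na(pp$fst) & !is.na(pp$dxy) & pp$fst >= tf & pp$dxy >= td
      sel <- sel | hit[match(paste(wins$start, wins$end),
                             paste(pp$start, pp$end))]
    }
    selFst <- tapply(ps$fst, key, mean, na.rm = TRUE)[paste(wins$start, wins$end)]
    selDxy <- tapply(ps$dxy, key, mean, na.rm = TRUE)[paste(wins$start, wins$end)]
  }

  if (!any(sel, na.rm = TRUE))
    return(GRanges())
  selWins <- wins[which(sel), , drop = FALSE]
  gr <- GRanges("genome", IRanges(selWins$start, selWins$end))
  merged <- reduce(gr, min.gapwidth = 1L)
  ov <- findOverlaps(gr, merged)
  mcols(merged)$n_windows <- as.integer(table(factor(
    S4Vectors::subjectHits(ov), levels = seq_along(merged))))
  agg <- function(v) as.numeric(tapply(
    v[which(sel)][S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), mean))
  mcols(merged)$mean_fst <- agg(selFst)
  mcols(merged)$mean_dxy <- agg(selDxy)
  if (!is.null(genes)) {
    gg <- GRanges("genome", IRanges(start(genes), end(genes)))
    gov <- findOverlaps(merged, gg)
    ids <- split(mcols(genes)$gene_id[S4Vectors::subjectHits(gov)],
                 factor(S4Vectors::queryHits(gov), levels = seq_along(merged)))
    mcols(merged)$gene_ids <- IRanges::CharacterList(ids)
  }
  merged
}
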