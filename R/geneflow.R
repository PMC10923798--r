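# Gene-flow quantities from recombination-event lists: within/between-lineage
# genome fractions, per-strain r/m and rho/theta, and divergence-probability
# staging of lineage pairs.

.carrierLineages <- function(events, lineages, strict = TRUE) {
  lapply(mcols(events)$carriers, function(cc) {
    known <- cc %in% names(lineages)
    if (!all(known)) {
      msg <- paste("unknown carrier(s):",
                   paste(cc[!known], collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      cc <- cc[known]
    }
    unique(unname(lineages[cc]))
  })
}

#' Attribute recombination events to within- or between-lineage gene flow
#'
#' An event whose carriers all belong to one lineage is *within* that
#' lineage; an event whose carriers span two or more lineages contributes a
#' *between* record for every intersected lineage pair (one block may be
#' counted more than once).  Single-carrier events are within-lineage
#' (terminal-branch events) and are flagged separately.
#'
#' @param events `GRanges` with a `carriers` metadata column.
#' @param lineages named lineage map (sample id -> lineage).
#' @param strict error on carriers without a lineage assignment.
#' @return data.frame with one row per (event, category): `event`, `type`
#'   (`within`/`between`), `lineageA`, `lineageB` (equal for within),
#'   `start`, `end`, `single_carrier`.
#' @export
attributeEvents <- function(events, lineages, strict = TRUE) {
  lineages <- if (is.data.frame(lineages))
    setNames(as.character(lineages$lineage), lineages$sample_id) else lineages
  linsPerEvent <- .carrierLineages(events, lineages, strict)
  rows <- lapply(seq_along(events), function(i) {
    lv <- sort(linsPerEvent[[i]])
    single <- length(mcols(events)$carriers[[i]]) == 1
    if (length(lv) <= 1) {
      data.frame(event = i, type = "within", lineageA = lv, lineageB = lv,
                 start = start(events)[i], end = end(events)[i],
                 single_carrier = single)
    } else {
      pr <- utils::combn(lv, 2)
      data.frame(event = i, type = "between", lineageA = pr[1, ],
                 lineageB = pr[2, ], start = start(events)[i],
                 end = end(events)[i], single_carrier = single)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome fractions subjected to gene flow
#'
#' In `summed` mode (how such fractions are usually reported) every event's
#' length is counted for every category it touches, so overlapping blocks are
#' counted repeatedly and a lineage's summed fraction may exceed 1.  In
#' `union` mode each category's events are collapsed to their interval union
#' first, so fractions are true genome proportions (<= 1); union mode is
#' required for divergence probabilities ([upcelStages()]).
#'
#' @param events `GRanges` with `carriers`.
#' @param lineages named lineage map.
#' @param genomeLength reference length (bp).
#' @param mode `"summed"` or `"union"`.
#' @return list of class `geneFlowMatrix`: `within` (named vector),
#'   `between` (symmetric lineage x lineage matrix), `mode`,
#'   `genome_length`.
#' @export
geneflowFractions <- function(events, lineages, genomeLength,
                              mode = c("summed", "union")) {
  mode <- match.arg(mode)
  if (genomeLength <= 0) stop("genomeLength must be positive")
  if (length(events) && (any(start(events) < 1) ||
                         any(end(events) > genomeLength)))
    stop("event outside genome bounds")
  lineages <- if (is.data.frame(lineages))
    setNames(as.character(lineages$lineage), lineages$sample_id) else lineages
  lins <- sort(unique(unname(lineages)))
  within <- setNames(numeric(length(lins)), lins)
  between <- matrix(0, length(lins), length(lins),
                    dimnames = list(lins, lins))
  frac <- function(starts, ends) {
    if (!length(starts)) return(0)
    if (mode == "summed") sum(ends - starts + 1) / genomeLength
    else sum(width(reduce(IRanges(starts, ends)))) / genomeLength
  }
  if (length(events)) {
    attr <- attributeEvents(events, lineages)
    for (l in lins) {
      w <- attr[attr$type == "within" & attr$lineageA == l, ]
      within[l] <- frac(w$start, w$end)
    }
    bt <- attr[attr$type == "between", ]
    if (nrow(bt)) for (p in split(bt, paste(bt$lineageA, bt$lineageB))) {
      f <- frac(p$start, p$end)
      between[p$lineageA[1], p$lineageB[1]] <- f
      between[p$lineageB[1], p$lineageA[1]] <- f
    }
  }
  structure(list(within = within, between = between, mode = mode,
                 genome_length = genomeLength), class = "geneFlowMatrix")
}

#' @export
print.geneFlowMatrix <- function(x, ...) {
  cat("Gene-flow fractions (", x$mode, " mode) over ", x$genome_length,
      " bp\n", sep = "")
  cat("within:\n"); print(signif(x$within, 4))
  cat("between:\n"); print(signif(x$between, 4))
  invisible(x)
}

#' Per-strain recombination parameters
#'
#' For one strain, with its SNPs defined as the positions where it carries
#' the alternate allele relative to the reference: `r/m` is the ratio of
#' SNPs inside the union of its recombination tracts to SNPs outside, and
#' `rho/theta` is the ratio of its event count to SNPs outside tracts (zero
#' outside-SNPs give `NaN` with a warning).  `frac_recombined` is the
#' fraction of the genome covered by the union of its tracts.
#'
#' @param events `GRanges` with `carriers`.
#' @param x a [SnpAlignment-class].
#' @param sample sample id.
#' @param lineages optional lineage map (adds the lineage label).
#' @return one-row data.frame: `sample_id`, `lineage`, `n_events`,
#'   `snps_inside`, `snps_outside`, `rm`, `rho_theta`, `frac_recombined`.
#' @export
strainRecombParams <- function(events, x, sample, lineages = NULL) {
  if (!sample %in% sampleIds(x))
    stop("no SNP data for sample ", sample)
  gv <- x@genotypes[sample, ]
  snpPos <- x@positions[!is.na(gv) & gv == 1L]
  mine <- if (length(events))
    events[vapply(mcols(events)$carriers, function(cc) sample %in% cc,
                  logical(1))] else events
  un <- reduce(IRanges(start(mine), end(mine)))
  inside <- if (length(un))
    sum(IRanges::overlapsAny(IRanges(snpPos, snpPos), un)) else 0L
  outside <- length(snpPos) - inside
  rm <- if (outside == 0) {
    if (inside > 0 || length(mine) > 0)
      warning("no SNPs outside tracts for ", sample, "; ratios undefined")
    if (inside == 0 && length(mine) == 0) 0 else NaN
  } else inside / outside
  rt <- if (outside == 0) {
    if (length(mine) == 0) 0 else NaN
  } else length(mine) / outside
  lin <- if (!is.null(lineages)) {
    lm <- if (is.data.frame(lineages))
      setNames(as.character(lineages$lineage), lineages$sample_id) else
        lineages
    unname(lm[sample])
  } else NA_character_
  data.frame(sample_id = sample, lineage = lin,
             n_events = length(mine), snps_inside = inside,
             snps_outside = outside, rm = rm, rho_theta = rt,
             frac_recombined = sum(width(un)) / genomeLength(x))
}

#' @rdname strainRecombParams
#' @return `strainRecombSummary`: the per-strain table for all samples.
#' @export
strainRecombSummary <- function(events, x, lineages = NULL) {
  out <- do.call(rbind, lapply(sampleIds(x), function(s)
    strainRecombParams(events, x, s, lineages)))
  rownames(out) <- NULL
  out
}

#' Compare recombination parameters across lineages or habitats
#'
#' Tie-corrected Kruskal-Wallis test followed by Dunn's pairwise test with
#' Bonferroni adjustment on a per-strain recombination summary.  Groups with
#' fewer than 2 members are dropped with a message.
#'
#' @param summaries data.frame from [strainRecombSummary()] (or any table
#'   with the value and grouping columns).
#' @param value column to compare (e.g. `"rho_theta"` or `"rm"`).
#' @param group grouping column (e.g. `"lineage"` or `"habitat"`).
#' @return list with `H`, `df`, `p` and `dunn` (pairwise table).
#' @export
lineageRecombComparison <- function(summaries, value = "rho_theta",
                                    group = "lineage") {
  v <- summaries[[value]]
  g <- as.character(summaries[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    message("dropping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    sel <- !g %in% small
    v <- v[sel]; g <- g[sel]
  }
  if (length(unique(g)) < 2) stop("need >= 2 groups with >= 2 members")
  kw <- kruskalWallis(split(v, g))
  list(H = kw$H, df = kw$df, p = kw$p,
       dunn = dunnPosthoc(v, g, adjust = "bonferroni"))
}

#' Divergence probability and speciation stage per lineage pair
#'
#' The genome fraction resistant to between-lineage gene flow serves as a
#' proxy of the divergence probability: `P_div = 1 - fraction_between`,
#' clamped to `[0, 1]`.  Stages follow configurable thresholds on `P_div`
#' (defaults: species at >= 0.89, grey zone at >= 0.85, early below);
#' thresholds are presentation, not inference, and `P_div` is a proxy, not a
#' fitted probability.
#'
#' @param gfm a `geneFlowMatrix` in union mode (fractions must be true
#'   proportions).
#' @param thresholds named numeric `c(species = ..., grey = ...)`, strictly
#'   descending.
#' @return data.frame: `lineageA`, `lineageB`, `fraction_between`, `p_div`,
#'   `stage` (one of `"species (stages 4-5)"`, `"grey zone (stages 2-3)"`,
#'   `"early (stages 1-2)"`).
#' @export
upcelStages <- function(gfm, thresholds = c(species = 0.89, grey = 0.85)) {
  stopifnot(inherits(gfm, "geneFlowMatrix"))
  if (gfm$mode != "union")
    stop("divergence probabilities require union-mode fractions")
  if (length(thresholds) != 2 || diff(thresholds) >= 0)
    stop("thresholds must be two strictly descending values")
  lins <- names(gfm$within)
  if (length(lins) < 2) stop("need >= 2 lineages")
  pr <- utils::combn(lins, 2)
  fb <- gfm$between[cbind(pr[1, ], pr[2, ])]
  pdiv <- pmin(pmax(1 - fb, 0), 1)
  stage <- ifelse(pdiv >= thresholds["species"], "species (stages 4-5)",
           ifelse(pdiv >= thresholds["grey"], "grey zone (stages 2-3)",
                  "early (stages 1-2)"))
  data.frame(lineageA = pr[1, ], lineageB = pr[2, ], fraction_between = fb,
             p_div = pdiv, stage = stage)
}
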