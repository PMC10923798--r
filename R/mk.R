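# McDonald-Kreitman tests: per-gene contrasts of nonsynonymous vs synonymous
# polymorphism and divergence against a reference genome.

.GENETIC_CODE <- Biostrings::GENETIC_CODE  # table 11 elongation == standard

.complementBase <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.translateCodon <- function(codon) {
  if (any(!codon %in% c("A", "C", "G", "T"))) return(NA_character_)
  unname(.GENETIC_CODE[paste(codon, collapse = "")])
}

#' Classify segregating and fixed changes of one gene
#'
#' For each SNP inside the gene the ingroup is compared with the reference
#' genome: a site is a *fixed difference* when all non-missing ingroup
#' genotypes carry the alternate allele, and *polymorphic* when both alleles
#' segregate in the ingroup.  Synonymous versus nonsynonymous status is
#' decided by translating the codon with each allele substituted into the
#' ingroup-consensus codon background (ties in the consensus resolved toward
#' the reference allele); minus-strand genes are reverse-complemented.
#' Sites with missing genotypes in more than `maxMissing` of the ingroup are
#' excluded and counted.
#'
#' Genes whose reference frame contains an internal stop are flagged and
#' skipped (`skipped = TRUE`).
#'
#' @param gene one-row `GRanges` (or list with `start`, `end`, `strand`);
#'   length must be a multiple of 3.
#' @param x a [SnpAlignment-class].
#' @param ingroup sample ids forming the ingroup.
#' @param refSeq reference genome sequence (single string).
#' @param maxMissing maximum tolerated fraction of missing genotypes per
#'   site (default 0.5).
#' @return list with integer counts `Dn`, `Ds`, `Pn`, `Ps`, plus
#'   `n_excluded_missing` and `skipped`.
#' @export
classifySiteChanges <- function(gene, x, ingroup, refSeq, maxMissing = 0.5) {
  if (inherits(gene, "GRanges")) {
    gs <- start(gene)[1]; ge <- end(gene)[1]
    gstrand <- as.character(strand(gene))[1]
  } else {
    gs <- gene$start; ge <- gene$end; gstrand <- gene$strand
  }
  glen <- ge - gs + 1
  if (glen %% 3 != 0) stop("gene length not a multiple of 3")
  ingroup <- .resolveSamples(x, ingroup)

  refChars <- strsplit(toupper(refSeq), "")[[1]]
  geneRef <- refChars[gs:ge]
  if (gstrand == "-") geneRef <- rev(unname(.complementBase[geneRef]))
  aaRef <- vapply(seq_len(glen / 3), function(i)
    .translateCodon(geneRef[(3 * i - 2):(3 * i)]) %||% NA_character_,
    character(1))
  if (any(aaRef[-length(aaRef)] == "*", na.rm = TRUE))
    return(list(Dn = 0L, Ds = 0L, Pn = 0L, Ps = 0L,
                n_excluded_missing = 0L, skipped = TRUE,
                reason = "internal stop codon in reference frame"))

  idx <- .siteIdx(x, gs, ge)
  counts <- c(Dn = 0L, Ds = 0L, Pn = 0L, Ps = 0L)
  excluded <- 0L
  if (length(idx)) {
    g <- x@genotypes[ingroup, idx, drop = FALSE]
    alt <- colSums(g == 1L, na.rm = TRUE)
    n <- colSums(!is.na(g))
    posAll <- x@positions[idx]
    # gene-oriented offsets (0-based) and oriented alleles
    off <- if (gstrand == "-") ge - posAll else posAll - gs
    refAll <- x@refAllele[idx]; altAll <- x@altAllele[idx]
    if (gstrand == "-") {
      refAll <- unname(.complementBase[refAll])
      altAll <- unname(.complementBase[altAll])
    }
    keep <- n >= length(ingroup) * (1 - maxMissing) & n > 0
    excluded <- sum(!keep)
    # consensus background across all retained SNP sites of the gene
    consensus <- geneRef
    consAllele <- ifelse(alt > n / 2, altAll, refAll)
    consensus[off[keep] + 1L] <- consAllele[keep]
    for (j in which(keep)) {
      if (alt[j] == 0) next  # ingroup matches reference: no change
      type <- if (alt[j] == n[j]) "D" else "P"
      ci <- off[j] %/% 3L
      codon <- consensus[(3 * ci + 1):(3 * ci + 3)]
      p <- off[j] %% 3L + 1L
      c1 <- codon; c1[p] <- refAll[j]
      c2 <- codon; c2[p] <- altAll[j]
      aa1 <- .translateCodon(c1); aa2 <- .translateCodon(c2)
      if (is.na(aa1) || is.na(aa2)) { excluded <- excluded + 1L; next }
      cls <- if (aa1 == aa2) "s" else "n"
      key <- paste0(type, cls)
      counts[key] <- counts[key] + 1L
    }
  }
  list(Dn = unname(counts["Dn"]), Ds = unname(counts["Ds"]),
       Pn = unname(counts["Pn"]), Ps = unname(counts["Ps"]),
       n_excluded_missing = excluded, skipped = FALSE)
}

#' McDonald-Kreitman test on a 2x2 contingency table
#'
#' Neutrality index `NI = (Pn/Ps) / (Dn/Ds)`; a zero in any of `Ps`, `Dn`,
#' `Ds` leaves NI undefined (no continuity correction).  Significance by
#' Fisher's exact two-sided test on `[[Dn, Ds], [Pn, Ps]]`.  Classification
#' at level `alpha`: positive selection when `NI < 1` and `p < alpha`,
#' negative when `NI > 1` and `p < alpha`, otherwise none (undefined when NI
#' is undefined).
#'
#' @param Dn,Ds fixed nonsynonymous / synonymous differences.
#' @param Pn,Ps segregating nonsynonymous / synonymous polymorphisms.
#' @param alpha significance level (default 0.05).
#' @return list with `Dn`, `Ds`, `Pn`, `Ps`, `NI`, `p`, `class`.
#' @examples
#' mkTest(10, 5, 2, 4)  # NI = 0.25
#' @export
mkTest <- function(Dn, Ds, Pn, Ps, alpha = 0.05) {
  counts <- c(Dn, Ds, Pn, Ps)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  NI <- if (Ps == 0 || Dn == 0 || Ds == 0) NA_real_ else
    (Pn / Ps) / (Dn / Ds)
  p <- fisher.test(matrix(c(Dn, Ds, Pn, Ps), nrow = 2,
                          byrow = TRUE))$p.value
  cls <- if (is.na(NI)) "undefined"
         else if (NI < 1 && p < alpha) "positive"
         else if (NI > 1 && p < alpha) "negative"
         else "none"
  list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps, NI = NI, p = p, class = cls)
}

#' Genome-wide McDonald-Kreitman scan
#'
#' Runs [classifySiteChanges()] + [mkTest()] for every gene and every
#' lineage with at least 2 samples, polarizing divergence against the
#' reference genome sequence.  Genes flagged as not a multiple of 3, or with
#' an internal reference-frame stop, are reported with class `skipped`.
#' Genes overlapping the supplied outlier `regions` are flagged as
#' candidates.
#'
#' @param genes `GRanges` of gene models (metadata `gene_id`, `flagged`).
#' @param x a [SnpAlignment-class].
#' @param lineages named lineage map (see [scanGenome()]).
#' @param refSeq reference genome sequence (single string).
#' @param alpha per-gene significance level.
#' @param regions optional `GRanges` of divergence-outlier regions.
#' @param correction `"none"` (default, per-gene Fisher significance) or
#'   `"BH"` for Benjamini-Hochberg adjustment within each lineage.
#' @return data.frame with one row per gene x lineage: counts, `NI`, `p`,
#'   `class`, `in_outlier_region`.
#' @export
genomewideMk <- function(genes, x, lineages, refSeq, alpha = 0.05,
                         regions = NULL, correction = c("none", "BH")) {
  correction <- match.arg(correction)
  groups <- .lineageMapToList(lineages, sampleIds(x))
  groups <- groups[lengths(groups) >= 2]
  if (!length(genes))
    return(data.frame(gene_id = character(), lineage = character(),
                      Dn = integer(), Ds = integer(), Pn = integer(),
                      Ps = integer(), NI = numeric(), p = numeric(),
                      class = character(), in_outlier_region = logical()))
  inRegion <- rep(FALSE, length(genes))
  if (!is.null(regions) && length(regions)) {
    gg <- GRanges("genome", IRanges(start(genes), end(genes)))
    rr <- GRanges("genome", IRanges(start(regions), end(regions)))
    inRegion <- IRanges::overlapsAny(gg, rr)
  }
  flagged <- if (!is.null(mcols(genes)$flagged)) mcols(genes)$flagged else
    (width(genes) %% 3L) != 0L
  res <- do.call(rbind, lapply(names(groups), function(l) {
    do.call(rbind, lapply(seq_along(genes), function(i) {
      row <- data.frame(gene_id = mcols(genes)$gene_id[i], lineage = l,
                        Dn = NA_integer_, Ds = NA_integer_,
                        Pn = NA_integer_, Ps = NA_integer_, NI = NA_real_,
                        p = NA_real_, class = "skipped",
                        in_outlier_region = inRegion[i])
      if (flagged[i]) return(row)
      cc <- classifySiteChanges(genes[i], x, groups[[l]], refSeq)
      if (cc$skipped) return(row)
      mk <- mkTest(cc$Dn, cc$Ds, cc$Pn, cc$Ps, alpha)
      row[c("Dn", "Ds", "Pn", "Ps")] <- mk[c("Dn", "Ds", "Pn", "Ps")]
      row$NI <- mk$NI; row$p <- mk$p; row$class <- mk$class
      row
    }))
  }))
  if (correction == "BH") {
    for (l in unique(res$lineage)) {
      sel <- res$lineage == l & !is.na(res$p)
      padj <- p.adjust(res$p[sel], "BH")
      res$p[sel] <- padj
      defined <- sel & !is.na(res$NI)
      res$class[defined] <-
        ifelse(res$NI[defined] < 1 & res$p[defined] < alpha, "positive",
        ifelse(res$NI[defined] > 1 & res$p[defined] < alpha, "negative",
               "none"))
    }
  }
  rownames(res) <- NULL
  res
}
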