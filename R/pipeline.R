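# End-to-end orchestration: simulate/load -> scan -> MK -> gene flow ->
# isolation statistics, with a consolidated report.

#' Cross-check sample-id consistency of a bundle
#'
#' Report-only validation: compares the sample ids seen by the alignment,
#' metadata, recombination events, tree and ANI matrix, and flags
#' duplicates.  Error-grade issues (duplicated ids, samples missing from
#' the metadata) are labelled `error`; the rest `warning`.
#'
#' @param bundle a `continuumBundle` (or any list with the same elements).
#' @return data.frame with columns `level`, `issue`; zero rows when fully
#'   consistent.
#' @export
validateInputs <- function(bundle) {
  issues <- data.frame(level = character(), issue = character())
  add <- function(level, issue)
    rbind(issues, data.frame(level = level, issue = issue))
  alnIds <- sampleIds(bundle$alignment)
  metaIds <- bundle$metadata$sample_id
  if (anyDuplicated(metaIds))
    issues <- add("error", "duplicated sample id in metadata")
  miss <- setdiff(alnIds, metaIds)
  if (length(miss))
    issues <- add("error", paste("missing-in-metadata:",
                                 paste(miss, collapse = ", ")))
  if (!is.null(bundle$tree)) {
    mt <- setdiff(alnIds, bundle$tree$tip.label)
    if (length(mt))
      issues <- add("warning", paste("missing-in-tree:",
                                     paste(mt, collapse = ", ")))
  }
  if (!is.null(bundle$ani)) {
    ma <- setdiff(alnIds, sampleIds(bundle$ani))
    if (length(ma))
      issues <- add("warning", paste("missing-in-ani:",
                                     paste(ma, collapse = ", ")))
  }
  if (!is.null(bundle$events) && length(bundle$events)) {
    ce <- setdiff(unique(unlist(mcols(bundle$events)$carriers)), alnIds)
    if (length(ce))
      issues <- add("warning", paste("unknown-event-carrier:",
                                     paste(ce, collapse = ", ")))
  }
  issues
}

#' Run the full speciation-continuum pipeline
#'
#' Executes every stage in dependency order on a simulated or loaded bundle:
#' windowed scan, neutrality departure tests, dual-percentile outlier
#' regions, genome-wide MK tests, gene-flow fractions (both counting modes)
#' with divergence-probability staging, per-strain recombination parameters,
#' and the isolation-by-distance/environment statistics.  When `outDir` is
#' given, per-stage tables and a consolidated `report.json` are written.
#'
#' @param input a [simConfig()] (the bundle is simulated first) or a
#'   `continuumBundle`.
#' @param outDir optional output directory.
#' @param divSize,divStep,neutSize,neutStep window specs (bp); defaults 50
#'   kb / 12.5 kb and 10 kb / 2.5 kb.
#' @param q outlier-region percentile.
#' @param alpha MK significance level.
#' @param nPerm permutations for Mantel and K tests.
#' @param upcelThresholds staging thresholds, see [upcelStages()].
#' @return list of class `continuumReport` with elements `validation`,
#'   `scan`, `neutrality`, `regions`, `mk`, `geneflow`, `strains`, `upcel`,
#'   `isolation`, `summary`.
#' @export
runPipeline <- function(input, outDir = NULL, divSize = 50000,
                        divStep = 12500, neutSize = 10000, neutStep = 2500,
                        q = 0.99, alpha = 0.05, nPerm = 999,
                        upcelThresholds = c(species = 0.89, grey = 0.85)) {
  bundle <- if (inherits(input, "simConfig")) simulateContinuum(input)
            else input
  stopifnot(inherits(bundle, "continuumBundle"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  validation <- stage("validate", validateInputs(bundle))
  lineages <- setNames(bundle$metadata$lineage, bundle$metadata$sample_id)

  scan <- stage("scan", scanGenome(bundle$alignment, lineages,
                                   divSize, divStep, neutSize, neutStep))
  neut <- stage("neutrality", neutralityDeparture(scan))
  regions <- stage("outliers", suppressWarnings(
    outlierRegions(scan, q = q, genes = bundle$genes)))
  mk <- stage("mktest", genomewideMk(bundle$genes, bundle$alignment,
                                     lineages, bundle$ref_seq,
                                     alpha = alpha, regions = regions))
  gfUnion <- stage("geneflow", geneflowFractions(
    bundle$events, lineages, genomeLength(bundle$alignment), "union"))
  gfSummed <- stage("geneflow", geneflowFractions(
    bundle$events, lineages, genomeLength(bundle$alignment), "summed"))
  strains <- stage("geneflow", strainRecombSummary(
    bundle$events, bundle$alignment, lineages))
  upcel <- stage("upcel", if (length(gfUnion$within) >= 2)
    upcelStages(gfUnion, upcelThresholds) else NULL)

  isolation <- stage("isolation", {
    gd <- aniDistanceMatrix(bundle$ani)
    geo <- geoDistanceMatrix(bundle$metadata)
    res <- list(ibd = mantelTest(gd, geo, nPerm = nPerm))
    envVars <- grep("^env_", names(bundle$metadata), value = TRUE)
    if (length(envVars)) {
      res$ibe <- mantelTest(gd, envDistanceMatrix(bundle$metadata),
                            nPerm = nPerm)
      if (!is.null(bundle$tree))
        res$signal <- do.call(rbind, lapply(envVars, function(v) {
          tr <- setNames(bundle$metadata[[v]], bundle$metadata$sample_id)
          k <- blombergK(bundle$tree, tr, nPerm = nPerm)
          l <- pagelLambda(bundle$tree, tr)
          data.frame(trait = v, K = k$K, K_p = k$p, lambda = l$lambda,
                     lambda_p = l$p)
        }))
    }
    res$clusters <- aniCluster(bundle$ani, threshold = 95)
    if (!is.null(bundle$metadata$hgt_count))
      res$hgt <- hgtPerMb(bundle$metadata)
    res
  })

  mkPos <- unique(mk$gene_id[mk$class == "positive"])
  summary <- list(
    n_samples = nSamples(bundle$alignment),
    n_snps = nSites(bundle$alignment),
    lineage_pi_mean = tapply(lineageStats(scan)$pi,
                             lineageStats(scan)$lineage, mean),
    pair_fst_mean = if (nrow(pairStats(scan)))
      tapply(pairStats(scan)$fst,
             paste(pairStats(scan)$lineageA, pairStats(scan)$lineageB),
             mean, na.rm = TRUE) else NULL,
    pair_dxy_mean = if (nrow(pairStats(scan)))
      tapply(pairStats(scan)$dxy,
             paste(pairStats(scan)$lineageA, pairStats(scan)$lineageB),
             mean, na.rm = TRUE) else NULL,
    n_outlier_regions = length(regions),
    mk_positive_genes = mkPos,
    n_ani_clusters = length(unique(isolation$clusters)),
    mantel_ibd_r = isolation$ibd$r,
    mantel_ibd_p = isolation$ibd$p)

  report <- structure(list(validation = validation, scan = scan,
                           neutrality = neut, regions = regions, mk = mk,
                           geneflow = list(union = gfUnion,
                                           summed = gfSummed),
                           strains = strains, upcel = upcel,
                           isolation = isolation, summary = summary),
                      class = "continuumReport")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, name) write.table(
      d, file.path(outDir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(lineageStats(scan), "windows_lineage.tsv")
    wt(pairStats(scan), "windows_pairs.tsv")
    wt(neutralityStats(scan), "windows_neutrality.tsv")
    wt(neut, "neutrality_departure.tsv")
    regDf <- as.data.frame(regions)
    if (!is.null(regDf$gene_ids))
      regDf$gene_ids <- vapply(regDf$gene_ids, paste, "", collapse = ",")
    wt(regDf, "outlier_regions.tsv")
    wt(mk, "mk_results.tsv")
    wt(strains, "strain_recombination.tsv")
    if (!is.null(upcel)) wt(upcel, "upcel_stages.tsv")
    jsonlite::write_json(
      list(summary = summary,
           upcel = upcel,
           geneflow_within = as.list(gfUnion$within),
           validation_issues = validation$issue),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  report
}

#' @export
print.continuumReport <- function(x, ...) {
  cat("Speciation-continuum pipeline report\n")
  cat("  samples:", x$summary$n_samples, " SNPs:", x$summary$n_snps, "\n")
  cat("  mean pi per lineage:\n")
  print(signif(x$summary$lineage_pi_mean, 4))
  if (!is.null(x$summary$pair_fst_mean)) {
    cat("  mean F_ST per pair:\n"); print(signif(x$summary$pair_fst_mean, 4))
  }
  cat("  outlier regions:", x$summary$n_outlier_regions,
      " MK-positive genes:", length(x$summary$mk_positive_genes),
      " ANI clusters:", x$summary$n_ani_clusters, "\n")
  cat(sprintf("  isolation by distance: Mantel r = %.3f (p = %.4g)\n",
              x$summary$mantel_ibd_r, x$summary$mantel_ibd_p))
  if (!is.null(x$upcel)) {
    cat("  divergence-probability stages:\n")
    print(x$upcel)
  }
  invisible(x)
}
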