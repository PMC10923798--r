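# Synthetic speciation-continuum datasets with a machine-readable truth set.
#
# Generative model (documented in the methods vignette):
#  * one random reference (root) genome;
#  * each lineage founder diverges from the root at Bernoulli(d/2) sites
#    (island interval: d/2 * multiplier), at globally unique positions, so
#    every expected pairwise founder divergence is d (infinite sites);
#  * within-lineage haplotypes from a Kingman coalescent with per-site
#    mutation parameter theta (E[pi] = theta, E[S] = theta*L*a1), drawn
#    independently per recombination block to emulate the pervasive
#    homologous recombination of the organism;
#  * purifying selection inside genes: nonsynonymous mutations retained with
#    probability ns_retention;
#  * positive selection: designated genes receive omega_pos extra fixed
#    nonsynonymous differences per lineage;
#  * HR tracts copied donor -> recipient and recorded as events carrying
#    {recipient, donor};
#  * geography scattered around lineage centroids, environment by Brownian
#    motion on the clonal-frame tree, ANI from pairwise SNP identity.

.ACGT <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a multi-lineage biocrust
#' cyanobacterium collection: a 100 kb reference, four lineages of ten
#' strains, within-lineage diversity `theta = 0.005` and between-lineage
#' divergence `d = 0.015` per site (inside the ranges observed for such
#' collections), HR tracts of mean 2 kb at 2 per strain with 20% of donors
#' from another lineage.
#'
#' @param seed integer RNG seed; a single global stream drives the whole
#'   bundle.
#' @param n_lineages number of lineages K.
#' @param samples_per_lineage strains per lineage (recycled to K).
#' @param genome_length reference length G in bp.
#' @param theta within-lineage per-site diversity.
#' @param divergence expected per-site founder divergence d between any
#'   lineage pair.
#' @param island optional `list(start, end, multiplier)` divergence island.
#' @param tract_rate expected HR tracts per strain.
#' @param tract_mean_len mean tract length (geometric), bp.
#' @param between_tract_prob probability a tract's donor comes from another
#'   lineage; alternatively supply `migration`, a K x K matrix of donor
#'   weights (rows = recipient lineage), to simulate a migration gradient.
#' @param migration optional K x K donor-lineage weight matrix.
#' @param n_genes,codons_per_gene gene models tiled across the genome.
#' @param n_selected_genes number of genes given excess nonsynonymous fixed
#'   differences.
#' @param omega_pos implanted nonsynonymous fixed differences per selected
#'   gene and lineage.
#' @param ns_retention retention probability of nonsynonymous neutral
#'   mutations inside genes (purifying selection); 1 disables it.
#' @param recomb_block_len length of independently coalescing blocks, bp.
#' @param lineage_centroids optional data.frame `lat`, `lon` (one row per
#'   lineage).
#' @param scatter_km geographic scatter around the centroid.
#' @param n_env number of Brownian environmental variables.
#' @param brownian_sigma BM standard deviation per unit branch length.
#' @param hgt simulate per-sample HGT counts and genome sizes.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(seed = 1L, n_lineages = 4, samples_per_lineage = 10,
                      genome_length = 100000L, theta = 0.005,
                      divergence = 0.015, island = NULL, tract_rate = 2,
                      tract_mean_len = 2000, between_tract_prob = 0.2,
                      migration = NULL, n_genes = 20, codons_per_gene = 300,
                      n_selected_genes = 0, omega_pos = 20,
                      ns_retention = 0.2, recomb_block_len = 10000,
                      lineage_centroids = NULL, scatter_km = 50, n_env = 3,
                      brownian_sigma = 1, hgt = TRUE) {
  K <- as.integer(n_lineages)
  n <- rep_len(as.integer(samples_per_lineage), K)
  if (K < 1 || any(n < 1)) stop("need >= 1 sample per lineage")
  if (theta < 0 || theta > 0.2 || divergence < 0 || divergence > 0.2)
    stop("theta and divergence must lie in [0, 0.2]")
  G <- as.integer(genome_length)
  if (!is.null(island)) {
    if (island$start < 1 || island$end > G || island$start > island$end)
      stop("island interval outside [1, genome_length]")
  }
  if (n_genes > 0 && n_genes * codons_per_gene * 3 > G)
    stop("genes do not fit in the genome")
  if (!is.null(migration)) {
    migration <- as.matrix(migration)
    if (!all(dim(migration) == K) || any(migration < 0))
      stop("migration must be a non-negative K x K matrix")
  }
  if (n_selected_genes > n_genes) stop("more selected genes than genes")
  structure(list(seed = as.integer(seed), n_lineages = K,
                 samples_per_lineage = n, genome_length = G, theta = theta,
                 divergence = divergence, island = island,
                 tract_rate = tract_rate, tract_mean_len = tract_mean_len,
                 between_tract_prob = between_tract_prob,
                 migration = migration, n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene),
                 n_selected_genes = as.integer(n_selected_genes),
                 omega_pos = as.integer(omega_pos),
                 ns_retention = ns_retention,
                 recomb_block_len = as.integer(recomb_block_len),
                 lineage_centroids = lineage_centroids,
                 scatter_km = scatter_km, n_env = as.integer(n_env),
                 brownian_sigma = brownian_sigma, hgt = isTRUE(hgt)),
            class = "simConfig")
}

# Kingman coalescent on n tips: list of branches, each a tip-member set with
# a branch length (time while those tips share the branch); time units such
# that the pairwise coalescence time has mean 1 (so E[pi] = theta under
# Poisson(theta*L/2 * len) mutations per branch).
.kingmanBranches <- function(n) {
  active <- as.list(seq_len(n))
  blen <- numeric(n)
  branches <- vector("list", 2 * (n - 1))
  nb <- 0L
  k <- n
  while (k > 1) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t
    pick <- sort(sample.int(k, 2))
    for (p in pick) {
      nb <- nb + 1L
      branches[[nb]] <- list(members = active[[p]], len = blen[p])
    }
    merged <- c(active[[pick[1]]], active[[pick[2]]])
    active <- active[-pick]
    blen <- blen[-pick]
    active[[k - 1]] <- merged
    blen[k - 1] <- 0
    k <- k - 1L
  }
  branches[seq_len(nb)]
}

# is a substitution at pos to newBase nonsynonymous relative to the root
# codon background?  NA when pos is intergenic.
.nonsynVsRoot <- function(pos, newBase, geneIdx, geneTab, rootChars) {
  gi <- geneIdx[pos]
  if (gi == 0L) return(NA)
  gs <- geneTab$start[gi]; ge <- geneTab$end[gi]
  if (geneTab$strand[gi] == "+") {
    off <- pos - gs
    cs <- gs + 3L * (off %/% 3L)
    codon <- rootChars[cs:(cs + 2L)]
    p <- off %% 3L + 1L
    newB <- newBase
  } else {
    off <- ge - pos
    ci <- off %/% 3L
    gpos <- ge - (3L * ci):(3L * ci + 2L)
    codon <- unname(.complementBase[rootChars[gpos]])
    p <- off %% 3L + 1L
    newB <- unname(.complementBase[newBase])
  }
  c1 <- codon
  c2 <- codon; c2[p] <- newB
  a1 <- .translateCodon(c1); a2 <- .translateCodon(c2)
  if (is.na(a1) || is.na(a2)) return(NA)
  a1 != a2
}

#' Simulate a complete speciation-continuum dataset
#'
#' Runs the generative model described in [simConfig()] and returns an
#' in-memory bundle: the SNP alignment, reference sequence, gene models,
#' recombination events (with known carriers), per-sample metadata, the
#' clonal-frame tree, the ANI matrix and a truth set recording everything
#' that was implanted, including closed-form expected D_XY
#' (`d + theta_A(1-1/n_A) + theta_B(1-1/n_B)`) and Hudson F_ST per lineage
#' pair.
#'
#' Identical configurations (including the seed) yield byte-identical
#' bundles.
#'
#' @param config a [simConfig()].
#' @return list of class `continuumBundle` with elements `alignment`,
#'   `ref_seq`, `genes`, `events`, `metadata`, `tree`, `ani`, `truth`.
#' @export
simulateContinuum <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  K <- config$n_lineages
  G <- config$genome_length
  nPer <- config$samples_per_lineage
  linNames <- paste0("M", seq_len(K))
  members <- lapply(seq_len(K), function(l)
    sprintf("%s_s%02d", linNames[l], seq_len(nPer[l])))
  names(members) <- linNames
  ids <- unlist(members, use.names = FALSE)
  lineageOf <- setNames(rep(linNames, nPer), ids)

  rootChars <- sample(.ACGT, G, replace = TRUE)

  # gene models tiled across the genome, alternating strand
  geneTab <- NULL
  geneIdx <- integer(G)
  genes <- GRanges(gene_id = character())
  if (config$n_genes > 0) {
    glen <- 3L * config$codons_per_gene
    starts <- floor(seq(1, G - glen + 1, length.out = config$n_genes))
    geneTab <- data.frame(
      start = as.integer(starts), end = as.integer(starts + glen - 1L),
      strand = rep_len(c("+", "-"), config$n_genes),
      gene_id = sprintf("gene%03d", seq_len(config$n_genes)))
    # genes must be readable frames: replace any stop codon in the gene
    # frame with a random sense codon
    senseCodons <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
    for (i in seq_len(nrow(geneTab))) {
      p <- geneTab$start[i]:geneTab$end[i]
      oriented <- if (geneTab$strand[i] == "+") rootChars[p] else
        unname(.complementBase[rev(rootChars[p])])
      for (ci in seq_len(length(p) / 3)) {
        j <- (3 * ci - 2):(3 * ci)
        if (.GENETIC_CODE[paste(oriented[j], collapse = "")] == "*")
          oriented[j] <- strsplit(sample(senseCodons, 1), "")[[1]]
      }
      rootChars[p] <- if (geneTab$strand[i] == "+") oriented else
        unname(.complementBase[rev(oriented)])
      geneIdx[p] <- i
    }
    genes <- GRanges("chr1", IRanges(geneTab$start, geneTab$end),
                     strand = geneTab$strand)
    mcols(genes)$gene_id <- geneTab$gene_id
    mcols(genes)$phase <- 0L
    mcols(genes)$flagged <- FALSE
  }
  selectedGenes <- character()
  if (config$n_selected_genes > 0)
    selectedGenes <- sort(sample(geneTab$gene_id, config$n_selected_genes))

  used <- logical(G)
  # island site-probability multiplier
  isIsland <- logical(G)
  if (!is.null(config$island))
    isIsland[config$island$start:config$island$end] <- TRUE

  # a neutral mutation survives purifying selection inside genes
  acceptMutation <- function(pos, newBase) {
    ns <- .nonsynVsRoot(pos, newBase, geneIdx, geneTab, rootChars)
    if (is.na(ns) || !ns) return(TRUE)
    runif(1) < config$ns_retention
  }

  mutPos <- integer(); mutBase <- character(); mutCarriers <- list()

  # lineage founder divergence at unique sites
  d2 <- config$divergence / 2
  for (l in seq_len(K)) {
    for (stratum in list(which(!isIsland), which(isIsland))) {
      if (!length(stratum)) next
      p <- if (identical(stratum, which(isIsland)))
        min(1, d2 * config$island$multiplier) else d2
      nCand <- rbinom(1, length(stratum), p)
      if (nCand == 0) next
      avail <- stratum[!used[stratum]]
      take <- sample(avail, min(nCand, length(avail)))
      for (pos in take) {
        newBase <- sample(setdiff(.ACGT, rootChars[pos]), 1)
        if (!acceptMutation(pos, newBase)) next
        used[pos] <- TRUE
        mutPos <- c(mutPos, pos)
        mutBase <- c(mutBase, newBase)
        mutCarriers[[length(mutCarriers) + 1L]] <- members[[l]]
      }
    }
  }

  # implanted positive selection: omega_pos nonsynonymous fixed differences
  # per selected gene and lineage (bypass purifying thinning)
  for (gid in selectedGenes) {
    gi <- match(gid, geneTab$gene_id)
    gpos <- geneTab$start[gi]:geneTab$end[gi]
    for (l in seq_len(K)) {
      placed <- 0L; tries <- 0L
      while (placed < config$omega_pos && tries < 50L * config$omega_pos) {
        tries <- tries + 1L
        avail <- gpos[!used[gpos]]
        if (!length(avail)) break
        pos <- if (length(avail) == 1) avail else sample(avail, 1)
        newBase <- sample(setdiff(.ACGT, rootChars[pos]), 1)
        ns <- .nonsynVsRoot(pos, newBase, geneIdx, geneTab, rootChars)
        if (is.na(ns) || !ns) next
        used[pos] <- TRUE
        mutPos <- c(mutPos, pos)
        mutBase <- c(mutBase, newBase)
        mutCarriers[[length(mutCarriers) + 1L]] <- members[[l]]
        placed <- placed + 1L
      }
    }
  }

  # within-lineage coalescent variation, independent per block
  blockStarts <- seq.int(1L, G, by = config$recomb_block_len)
  for (l in seq_len(K)) {
    nl <- nPer[l]
    if (nl < 2) next
    for (bs in blockStarts) {
      be <- min(bs + config$recomb_block_len - 1L, G)
      Lb <- be - bs + 1L
      for (br in .kingmanBranches(nl)) {
        nMut <- rpois(1, config$theta * Lb / 2 * br$len)
        if (nMut == 0) next
        for (m in seq_len(nMut)) {
          pos <- NA
          for (try in 1:200) {
            cand <- bs + sample.int(Lb, 1) - 1L
            if (!used[cand]) { pos <- cand; break }
          }
          if (is.na(pos)) next  # block saturated
          newBase <- sample(setdiff(.ACGT, rootChars[pos]), 1)
          if (!acceptMutation(pos, newBase)) next
          used[pos] <- TRUE
          mutPos <- c(mutPos, pos)
          mutBase <- c(mutBase, newBase)
          mutCarriers[[length(mutCarriers) + 1L]] <- members[[l]][br$members]
        }
      }
    }
  }

  # assemble the SNP matrix (0 = root/reference allele)
  o <- order(mutPos)
  mutPos <- mutPos[o]; mutBase <- mutBase[o]; mutCarriers <- mutCarriers[o]
  geno <- matrix(0L, nrow = length(ids), ncol = length(mutPos),
                 dimnames = list(ids, NULL))
  for (j in seq_along(mutPos))
    geno[mutCarriers[[j]], j] <- 1L
  aln <- SnpAlignment(geno, mutPos, rootChars[mutPos], mutBase, G, "chr1")

  # HR tracts, applied sequentially (last writer wins)
  migration <- config$migration
  if (is.null(migration)) {
    p <- config$between_tract_prob
    migration <- matrix(if (K > 1) p / (K - 1) else 0, K, K)
    diag(migration) <- 1 - p
  }
  evStart <- integer(); evEnd <- integer(); evRecip <- character()
  evDonor <- character()
  for (s in ids) {
    recLin <- match(lineageOf[s], linNames)
    nT <- rpois(1, config$tract_rate)
    for (tr in seq_len(nT)) {
      len <- min(rgeom(1, 1 / config$tract_mean_len) + 1L, G)
      st <- sample.int(G - len + 1L, 1)
      w <- migration[recLin, ]
      if (sum(w) == 0) next
      donLin <- sample.int(K, 1, prob = w)
      pool <- setdiff(members[[donLin]], s)
      if (!length(pool)) next
      donor <- if (length(pool) == 1) pool else sample(pool, 1)
      evStart <- c(evStart, st); evEnd <- c(evEnd, st + len - 1L)
      evRecip <- c(evRecip, s); evDonor <- c(evDonor, donor)
    }
  }
  events <- GRanges(rep("chr1", length(evStart)), IRanges(evStart, evEnd))
  mcols(events)$carriers <- IRanges::CharacterList(unname(
    mapply(function(a, b) sort(c(a, b)), evRecip, evDonor,
           SIMPLIFY = FALSE)))
  mcols(events)$recipient <- evRecip
  mcols(events)$donor <- evDonor
  mcols(events)$recipient_lineage <- unname(lineageOf[evRecip])
  mcols(events)$donor_lineage <- unname(lineageOf[evDonor])
  if (length(events)) {
    aln <- implantRecombination(aln, events, mcols(events)$donor,
                                quiet = TRUE)
    # tract copying can erase the alternate allele everywhere; such columns
    # are no longer SNPs and are not representable as sequence variation
    keep <- colSums(genotypes(aln) == 1L) > 0
    if (!all(keep))
      aln <- SnpAlignment(genotypes(aln)[, keep, drop = FALSE],
                          snpPositions(aln)[keep], refAlleles(aln)[keep],
                          altAlleles(aln)[keep], G, "chr1")
  }

  # ANI from pairwise SNP identity
  dmat <- if (nSites(aln) == 0)
    matrix(0, length(ids), length(ids), dimnames = list(ids, ids)) else
    as.matrix(dist(genotypes(aln), method = "manhattan"))
  ani <- AniMatrix(100 * (1 - dmat / G))

  # clonal-frame tree: star over lineages, coalescent within, branch
  # lengths in substitutions per site
  subNwk <- vapply(seq_len(K), function(l) {
    if (nPer[l] == 1) return(paste0(members[[l]], ":0"))
    tr <- ape::rcoal(nPer[l], tip.label = members[[l]])
    tr$edge.length <- tr$edge.length * config$theta / 2
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  tree <- ape::read.tree(text = if (K == 1) paste0(subNwk, ";") else
    paste0("(", paste0(subNwk, ":", d2, collapse = ","), ");"))

  # metadata: geography, habitat, environment, HGT
  cent <- config$lineage_centroids
  if (is.null(cent))
    cent <- data.frame(lat = seq(-45, 45, length.out = max(K, 2))[seq_len(K)],
                       lon = seq(-150, 150, length.out = max(K, 2))[seq_len(K)])
  li <- match(lineageOf[ids], linNames)
  lat <- cent$lat[li] + rnorm(length(ids), 0, config$scatter_km / 111.32)
  lon <- cent$lon[li] + rnorm(length(ids), 0, config$scatter_km /
                                (111.32 * pmax(cos(cent$lat[li] * pi / 180),
                                               0.2)))
  lat <- pmin(pmax(lat, -90), 90)
  lon <- ((lon + 180) %% 360) - 180
  soilPref <- seq(0.2, 0.8, length.out = max(K, 2))[li]
  habitat <- vapply(soilPref, function(p)
    sample(c("soil", "puddle", "moss"), 1,
           prob = c(p, 0.95 - p, 0.05)), character(1))
  meta <- data.frame(sample_id = ids, lineage = unname(lineageOf[ids]),
                     latitude = lat, longitude = lon, habitat = habitat,
                     stringsAsFactors = FALSE)
  if (config$n_env > 0) {
    btree <- ape::multi2di(tree)
    for (j in seq_len(config$n_env)) {
      tr <- ape::rTraitCont(btree, model = "BM",
                            sigma = config$brownian_sigma)
      meta[[paste0("env_", j)]] <- unname(tr[ids])
    }
  }
  if (config$hgt) {
    meta$genome_size_mb <- pmax(rnorm(length(ids), 7, 0.4), 5)
    rate <- seq(600, 1000, length.out = max(K, 2))[li]
    meta$hgt_count <- rpois(length(ids), rate * meta$genome_size_mb)
  }

  # truth: implanted structure and closed-form neutral expectations
  expected <- NULL
  if (K >= 2) {
    pr <- utils::combn(linNames, 2)
    corr <- config$theta * (1 - 1 / nPer)
    dxyExp <- config$divergence + corr[match(pr[1, ], linNames)] +
      corr[match(pr[2, ], linNames)]
    expected <- data.frame(lineageA = pr[1, ], lineageB = pr[2, ],
                           dxy_expected = dxyExp,
                           fst_expected = 1 - config$theta / dxyExp)
  }
  geneClasses <- setNames(rep("none", config$n_genes),
                          if (config$n_genes) geneTab$gene_id else NULL)
  geneClasses[selectedGenes] <- "positive"
  truth <- list(
    lineages = as.list(lineageOf),
    events = data.frame(start = evStart, end = evEnd, recipient = evRecip,
                        donor = evDonor,
                        recipient_lineage = unname(lineageOf[evRecip]),
                        donor_lineage = unname(lineageOf[evDonor])),
    island = config$island,
    selected_genes = selectedGenes,
    gene_classes = as.list(geneClasses),
    expected = expected,
    tree_newick = ape::write.tree(tree),
    config = unclass(config[setdiff(names(config), "migration")]))

  structure(list(alignment = aln, ref_seq = paste(rootChars, collapse = ""),
                 genes = genes, events = events, metadata = meta,
                 tree = tree, ani = ani, truth = truth),
            class = "continuumBundle")
}

#' Copy donor haplotypes over recombination tracts
#'
#' For each event (in order) every carrier's genotypes over the tract are
#' replaced by the donor's current haplotype, so the returned alignment
#' differs from the input only inside tracts.  Overlapping tracts for the
#' same carrier resolve last-writer-wins (reported via a message).
#'
#' @param x a [SnpAlignment-class].
#' @param events `GRanges` with a `carriers` metadata column.
#' @param donors character vector, one donor sample id per event.
#' @param quiet suppress the overlap message.
#' @return the modified [SnpAlignment-class].
#' @export
implantRecombination <- function(x, events, donors, quiet = FALSE) {
  if (length(events) == 0) return(x)
  if (length(donors) != length(events))
    stop("one donor per event required")
  if (any(end(events) > genomeLength(x)) || any(start(events) < 1))
    stop("event outside genome bounds")
  allCarriers <- unique(c(unlist(mcols(events)$carriers), donors))
  unknown <- setdiff(allCarriers, sampleIds(x))
  if (length(unknown))
    stop("unknown samples in events: ", paste(unknown, collapse = ", "))
  g <- x@genotypes
  pos <- x@positions
  seen <- list()
  nOverlap <- 0L
  for (i in seq_along(events)) {
    cols <- which(pos >= start(events)[i] & pos <= end(events)[i])
    for (s in mcols(events)$carriers[[i]]) {
      prior <- seen[[s]]
      if (!is.null(prior) &&
          any(start(events)[i] <= prior$end & end(events)[i] >= prior$start))
        nOverlap <- nOverlap + 1L
      seen[[s]] <- rbind(prior, data.frame(start = start(events)[i],
                                           end = end(events)[i]))
      if (length(cols))
        g[s, cols] <- g[donors[i], cols]
    }
  }
  if (nOverlap && !quiet)
    message(nOverlap, " overlapping tract application(s): last writer wins")
  SnpAlignment(g, pos, x@refAllele, x@altAllele, x@genomeLength, x@contig,
               x@filterReport)
}

#' Write / read a simulated bundle on disk
#'
#' `writeBundle` emits the whole dataset in standard plain-text formats:
#' `alignment.fasta` (reference first, record `REF`), `snps.vcf`,
#' `genes.gff3`, `recombination.gff`, `tree.nwk`, `metadata.tsv`,
#' `ani.tsv` and `truth.json`, then a `manifest.json` of md5 checksums.
#' The manifest is written last, so a partial write leaves no manifest.
#' `readBundle` reads the files back through the package's own readers.
#'
#' @param bundle a `continuumBundle` from [simulateContinuum()].
#' @param outdir output directory (created if needed).
#' @return `writeBundle`: the manifest data.frame, invisibly.
#' @export
writeBundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outdir, name)
  writeFastaAlignment(bundle$alignment, bundle$ref_seq, f("alignment.fasta"))
  writeSnpVcf(bundle$alignment, f("snps.vcf"))
  writeGeneGff(bundle$genes, f("genes.gff3"))
  writeRecombGff(bundle$events, f("recombination.gff"))
  ape::write.tree(bundle$tree, f("tree.nwk"))
  writeSampleMetadata(bundle$metadata, f("metadata.tsv"))
  writeAniMatrix(bundle$ani, f("ani.tsv"))
  jsonlite::write_json(bundle$truth, f("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c("alignment.fasta", "snps.vcf", "genes.gff3",
             "recombination.gff", "tree.nwk", "metadata.tsv", "ani.tsv",
             "truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname writeBundle
#' @param dir directory written by [writeBundle()].
#' @return `readBundle`: a `continuumBundle` list.
#' @export
readBundle <- function(dir) {
  aln <- readSnpVcf(file.path(dir, "snps.vcf"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "alignment.fasta"))
  refSeq <- as.character(seqs[["REF"]])
  meta <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  structure(list(
    alignment = aln, ref_seq = refSeq,
    genes = readGeneGff(file.path(dir, "genes.gff3")),
    events = readRecombGff(file.path(dir, "recombination.gff"),
                           knownSamples = meta$sample_id),
    metadata = meta,
    tree = readPhyloTree(file.path(dir, "tree.nwk")),
    ani = readAniMatrix(file.path(dir, "ani.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)),
    class = "continuumBundle")
}
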