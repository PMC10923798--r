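# Fixture builders: everything is generated in code at test time.

# SnpAlignment from a list of per-sample genotype vectors
makeAln <- function(geno, positions = NULL, ref = NULL, alt = NULL,
                    genomeLength = NULL) {
  g <- if (is.matrix(geno)) geno else do.call(rbind, geno)
  if (is.null(rownames(g)))
    rownames(g) <- paste0("s", seq_len(nrow(g)))
  np <- ncol(g)
  if (is.null(positions)) positions <- seq_len(np)
  if (is.null(ref)) ref <- rep("A", np)
  if (is.null(alt)) alt <- rep("T", np)
  if (is.null(genomeLength)) genomeLength <- max(positions, 1)
  SnpAlignment(g, positions, ref, alt, genomeLength)
}

# random alignment for property tests (0/1 with optional missingness)
randomAln <- function(nSamples, nSitesMax, genomeLength = 200,
                      pMissing = 0) {
  ns <- sample(0:nSitesMax, 1)
  pos <- sort(sample(genomeLength, ns))
  g <- matrix(sample(0:1, nSamples * ns, replace = TRUE), nSamples, ns)
  if (pMissing > 0)
    g[matrix(runif(length(g)) < pMissing, nSamples, ns)] <- NA
  rownames(g) <- paste0("s", seq_len(nSamples))
  alt <- vapply(seq_len(ns), function(i) sample(c("C", "G", "T"), 1),
                character(1))
  SnpAlignment(g, pos, rep("A", ns), alt, genomeLength)
}

# write a small hand-rolled VCF with a given set of record lines
writeTestVcf <- function(path, records, samples = c("s1", "s2"),
                         contig = "chr1", len = 1000) {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, len),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
  path
}

vcfRecord <- function(pos, ref, alt, gts, contig = "chr1") {
  paste(c(contig, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# events GRanges builder
makeEvents <- function(starts, ends, carriers) {
  gr <- GenomicRanges::GRanges(rep("chr1", length(starts)),
                               IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr)$carriers <- IRanges::CharacterList(carriers)
  gr
}

# genes GRanges builder
makeGenes <- function(starts, ends, strands = "+", ids = NULL) {
  n <- length(starts)
  gr <- GenomicRanges::GRanges(rep("chr1", n), IRanges::IRanges(starts, ends),
                               strand = rep_len(strands, n))
  S4Vectors::mcols(gr)$gene_id <- ids %||%
    sprintf("g%02d", seq_len(n))
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$flagged <- (IRanges::width(gr) %% 3L) != 0L
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
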