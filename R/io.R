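# Readers and writers for every external format the pipeline touches.
# All interval types are 1-based inclusive (GFF/VCF convention); writers emit
# deterministic column order and 6-significant-digit numeric formatting.

.fmtNum <- function(x) formatC(signif(x, 6), format = "fg", flag = "#")

#' Read biallelic SNPs from a VCF
#'
#' Parses a VCF 4.x file with GT fields (haploid or diploid; diploid
#' heterozygotes are treated as missing with a warning).  With
#' `filterBiallelic = TRUE` (default) indels, MNPs and multiallelic records
#' are dropped and counted in the filter report; otherwise any such record is
#' an error.  Multi-contig files are an error unless `contig` names the one
#' to keep.
#'
#' @param path VCF file.
#' @param filterBiallelic drop and count non-biallelic-SNP records.
#' @param contig contig to extract from a multi-contig file.
#' @param genomeLength reference length; defaults to the `##contig` header
#'   length, falling back to the maximum position (with a warning).
#' @return A [SnpAlignment-class] whose `filterReport()` counts every dropped
#'   record (`dropped_indel`, `dropped_mnp`, `dropped_multiallelic`).
#' @export
readSnpVcf <- function(path, filterBiallelic = TRUE, contig = NULL,
                       genomeLength = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames =
                                         list(NULL, names(fix)))
  hdrLen <- NULL
  contigMeta <- grep("^##contig=", vcf@meta, value = TRUE)
  if (nrow(fix) == 0) {
    if (length(contigMeta) == 1) {
      hdrLen <- suppressWarnings(as.integer(
        sub(".*length=([0-9]+).*", "\\1", contigMeta)))
      contig <- sub(".*ID=([^,>]+).*", "\\1", contigMeta)
    }
    gt <- vcf@gt
    samples <- colnames(gt)[-1]
    if (is.null(samples)) samples <- character()
    g <- matrix(integer(), nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
    return(SnpAlignment(g, integer(), character(), character(),
                        genomeLength %||% hdrLen %||% 0L,
                        contig %||% "chr1"))
  }
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1) {
    if (is.null(contig))
      stop("multi-contig VCF; name the contig to extract")
    keep <- fix[, "CHROM"] == contig
  } else {
    contig <- chroms
    keep <- rep(TRUE, nrow(fix))
  }
  if (length(contigMeta)) {
    m <- grep(paste0("ID=", contig, "[,>]"), contigMeta, value = TRUE)
    if (length(m) == 1 && grepl("length=", m))
      hdrLen <- as.integer(sub(".*length=([0-9]+).*", "\\1", m))
  }

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  isMulti <- grepl(",", alt)
  isSnp <- !isMulti & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  isIndel <- !isMulti & !isSnp & nchar(ref) != nchar(alt)
  isMnp <- !isMulti & !isSnp & !isIndel
  report <- list(dropped_indel = sum(isIndel & keep),
                 dropped_mnp = sum(isMnp & keep),
                 dropped_multiallelic = sum(isMulti & keep))
  if (!filterBiallelic && any(unlist(report) > 0))
    stop("non-biallelic-SNP records present and filterBiallelic = FALSE")
  keep <- keep & isSnp
  report$n_kept <- sum(keep)

  pos <- as.integer(fix[keep, "POS"])
  if (anyDuplicated(pos))
    stop("duplicate positions in VCF: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  gtRaw <- vcfR::extract.gt(vcf, element = "GT")
  gtRaw <- gtRaw[keep, , drop = FALSE]
  samples <- colnames(gtRaw)
  parse1 <- function(v) {
    v[v %in% c(".", "./.", ".|.")] <- NA
    first <- sub("[/|].*$", "", v)
    het <- !is.na(v) & grepl("[/|]", v) &
      first != sub("^[^/|]*[/|]", "", v)
    if (any(het)) {
      warning(sum(het), " heterozygous genotype(s) treated as missing")
      first[het] <- NA
    }
    suppressWarnings(as.integer(first))
  }
  g <- apply(gtRaw, 2, parse1)
  if (is.null(dim(g))) g <- matrix(g, ncol = length(samples))
  g <- t(g)
  rownames(g) <- samples
  if (length(g) && any(!is.na(g) & g > 1))
    stop("allele index > 1 in a record marked biallelic")
  o <- order(pos)
  gl <- genomeLength %||% hdrLen
  if (is.null(gl)) {
    gl <- max(pos)
    warning("genome length unknown; using max(position)")
  }
  SnpAlignment(g[, o, drop = FALSE], pos[o], fix[keep, "REF"][o],
               fix[keep, "ALT"][o], gl, contig, report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a SnpAlignment as a minimal VCF 4.2 file
#'
#' Haploid GT fields (`0`, `1` or `.`); the contig header records the genome
#' length so that [readSnpVcf()] round-trips losslessly.
#'
#' @param x a [SnpAlignment-class].
#' @param path output file.
#' @export
writeSnpVcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", x@contig,
                       x@genomeLength),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(x)), collapse = "\t"), con)
  if (nSites(x)) {
    gt <- x@genotypes
    gtChr <- matrix(as.character(gt), nrow = nrow(gt))
    gtChr[is.na(gtChr)] <- "."
    body <- vapply(seq_len(nSites(x)), function(j) {
      paste(c(x@contig, x@positions[j], ".", x@refAllele[j], x@altAllele[j],
              ".", "PASS", ".", "GT", gtChr[, j]), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a whole-genome FASTA alignment as SNPs
#'
#' All records must have equal length.  One record serves as the reference:
#' by default the first record (which then also remains a sample); if
#' `refName` is given, that record is the reference and is excluded from the
#' sample set.  Columns with more than two bases, or containing a gap or
#' ambiguity code, are excluded from the SNP set and counted in the filter
#' report.
#'
#' @param path FASTA file of aligned sequences.
#' @param refName record to use as the reference (excluded from samples);
#'   `NULL` (default) uses the first record and keeps it as a sample.
#' @return A [SnpAlignment-class]; `genomeLength` is the alignment length.
#' @export
readFastaAlignment <- function(path, refName = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file")
  if (length(unique(Biostrings::width(seqs))) != 1)
    stop("ragged alignment: sequences differ in length")
  G <- Biostrings::width(seqs)[1]
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- names(seqs)
  if (is.null(refName)) {
    refRow <- 1L
    sampleRows <- seq_len(nrow(mat))
  } else {
    refRow <- match(refName, rownames(mat))
    if (is.na(refRow)) stop("reference record not found: ", refName)
    sampleRows <- setdiff(seq_len(nrow(mat)), refRow)
  }
  if (!length(sampleRows)) stop("no sample records in alignment")

  refSeq <- mat[refRow, ]
  sub <- mat[sampleRows, , drop = FALSE]
  # candidate columns: any state differing from the reference, or variable
  variable <- which(colSums(sub != rep(refSeq, each = nrow(sub))) > 0)
  acgt <- c("A", "C", "G", "T")
  dropGap <- 0L; dropMulti <- 0L
  pos <- integer(); ref <- character(); alt <- character()
  geno <- list()
  for (j in variable) {
    states <- unique(c(refSeq[j], sub[, j]))
    if (any(!states %in% acgt)) { dropGap <- dropGap + 1L; next }
    if (length(states) > 2) { dropMulti <- dropMulti + 1L; next }
    altBase <- setdiff(states, refSeq[j])
    pos <- c(pos, j); ref <- c(ref, refSeq[j]); alt <- c(alt, altBase)
    geno[[length(geno) + 1L]] <- as.integer(sub[, j] != refSeq[j])
  }
  g <- if (length(geno)) do.call(cbind, geno) else
    matrix(integer(), nrow = nrow(sub), ncol = 0)
  rownames(g) <- rownames(sub)
  SnpAlignment(g, pos, ref, alt, G, "chr1",
               list(dropped_gapped = dropGap,
                    dropped_multiallelic = dropMulti,
                    n_kept = length(pos)))
}

#' Write a SnpAlignment (plus reference sequence) as a FASTA alignment
#'
#' Reconstructs full-length sequences by substituting each sample's alternate
#' alleles into the reference; missing genotypes become `N`.  The reference
#' is written first under `refName`, so
#' `readFastaAlignment(path, refName = refName)` round-trips.
#'
#' @param x a [SnpAlignment-class].
#' @param refSeq reference sequence (single string of length
#'   `genomeLength(x)`).
#' @param path output FASTA.
#' @param refName name for the reference record.
#' @export
writeFastaAlignment <- function(x, refSeq, path, refName = "REF") {
  refChars <- strsplit(toupper(refSeq), "")[[1]]
  if (length(refChars) != x@genomeLength)
    stop("reference sequence length does not match genomeLength")
  if (nSites(x) && any(refChars[x@positions] != x@refAllele))
    stop("reference sequence disagrees with SNP reference alleles")
  out <- c(setNames(paste(refChars, collapse = ""), refName),
           vapply(sampleIds(x), function(s) {
             chars <- refChars
             gv <- x@genotypes[s, ]
             if (nSites(x)) {
               chars[x@positions[which(gv == 1L)]] <-
                 x@altAllele[which(gv == 1L)]
               chars[x@positions[which(is.na(gv))]] <- "N"
             }
             paste(chars, collapse = "")
           }, character(1)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(out), path)
  invisible(path)
}

#' Read recombination events from a Gubbins-style GFF
#'
#' Each record carries the carrier strains in a `taxa="s1 s2 ..."`
#' attribute.  Coordinates are kept 1-based inclusive.  Records without the
#' carrier attribute are an error; a carrier absent from `knownSamples` is an
#' error in strict mode, otherwise a warning (the event is retained).
#' Identical intervals with different carriers remain distinct events: all
#' events, shared and unique, are counted.
#'
#' @param path GFF file.
#' @param knownSamples optional character vector of valid sample ids.
#' @param strict error (rather than warn) on unknown carriers.
#' @return `GRanges` with a `carriers` CharacterList metadata column.
#' @export
readRecombGff <- function(path, knownSamples = NULL, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(GRanges(carriers = IRanges::CharacterList()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad))
    stop("malformed GFF record at line ", bad[1])
  starts <- as.integer(vapply(fields, `[[`, "", 4))
  ends <- as.integer(vapply(fields, `[[`, "", 5))
  if (any(is.na(starts)) || any(is.na(ends)) || any(ends < starts))
    stop("invalid interval coordinates in recombination GFF")
  attrs <- vapply(fields, `[[`, "", 9)
  m <- regmatches(attrs, regexpr('taxa="[^"]*"', attrs))
  hasTaxa <- grepl('taxa="', attrs)
  if (!all(hasTaxa))
    stop("record without taxa attribute at line ", which(!hasTaxa)[1])
  carriers <- lapply(m, function(a)
    strsplit(trimws(sub('^taxa="([^"]*)"$', "\\1", a)), "[[:space:]]+")[[1]])
  if (any(lengths(carriers) == 0))
    stop("record with empty carrier set")
  if (!is.null(knownSamples)) {
    unknown <- setdiff(unique(unlist(carriers)), knownSamples)
    if (length(unknown)) {
      msg <- paste("unknown carrier taxa:", paste(unknown, collapse = ", "))
      if (strict) stop(msg) else warning(msg, " (events retained)")
    }
  }
  gr <- GRanges(vapply(fields, `[[`, "", 1), IRanges(starts, ends))
  mcols(gr)$carriers <- IRanges::CharacterList(carriers)
  gr
}

#' @rdname readRecombGff
#' @param events `GRanges` with a `carriers` metadata column.
#' @export
writeRecombGff <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(events)) {
    rows <- vapply(seq_along(events), function(i) {
      paste(c(as.character(seqnames(events))[i], "contiscan",
              "recombination", start(events)[i], end(events)[i], ".", ".",
              ".", sprintf('taxa="%s";',
                           paste(mcols(events)$carriers[[i]],
                                 collapse = " "))),
            collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read gene models from a GFF3
#'
#' Keeps `CDS` features (falling back to `gene` when no CDS is present),
#' sorted by start.  Genes whose length is not a multiple of 3 are retained
#' but flagged (`flagged = TRUE`); they are skipped by the MK test.
#'
#' @param path GFF3 file.
#' @return `GRanges` sorted by start with metadata columns `gene_id`,
#'   `phase`, `flagged`.
#' @export
readGeneGff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(GRanges(gene_id = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) stop("malformed GFF3 record")
  type <- vapply(fields, `[[`, "", 3)
  use <- if (any(type == "CDS")) type == "CDS" else type == "gene"
  fields <- fields[use]
  starts <- as.integer(vapply(fields, `[[`, "", 4))
  ends <- as.integer(vapply(fields, `[[`, "", 5))
  if (any(ends < starts)) stop("gene with end < start")
  strands <- vapply(fields, `[[`, "", 7)
  phase <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 8)))
  attrs <- vapply(fields, `[[`, "", 9)
  getAttr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  ids <- vapply(attrs, function(a) {
    v <- getAttr(a, "ID")
    if (is.na(v)) v <- getAttr(a, "locus_tag")
    if (is.na(v)) v <- getAttr(a, "gene_id")
    v
  }, character(1), USE.NAMES = FALSE)
  o <- order(starts)
  gr <- GRanges(vapply(fields, `[[`, "", 1)[o],
                IRanges(starts[o], ends[o]), strand = strands[o])
  mcols(gr)$gene_id <- ids[o]
  mcols(gr)$phase <- ifelse(is.na(phase[o]), 0L, phase[o])
  mcols(gr)$flagged <- (width(gr) %% 3L) != 0L
  gr
}

#' @rdname readGeneGff
#' @param genes `GRanges` with `gene_id` (and optionally `phase`) metadata.
#' @export
writeGeneGff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(genes)) {
    ph <- if (!is.null(mcols(genes)$phase)) mcols(genes)$phase else
      rep(0L, length(genes))
    rows <- vapply(seq_along(genes), function(i) {
      paste(c(as.character(seqnames(genes))[i], "contiscan", "CDS",
              start(genes)[i], end(genes)[i], ".",
              as.character(strand(genes))[i], ph[i],
              sprintf("ID=%s;", mcols(genes)$gene_id[i])), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a pairwise ANI matrix
#'
#' Accepts either a long-format TSV (`query`, `target`, `identity`, e.g.
#' fastANI output) or a square matrix with a header row/column of sample
#' ids.  Asymmetric reciprocal values are resolved by their arithmetic mean;
#' self-identity is forced to 100.  Identities outside `[0, 100]` are an
#' error; missing pairs stay `NA`.
#'
#' @param path TSV file.
#' @return An [AniMatrix-class].
#' @export
readAniMatrix <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  isLong <- length(first) == 3 &&
    !is.na(suppressWarnings(as.numeric(first[3])))
  if (isLong) {
    d <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("query", "target", "identity"),
                    stringsAsFactors = FALSE)
  } else {
    m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
    d <- data.frame(query = rep(rownames(m), ncol(m)),
                    target = rep(colnames(m), each = nrow(m)),
                    identity = as.vector(m))
    d <- d[!is.na(d$identity), ]
  }
  if (any(d$identity < 0 | d$identity > 100))
    stop("ANI identity outside [0, 100]")
  ids <- sort(unique(c(d$query, d$target)))
  v <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(d)))
    v[d$query[i], d$target[i]] <- d$identity[i]
  sym <- (v + t(v)) / 2
  oneSided <- is.na(v) & !is.na(t(v))
  sym[oneSided] <- t(v)[oneSided]
  sym[!is.na(v) & is.na(t(v))] <- v[!is.na(v) & is.na(t(v))]
  diag(sym) <- 100
  AniMatrix(sym)
}

#' @rdname readAniMatrix
#' @param ani an [AniMatrix-class].
#' @export
writeAniMatrix <- function(ani, path) {
  v <- aniValues(ani)
  out <- cbind(sample_id = rownames(v),
               as.data.frame(apply(v, 2, .fmtNum)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated with required columns `sample_id`, `lineage`, `latitude`,
#' `longitude`, `habitat`; any column prefixed `env_` is treated as a
#' numeric environmental variable; `hgt_count` and `genome_size_mb` are
#' optional.  Coordinate ranges and non-empty lineages are validated.
#'
#' @param path TSV file.
#' @return data.frame of per-sample metadata.
#' @export
readSampleMetadata <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "lineage", "latitude", "longitude", "habitat")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in metadata")
  if (any(!nzchar(d$lineage))) stop("empty lineage label")
  if (any(abs(d$latitude) > 90) || any(abs(d$longitude) > 180))
    stop("coordinates out of range")
  d
}

#' @rdname readSampleMetadata
#' @param meta data.frame as returned by [readSampleMetadata()].
#' @export
writeSampleMetadata <- function(meta, path) {
  out <- meta
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], .fmtNum)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' Thin wrapper over [ape::read.tree()] validating unique tip labels and
#' non-negative branch lengths.
#'
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
readPhyloTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths")
  tr
}
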