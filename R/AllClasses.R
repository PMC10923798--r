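#' SnpAlignment: a multi-sample biallelic SNP matrix
#'
#' Container for whole-genome SNP variation of haploid samples against a
#' single reference contig.  Genotypes are coded `0L` (reference allele),
#' `1L` (alternate allele) or `NA` (missing); rows are samples, columns are
#' 1-based reference positions in strictly increasing order.
#'
#' @slot genotypes integer matrix (samples x positions) over \{0, 1, NA\}.
#' @slot positions integer vector of 1-based reference coordinates, strictly
#'   increasing; every position is biallelic.
#' @slot refAllele,altAllele single-nucleotide reference / alternate allele
#'   per position.
#' @slot genomeLength reference length in bp (>= max position).
#' @slot contig contig identifier.
#' @slot filterReport named list describing records excluded while reading
#'   (parsers never drop data silently).
#'
#' @exportClass SnpAlignment
setClass("SnpAlignment",
  slots = c(
    genotypes    = "matrix",
    positions    = "integer",
    refAllele    = "character",
    altAllele    = "character",
    genomeLength = "integer",
    contig       = "character",
    filterReport = "list"
  )
)

setValidity("SnpAlignment", function(object) {
  msgs <- character()
  g <- object@genotypes
  p <- object@positions
  if (ncol(g) != length(p))
    msgs <- c(msgs, "ncol(genotypes) must equal length(positions)")
  if (length(p) > 1 && any(diff(p) <= 0))
    msgs <- c(msgs, "positions must be unique and strictly increasing")
  if (length(object@refAllele) != length(p) ||
      length(object@altAllele) != length(p))
    msgs <- c(msgs, "one ref and one alt allele required per position")
  ok <- c("A", "C", "G", "T")
  if (length(p) && (!all(object@refAllele %in% ok) ||
                    !all(object@altAllele %in% ok)))
    msgs <- c(msgs, "alleles must be single nucleotides in A/C/G/T")
  if (length(p) && any(object@refAllele == object@altAllele))
    msgs <- c(msgs, "ref and alt allele must differ (biallelic sites)")
  if (length(p) && object@genomeLength < max(p))
    msgs <- c(msgs, "genomeLength must be >= max(positions)")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msgs <- c(msgs, "genotypes must be 0, 1 or NA")
  if (is.null(rownames(g)))
    msgs <- c(msgs, "genotypes must have sample ids as rownames")
  else if (anyDuplicated(rownames(g)))
    msgs <- c(msgs, "sample ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SnpAlignment
#'
#' @param genotypes integer matrix (samples x positions), values 0/1/NA, with
#'   sample ids as rownames.
#' @param positions 1-based reference positions (strictly increasing).
#' @param refAllele,altAllele per-position alleles (single nucleotides).
#' @param genomeLength reference length in bp.
#' @param contig contig id.
#' @param filterReport optional list of parse/filter counts.
#' @return A [SnpAlignment-class] object.
#' @examples
#' g <- rbind(s1 = c(0L, 1L), s2 = c(1L, 1L))
#' SnpAlignment(g, c(10L, 20L), c("A", "C"), c("G", "T"), 100L)
#' @export
SnpAlignment <- function(genotypes, positions, refAllele, altAllele,
                         genomeLength, contig = "chr1",
                         filterReport = list()) {
  storage.mode(genotypes) <- "integer"
  colnames(genotypes) <- as.character(positions)
  new("SnpAlignment",
      genotypes = genotypes, positions = as.integer(positions),
      refAllele = as.character(refAllele), altAllele = as.character(altAllele),
      genomeLength = as.integer(genomeLength), contig = contig,
      filterReport = filterReport)
}

#' @rdname SnpAlignment-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("refAlleles", function(x) standardGeneric("refAlleles"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("altAlleles", function(x) standardGeneric("altAlleles"))
#' @rdname SnpAlignment-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' Accessors for SnpAlignment objects
#'
#' `sampleIds()`, `snpPositions()`, `genotypes()`, `genomeLength()`,
#' `refAlleles()`, `altAlleles()` and `filterReport()` extract the
#' corresponding slots; `nSamples()` and `nSites()` give the matrix
#' dimensions.
#'
#' @param x a [SnpAlignment-class].
#' @name SnpAlignment-accessors
#' @aliases sampleIds snpPositions genotypes genomeLength refAlleles
#'   altAlleles filterReport
NULL

#' @rdname SnpAlignment-accessors
setMethod("sampleIds", "SnpAlignment", function(x) rownames(x@genotypes))
#' @rdname SnpAlignment-accessors
setMethod("snpPositions", "SnpAlignment", function(x) x@positions)
#' @rdname SnpAlignment-accessors
setMethod("genotypes", "SnpAlignment", function(x) x@genotypes)
#' @rdname SnpAlignment-accessors
setMethod("genomeLength", "SnpAlignment", function(x) x@genomeLength)
#' @rdname SnpAlignment-accessors
setMethod("refAlleles", "SnpAlignment", function(x) x@refAllele)
#' @rdname SnpAlignment-accessors
setMethod("altAlleles", "SnpAlignment", function(x) x@altAllele)
#' @rdname SnpAlignment-accessors
setMethod("filterReport", "SnpAlignment", function(x) x@filterReport)

#' @rdname SnpAlignment-accessors
#' @export
nSamples <- function(x) nrow(x@genotypes)
#' @rdname SnpAlignment-accessors
#' @export
nSites <- function(x) length(x@positions)

setMethod("show", "SnpAlignment", function(object) {
  cat("SnpAlignment:", nSamples(object), "samples x", nSites(object),
      "biallelic SNPs\n")
  cat("  contig:", object@contig, " genome length:", object@genomeLength,
      "bp\n")
  if (length(object@filterReport))
    cat("  filter report:",
        paste(names(object@filterReport), unlist(object@filterReport),
              sep = "=", collapse = ", "), "\n")
})

#' Subset a SnpAlignment by samples or by reference region
#'
#' @param x a [SnpAlignment-class].
#' @param ids sample ids to keep (order preserved as given).
#' @param start,end 1-based inclusive reference interval.
#' @return A [SnpAlignment-class] restricted to the requested samples /
#'   positions.  `subsetRegion` keeps `genomeLength` untouched so per-site
#'   rates remain interpretable.
#' @export
subsetSamples <- function(x, ids) {
  missing <- setdiff(ids, sampleIds(x))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  SnpAlignment(x@genotypes[ids, , drop = FALSE], x@positions,
               x@refAllele, x@altAllele, x@genomeLength, x@contig,
               x@filterReport)
}

#' @rdname subsetSamples
#' @export
subsetRegion <- function(x, start, end) {
  keep <- x@positions >= start & x@positions <= end
  SnpAlignment(x@genotypes[, keep, drop = FALSE], x@positions[keep],
               x@refAllele[keep], x@altAllele[keep], x@genomeLength,
               x@contig, x@filterReport)
}

#' AniMatrix: pairwise average nucleotide identity
#'
#' Symmetric matrix of percent identities in `[0, 100]` with 100 on the
#' diagonal; missing pairs are allowed (`NA`) and are excluded from
#' downstream distance vectors.
#'
#' @slot values numeric matrix with sample ids as dimnames.
#' @exportClass AniMatrix
setClass("AniMatrix", slots = c(values = "matrix"))

setValidity("AniMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "dimnames must carry matching sample ids")
  if (nrow(v)) {
    if (any(abs(v - t(v)) > 1e-9, na.rm = TRUE))
      msgs <- c(msgs, "matrix must be symmetric (tolerance 1e-9)")
    if (any(abs(diag(v) - 100) > 1e-9))
      msgs <- c(msgs, "diagonal must be 100")
    if (any(v < 0 | v > 100, na.rm = TRUE))
      msgs <- c(msgs, "identities must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param values symmetric percent-identity matrix with sample-id dimnames.
#' @return An [AniMatrix-class].
#' @rdname AniMatrix-class
#' @export
AniMatrix <- function(values) new("AniMatrix", values = values)

#' @rdname AniMatrix-class
#' @export
aniValues <- function(x) x@values

setMethod("sampleIds", "AniMatrix", function(x) rownames(x@values))

setMethod("show", "AniMatrix", function(object) {
  v <- object@values
  cat("AniMatrix:", nrow(v), "samples; identity range",
      if (nrow(v) > 1)
        paste(signif(range(v[upper.tri(v)], na.rm = TRUE), 6), collapse = "-")
      else "n/a", "\n")
})

#' GenomeScan: windowed population-genetic statistics
#'
#' Result container for [scanGenome()].  `lineageStats` holds per-window,
#' per-lineage diversity statistics on the diversity window grid;
#' `pairStats` holds per-window F_ST and D_XY per lineage pair;
#' `neutralityStats` holds Tajima's D and Fu's F(S) on the (finer)
#' neutrality window grid.
#'
#' @slot lineageStats data.frame: start, end, lineage, pi, S, theta_w.
#' @slot pairStats data.frame: start, end, lineageA, lineageB, fst, dxy.
#' @slot neutralityStats data.frame: start, end, lineage, tajima_d, fu_f.
#' @slot genomeLength reference length (bp).
#' @slot windowSpecs list with `diversity` and `neutrality` c(size, step).
#' @exportClass GenomeScan
setClass("GenomeScan",
  slots = c(lineageStats = "data.frame", pairStats = "data.frame",
            neutralityStats = "data.frame", genomeLength = "integer",
            windowSpecs = "list"))

#' @rdname GenomeScan-class
#' @param x a GenomeScan.
#' @export
lineageStats <- function(x) x@lineageStats
#' @rdname GenomeScan-class
#' @export
pairStats <- function(x) x@pairStats
#' @rdname GenomeScan-class
#' @export
neutralityStats <- function(x) x@neutralityStats

setMethod("show", "GenomeScan", function(object) {
  nw <- length(unique(object@lineageStats$start))
  nn <- length(unique(object@neutralityStats$start))
  cat("GenomeScan over", object@genomeLength, "bp\n")
  cat("  diversity grid:", nw, "windows of",
      object@windowSpecs$diversity[1], "bp (step",
      object@windowSpecs$diversity[2], ")\n")
  cat("  neutrality grid:", nn, "windows of",
      object@windowSpecs$neutrality[1], "bp (step",
      object@windowSpecs$neutrality[2], ")\n")
  cat("  lineages:", paste(unique(object@lineageStats$lineage),
                           collapse = ", "), "\n")
})
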