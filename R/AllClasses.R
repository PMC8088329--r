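#' Gene panel: an ordered set of gene locus sequences with integer IDs
#'
#' A thin S4 wrapper around a named [Biostrings::DNAStringSet] that fixes
#' the gene-ID convention used throughout the package: genes receive
#' incremental integer IDs 0, 1, ... in input order (the gene-ID map), and
#' all index and classification structures refer to genes by these IDs.
#'
#' @slot sequences A named `DNAStringSet`, one record per gene locus.
#'
#' @seealso [GenePanel()], [readGenePanel()], [buildIndex()]
#' @exportClass GenePanel
setClass("GenePanel", representation(sequences = "DNAStringSet"))

setValidity("GenePanel", function(object) {
  nm <- names(object@sequences)
  if (length(object@sequences) == 0L)
    return("panel must contain at least one gene")
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("every gene must be named")
  if (anyDuplicated(nm))
    return(paste0("duplicate gene names: ",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object@sequences) == 0L))
    return("every gene sequence must be non-empty")
  TRUE
})

#' Construct a gene panel
#'
#' @param x A named `DNAStringSet` or a named character vector of DNA
#'   sequences.  Names are the gene names; input order fixes the integer
#'   gene IDs (0-based, incremental).
#' @return A [GenePanel-class] object.
#' @examples
#' panel <- GenePanel(c(geneA = "ACGTACGTAC", geneB = "TTTTGGGGCC"))
#' geneNames(panel)
#' @export
GenePanel <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  new("GenePanel", sequences = x)
}

#' Succinct k-mer to gene-set index
#'
#' The index couples three structures: a Bloom filter `bloom` of `m` bits
#' storing the canonical k-mers of the panel under a single hash; an
#' integer vector `geneIds` that concatenates, for each set Bloom bit in
#' position order, the sorted list of IDs of the genes containing a k-mer
#' hashing to that bit; and a boundary bit vector `boundary` (same length
#' as `geneIds`) whose 1s mark the end of each per-bit list.  A query
#' locates the segment of `geneIds` for a k-mer via rank on the Bloom
#' filter and select on the boundary vector.  Bloom/hash collisions can
#' only add spurious genes to a query result, never remove true ones.
#'
#' Packed bit vectors use the bit order of [rawToBits()]: bit `p`
#' (0-based) is bit `p %% 8` of byte `p %/% 8`.
#'
#' @slot bloom Packed Bloom filter bits (raw vector of `ceiling(m/8)` bytes).
#' @slot boundary Packed boundary bits, one per entry of `geneIds`.
#' @slot geneIds Integer vector of 0-based gene IDs (the concatenated lists).
#' @slot k Integer k-mer length (1..32).
#' @slot m Numeric number of Bloom filter bits.
#' @slot seed Integer hash seed.
#' @slot geneNames Character vector mapping gene ID (position - 1) to name.
#' @slot onesCount Numeric number of set bits in the Bloom filter.
#'
#' @seealso [buildIndex()], [queryKmer()], [saveIndex()]
#' @exportClass GeneKmerIndex
setClass("GeneKmerIndex",
  representation(bloom = "raw", boundary = "raw", geneIds = "integer",
                 k = "integer", m = "numeric", seed = "integer",
                 geneNames = "character", onesCount = "numeric"))

setValidity("GeneKmerIndex", function(object) {
  nI <- length(object@geneIds)
  if (object@k < 1L || object@k > 32L) return("k must be in [1, 32]")
  if (object@m < 1) return("m must be >= 1")
  if (length(object@bloom) != ceiling(object@m / 8))
    return("bloom byte length inconsistent with m")
  if (length(object@boundary) < ceiling(nI / 8))
    return("boundary byte length inconsistent with geneIds")
  if (nI > 0) {
    if (min(object@geneIds) < 0L ||
        max(object@geneIds) >= length(object@geneNames))
      return("gene IDs out of range")
    # one list terminator per set Bloom bit; final list end is marked
    if (.cpp_popcount(object@boundary, nI) != object@onesCount)
      return("number of 1s in boundary vector != Bloom ones count")
    if (object@onesCount > 0 && !.bitAt(object@boundary, nI))
      return("last boundary bit must be set")
  }
  TRUE
})

# bit p (1-based) of a packed raw vector
.bitAt <- function(raw, p) {
  as.integer(rawToBits(raw[(p - 1) %/% 8 + 1])[(p - 1) %% 8 + 1]) == 1L
}

#' @describeIn GenePanel-class number of genes in the panel
#' @param x,object A `GenePanel`.
#' @export
setMethod("length", "GenePanel", function(x) length(x@sequences))

#' Gene names of a panel or index, in gene-ID order
#'
#' @param x A [GenePanel-class] or [GeneKmerIndex-class].
#' @return Character vector; position `i` is the name of gene ID `i - 1`.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname geneNames
#' @export
setMethod("geneNames", "GenePanel", function(x) names(x@sequences))

#' @rdname geneNames
#' @export
setMethod("geneNames", "GeneKmerIndex", function(x) x@geneNames)

#' Gene sequences of a panel
#' @param x A [GenePanel-class].
#' @return The underlying named `DNAStringSet`.
#' @export
panelSequences <- function(x) {
  stopifnot(is(x, "GenePanel"))
  x@sequences
}

#' Gene-ID map of a panel
#' @param x A [GenePanel-class].
#' @return Named integer vector mapping gene name to its 0-based ID.
#' @export
geneIdMap <- function(x) {
  stopifnot(is(x, "GenePanel"))
  ids <- seq_along(x@sequences) - 1L
  names(ids) <- names(x@sequences)
  ids
}

#' @describeIn GeneKmerIndex-class k-mer length of the index
#' @param x,object A `GeneKmerIndex`.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname GeneKmerIndex-class
#' @export
setMethod("kmerSize", "GeneKmerIndex", function(x) x@k)

#' @describeIn GeneKmerIndex-class Bloom filter size in bits
#' @export
setGeneric("bloomSize", function(x) standardGeneric("bloomSize"))

#' @rdname GeneKmerIndex-class
#' @export
setMethod("bloomSize", "GeneKmerIndex", function(x) x@m)

setMethod("show", "GenePanel", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("GenePanel with", length(object@sequences), "genes",
      sprintf("(widths %d..%d)\n", min(w), max(w)))
  nm <- names(object@sequences)
  shown <- head(nm, 5L)
  cat("  IDs 0..", length(nm) - 1L, ": ", paste(shown, collapse = ", "),
      if (length(nm) > 5L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "GeneKmerIndex", function(object) {
  cat("GeneKmerIndex\n")
  cat(sprintf("  k = %d, m = %s bits, seed = %d\n", object@k,
              format(object@m, big.mark = ","), object@seed))
  cat(sprintf("  genes: %d; set Bloom bits: %s (load %.2e)\n",
              length(object@geneNames),
              format(object@onesCount, big.mark = ","),
              object@onesCount / object@m))
  cat(sprintf("  gene-ID vector length: %d\n", length(object@geneIds)))
})
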