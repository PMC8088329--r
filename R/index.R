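#' Read a gene panel from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA; the record ID up to the
#' first whitespace is the gene name.  Duplicate gene names are a hard
#' error.  Input order fixes the 0-based incremental gene IDs.
#'
#' @param path Path to a FASTA file.
#' @return A [GenePanel-class].
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path)) stop("panel FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty panel FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  GenePanel(seqs)
}

#' Build the succinct k-mer to gene-set index of a panel
#'
#' Three-phase construction.  (1) A first scan of all gene canonical
#' k-mers sets Bloom filter bits under a single hash.  (2) A second scan
#' appends each gene's ID to the list belonging to the rank of its
#' k-mer's set bit; genes are scanned in ID order so duplicates are
#' adjacent and removed on the fly, leaving each list strictly
#' increasing.  (3) The lists are concatenated into the gene-ID vector
#' and the boundary bit vector receives a 1 at each cumulative list end.
#'
#' Genes shorter than `k` contribute no k-mers but keep their ID (a
#' warning is emitted), so the gene-ID map stays stable.
#'
#' @param panel A [GenePanel-class].
#' @param k k-mer length (1..32); default 17.
#' @param m Bloom filter size in bits; default `2^33` (1 GB).  Use a
#'   much smaller `m` for small panels and tests.
#' @param seed Hash seed; defaults to [defaultHashSeed()].
#' @return A [GeneKmerIndex-class].
#' @examples
#' panel <- GenePanel(c(g0 = "ACGTACGGTT", g1 = "TTACCGGTAC"))
#' idx <- buildIndex(panel, k = 5, m = 2^16)
#' queryKmer(idx, "ACGTA")
#' @export
buildIndex <- function(panel, k = 17L, m = 2^33, seed = defaultHashSeed()) {
  stopifnot(is(panel, "GenePanel"))
  k <- as.integer(k)
  if (k < 1L || k > 32L) stop("k must be in [1, 32], got ", k)
  if (m < 1) stop("Bloom size m must be >= 1")
  w <- Biostrings::width(panel@sequences)
  if (any(w < k))
    warning(sum(w < k), " gene(s) shorter than k = ", k,
            " contribute no k-mers: ",
            paste(head(names(panel@sequences)[w < k], 5L), collapse = ", "))
  raw <- .cpp_build_index(as.character(panel@sequences), k, as.numeric(m),
                          as.integer(seed))
  new("GeneKmerIndex", bloom = raw$bloom, boundary = raw$boundary,
      geneIds = raw$geneIds, k = k, m = as.numeric(m),
      seed = as.integer(seed), geneNames = names(panel@sequences),
      onesCount = raw$onesCount)
}

#' Query the index for the gene set of a k-mer
#'
#' If the k-mer's Bloom bit is clear the answer is definitively empty
#' (Bloom negatives are exact).  Otherwise, with `v` the rank ordinal of
#' the set bit, the result is the segment of the gene-ID vector between
#' the `(v-1)`-th and `v`-th set boundary bits (select queries).  The
#' result is always a superset of (or equal to) the exact gene set:
#' hash collisions may add spurious IDs, never remove true ones.
#'
#' @param index A [GeneKmerIndex-class].
#' @param kmers Character vector of k-mers; each must have length
#'   `kmerSize(index)` (anything else is a usage error).
#' @return A named list (one element per k-mer) of strictly increasing
#'   integer vectors of 0-based gene IDs; possibly empty vectors.
#'   Map IDs to names with `geneNames(index)[id + 1]`.
#' @export
queryKmer <- function(index, kmers) {
  stopifnot(is(index, "GeneKmerIndex"))
  out <- .cpp_query(as.character(kmers), index@bloom, index@m, index@seed,
                    index@k, index@boundary, index@geneIds)
  names(out) <- as.character(kmers)
  out
}

#' Exact k-mer dictionary oracle of a panel
#'
#' Builds the exact canonical-k-mer to gene-set dictionary by direct
#' enumeration — the simple, memory-hungry alternative the succinct index
#' replaces.  Intended for small panels (tests and verification): for
#' every indexed k-mer `e`, `queryKmer(index, e)` is a superset of the
#' oracle's set, with equality whenever no two distinct indexed k-mers
#' share a Bloom position.
#'
#' @param panel A [GenePanel-class].
#' @param k k-mer length.
#' @return A named list mapping canonical k-mer string to a sorted
#'   integer vector of 0-based gene IDs.
#' @export
buildExactOracle <- function(panel, k) {
  stopifnot(is(panel, "GenePanel"))
  seqs <- as.character(panel@sequences)
  km <- lapply(seqs, function(s) unique(extractKmers(s, k = k)$kmer))
  ids <- rep(seq_along(seqs) - 1L, lengths(km))
  lapply(split(ids, unlist(km, use.names = FALSE)),
         function(v) sort(unique(v)))
}

#' Rank query on a packed bit vector
#'
#' `bitRank1(bits, nbits, i)` is the number of 1s in the 1-based
#' half-open prefix `B[1, i)` — positions strictly before `i`.  In
#' 0-based terms this counts set bits at positions `0 .. i-2`.
#' Consequently if 1-based position `p` holds a 1, its ordinal among the
#' set bits is `bitRank1(bits, nbits, p) + 1`.
#'
#' @param bits Raw vector of packed bits (bit order of [rawToBits()]) or
#'   a logical vector.
#' @param nbits Number of valid bits in `bits` (required for raw input;
#'   inferred for logical input).
#' @param i 1-based position, `1 <= i <= nbits + 1`.
#' @return Number of set bits before position `i`.
#' @seealso [bitSelect1()]
#' @export
bitRank1 <- function(bits, i, nbits = NULL) {
  b <- .asPackedBits(bits, nbits)
  .cpp_rank1(b$raw, b$nbits, as.numeric(i))
}

#' Select query on a packed bit vector
#'
#' `bitSelect1(bits, nbits, j)` is the 1-based position of the `j`-th set
#' bit; an error if fewer than `j` bits are set.  Round-trip with
#' [bitRank1()]: for any set-bit position `p`,
#' `bitSelect1(bits, bitRank1(bits, p) + 1) == p`.
#'
#' @inheritParams bitRank1
#' @param j Ordinal of the wanted set bit (`>= 1`).
#' @return 1-based position of the `j`-th 1.
#' @export
bitSelect1 <- function(bits, j, nbits = NULL) {
  b <- .asPackedBits(bits, nbits)
  .cpp_select1(b$raw, b$nbits, as.numeric(j))
}

.asPackedBits <- function(bits, nbits) {
  if (is.logical(bits)) {
    list(raw = packBits(c(bits, rep(FALSE, (8 - length(bits) %% 8) %% 8))),
         nbits = length(bits))
  } else if (is.raw(bits)) {
    if (is.null(nbits)) nbits <- 8 * length(bits)
    list(raw = bits, nbits = as.numeric(nbits))
  } else stop("bits must be raw or logical")
}

.INDEX_MAGIC <- "KASSIDX1"
.INDEX_VERSION <- 1L

#' Save an index to a binary container
#'
#' The container is documented and versioned: magic bytes `"KASSIDX1"`,
#' a format version, the parameters (`k`, `m`, `seed`), the gene-name
#' table and the three vectors (Bloom bits, boundary bits, gene IDs),
#' all little-endian.  [loadIndex()] performs a bit-exact round-trip:
#' the loaded index answers every query identically.
#'
#' @param index A [GeneKmerIndex-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "GeneKmerIndex"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.INDEX_MAGIC), con)
  writeBin(.INDEX_VERSION, con, size = 4L, endian = "little")
  writeBin(index@k, con, size = 4L, endian = "little")
  writeBin(index@seed, con, size = 4L, endian = "little")
  writeBin(index@m, con, size = 8L, endian = "little")
  writeBin(index@onesCount, con, size = 8L, endian = "little")
  writeBin(length(index@geneNames), con, size = 4L, endian = "little")
  nmRaw <- lapply(index@geneNames, charToRaw)
  writeBin(as.integer(lengths(nmRaw)), con, size = 4L, endian = "little")
  writeBin(unlist(nmRaw), con)
  writeBin(as.numeric(length(index@geneIds)), con, size = 8L,
           endian = "little")
  writeBin(index@geneIds, con, size = 4L, endian = "little")
  writeBin(as.numeric(length(index@bloom)), con, size = 8L,
           endian = "little")
  writeBin(index@bloom, con)
  writeBin(as.numeric(length(index@boundary)), con, size = 8L,
           endian = "little")
  writeBin(index@boundary, con)
  invisible(path)
}

#' Load an index saved with [saveIndex()]
#'
#' @param path Path to the index container.
#' @return A [GeneKmerIndex-class].  Truncated files, wrong magic bytes
#'   or an unknown format version raise a format error.
#' @export
loadIndex <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readN <- function(what, n, size) {
    out <- readBin(con, what, n = n, size = size, endian = "little")
    if (length(out) != n)
      stop("index format error: truncated file '", path, "'")
    out
  }
  magic <- rawToChar(readN("raw", nchar(.INDEX_MAGIC), 1L))
  if (!identical(magic, .INDEX_MAGIC))
    stop("index format error: bad magic bytes in '", path, "'")
  version <- readN("integer", 1L, 4L)
  if (version != .INDEX_VERSION)
    stop("index format error: unsupported version ", version)
  k <- readN("integer", 1L, 4L)
  seed <- readN("integer", 1L, 4L)
  m <- readN("numeric", 1L, 8L)
  ones <- readN("numeric", 1L, 8L)
  nGenes <- readN("integer", 1L, 4L)
  nmLens <- readN("integer", nGenes, 4L)
  nmBytes <- readN("raw", sum(nmLens), 1L)
  geneNames <- vapply(split(nmBytes, rep(seq_len(nGenes), nmLens)),
                      rawToChar, character(1), USE.NAMES = FALSE)
  nI <- readN("numeric", 1L, 8L)
  geneIds <- readN("integer", nI, 4L)
  nBf <- readN("numeric", 1L, 8L)
  bloom <- readN("raw", nBf, 1L)
  nP <- readN("numeric", 1L, 8L)
  boundary <- readN("raw", nP, 1L)
  new("GeneKmerIndex", bloom = bloom, boundary = boundary,
      geneIds = geneIds, k = k, m = m, seed = seed, geneNames = geneNames,
      onesCount = ones)
}
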