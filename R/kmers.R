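#' Default hash seed
#'
#' The documented default seed of the single k-mer hash.  All index and
#' query code shares this default so that results are reproducible across
#' runs and platforms; it can be overridden everywhere a `seed` argument
#' is accepted (index and queries must then agree).
#'
#' @return Integer scalar.
#' @export
defaultHashSeed <- function() 13L

#' Canonical form of DNA k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement (under A < C < G < T), so that both
#' strands index identically.  Comparison is performed on the 2-bit
#' integer encoding (A=0, C=1, G=2, T=3, leftmost base most significant),
#' which is equivalent to string comparison under that base order.
#' Lowercase input is accepted (soft-masked references are common).
#'
#' @param kmers Character vector of A/C/G/T strings, each of length 1..32.
#' @return Character vector of canonical k-mer strings.
#' @examples
#' canonicalKmer(c("AAAAA", "TTGAC"))  # "AAAAA", "GTCAA"
#' @export
canonicalKmer <- function(kmers) {
  out <- .cpp_canonical(as.character(kmers))
  names(out) <- names(kmers)
  out
}

#' 2-bit integer encoding of the canonical k-mer
#'
#' Returns the canonical k-mer value as a numeric: the unsigned integer
#' with 2 bits per base, leftmost base in the most significant occupied
#' bits.  The value is exact for `k <= 26` (at most 52 bits, within
#' double precision); for larger k the canonical *string* from
#' [canonicalKmer()] is the authoritative representation (internally all
#' computation uses exact 64-bit values).
#'
#' @inheritParams canonicalKmer
#' @return Numeric vector of canonical k-mer values.
#' @export
encodeKmer <- function(kmers) {
  k <- unique(nchar(kmers))
  if (length(k) == 1L && k > 26L)
    warning("numeric k-mer values are approximate for k > 26; ",
            "use canonicalKmer() strings instead")
  out <- .cpp_encode(as.character(kmers))
  names(out) <- names(kmers)
  out
}

#' Hash a k-mer to a Bloom filter position
#'
#' Maps the canonical form of each k-mer to a position in `[0, m)` with a
#' single well-mixed 64-bit hash (the murmur3 finaliser of the 2-bit
#' canonical value xored with a seed multiple), reduced modulo `m`.  The
#' result is deterministic for fixed `(kmer, m, seed)` and identical
#' across platforms and thread counts.
#'
#' @inheritParams canonicalKmer
#' @param m Bloom filter size in bits (`>= 1`).
#' @param seed Integer hash seed; defaults to [defaultHashSeed()].
#' @return Numeric vector of 0-based positions in `[0, m)`.
#' @export
hashKmer <- function(kmers, m, seed = defaultHashSeed()) {
  out <- .cpp_hash(as.character(kmers), as.numeric(m), as.integer(seed))
  names(out) <- names(kmers)
  out
}

#' Extract the admissible canonical k-mers of a read
#'
#' Scans the read left to right and reports one canonical k-mer per
#' admissible window.  A window is dropped when it contains a non-ACGT
#' base (ambiguity codes are all treated like N) or, when `q > 0` and
#' qualities are supplied, any base of quality below `q`.  When `quals`
#' is absent or `q = 0` no quality dropping occurs.
#'
#' @param seq A single DNA string (the read sequence).
#' @param quals Optional per-base qualities: either an integer vector of
#'   Phred scores or a Phred+33 encoded character string, the same length
#'   as `seq`.  A length mismatch is a malformed-record error.
#' @param k k-mer length (1..32).
#' @param q Quality threshold; k-mers spanning any base with quality
#'   `< q` are dropped.  `q = 0` disables the filter.
#' @param readId Optional read identifier stored as an attribute.
#' @return A `data.frame` with columns `start` (0-based window offset,
#'   strictly increasing), `kmer` (canonical string) and `value` (numeric
#'   encoding, see [encodeKmer()]), with attributes `read_id` and
#'   `read_length`.  Empty (zero-row) when `nchar(seq) < k`.
#' @examples
#' extractKmers("ACGTNACGTA", k = 4)$start  # 0, 5, 6: windows over N drop
#' @export
extractKmers <- function(seq, quals = NULL, k, q = 0L, readId = NULL) {
  stopifnot(length(seq) == 1L)
  seq <- as.character(seq)
  if (!is.null(quals)) {
    if (is.character(quals)) {
      stopifnot(length(quals) == 1L)
      quals <- phredFromString(quals)
    }
    quals <- as.integer(quals)
    if (length(quals) != nchar(seq))
      stop("malformed record: quality length (", length(quals),
           ") != sequence length (", nchar(seq), ")")
  }
  res <- .cpp_extract(seq, quals, as.integer(k), as.integer(q))
  out <- data.frame(start = res$start, kmer = res$kmer, value = res$value,
                    stringsAsFactors = FALSE)
  attr(out, "read_id") <- readId
  attr(out, "read_length") <- nchar(seq)
  out
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param x A single quality string (the de-facto FASTQ dialect,
#'   Phred+33).
#' @return Integer vector of Phred scores.
#' @export
phredFromString <- function(x) {
  as.integer(charToRaw(as.character(x))) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q Integer vector of Phred scores.
#' @return A single character string.
#' @export
phredToString <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}
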