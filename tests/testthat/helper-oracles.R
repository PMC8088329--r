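# Independent brute-force oracles used across the suite.  These work on
# plain character strings with base R only, so they share no code path
# with the package internals they check.

oracleRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# lexicographically smaller of a k-mer and its reverse complement
oracleCanonical <- function(s) {
  rc <- oracleRevcomp(s)
  if (s <= rc) s else rc
}

# all k-length windows of a string as a character vector
oracleWindows <- function(s, k) {
  n <- nchar(s)
  if (k > n) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# admissible window starts (0-based) of a read under ambiguity + quality
# masking, by explicitly checking every window against the base mask
oracleAdmissibleStarts <- function(s, k, quals = NULL, q = 0) {
  n <- nchar(s)
  if (k > n) return(integer(0))
  bases <- strsplit(s, "")[[1]]
  bad <- !(toupper(bases) %in% c("A", "C", "G", "T"))
  if (!is.null(quals) && q > 0) bad <- bad | (quals < q)
  starts <- integer(0)
  for (i in 0:(n - k)) {
    if (!any(bad[(i + 1):(i + k)])) starts <- c(starts, i)
  }
  starts
}

# exact canonical k-mer set of a gene sequence
oracleGeneKmers <- function(g, k) {
  unique(vapply(oracleWindows(g, k), oracleCanonical, character(1),
                USE.NAMES = FALSE))
}

# |SHARED(read, gene)| by explicit union of the base positions covered by
# read windows whose canonical k-mer occurs in the gene
oracleSharedBases <- function(readSeq, geneSeq, k, quals = NULL, q = 0) {
  gk <- oracleGeneKmers(geneSeq, k)
  starts <- oracleAdmissibleStarts(readSeq, k, quals, q)
  covered <- logical(nchar(readSeq))
  for (i in starts) {
    w <- substr(readSeq, i + 1, i + k)
    if (oracleCanonical(w) %in% gk) covered[(i + 1):(i + k)] <- TRUE
  }
  sum(covered)
}

# Shared-base counts of a read against every gene, by brute-force union
# of covered positions, but through the *effective* k-mer -> gene-set map
# of a single-hash Bloom index: a window's gene set is the union of the
# exact sets of all indexed k-mers hashing to the same position (hash
# collisions merge sets; a clear position is empty).  This reproduces,
# independently of the rank/select/accumulator machinery, exactly what a
# collision-bearing index must answer.
oracleSharedAllGenes <- function(readSeq, k, oracle, m, seed = NULL,
                                 quals = NULL, q = 0) {
  posIndexed <- if (is.null(seed)) hashKmer(names(oracle), m) else
    hashKmer(names(oracle), m, seed = seed)
  starts <- oracleAdmissibleStarts(readSeq, k, quals, q)
  geneIds <- sort(unique(unlist(oracle)))
  covered <- matrix(FALSE, nrow = nchar(readSeq), ncol = length(geneIds))
  colnames(covered) <- as.character(geneIds)
  for (i in starts) {
    e <- oracleCanonical(substr(readSeq, i + 1, i + k))
    h <- if (is.null(seed)) hashKmer(e, m) else hashKmer(e, m, seed = seed)
    hit <- unique(unlist(oracle[posIndexed == h]))
    for (g in hit) covered[(i + 1):(i + k), as.character(g)] <- TRUE
  }
  counts <- colSums(covered)
  counts[counts > 0]
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomPanel <- function(nGenes, lenRange = c(200L, 2000L)) {
  lens <- sample(lenRange[1]:lenRange[2], nGenes, replace = TRUE)
  seqs <- vapply(lens, randomDNA, character(1))
  names(seqs) <- sprintf("g%02d", seq_len(nGenes) - 1L)
  GenePanel(seqs)
}

# small deterministic scenario reused by classification / io tests
smallScenario <- function(seed = 7L, nReads = 2000L) {
  simulateScenario(simConfig(nGenes = 12L, panelSize = 4L, nReads = nReads,
                             seed = seed))
}
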