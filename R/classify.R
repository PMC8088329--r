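#' Shared-base counts of one read against every candidate gene
#'
#' Scans the admissible k-mers of the read left to right and accumulates,
#' for every gene returned by the index query at each window, the number
#' of read bases covered by at least one matching window — the
#' shared-base count.  Per gene the scan keeps `pos_g`, the exclusive end
#' of the last covering window (sentinel -1), and adds
#' `min(k, i + k - pos_g)` new bases at a hit starting at 0-based `i`,
#' then sets `pos_g` to `i + k`.  After the scan the count equals the
#' cardinality of the union of covered base positions.
#'
#' @param seq A single read sequence (character).
#' @param index A [GeneKmerIndex-class].
#' @param quals Optional qualities (Phred+33 string or integer vector).
#' @param q Quality threshold; windows spanning a base of quality `< q`
#'   are skipped (see [extractKmers()]).
#' @return Named integer vector of shared-base counts (names are gene
#'   names, in gene-ID order of first hit sorted by ID); genes never hit
#'   are absent.
#' @export
sharedCounts <- function(seq, index, quals = NULL, q = 0L) {
  stopifnot(is(index, "GeneKmerIndex"), length(seq) == 1L)
  qstr <- if (is.null(quals)) "" else if (is.character(quals)) quals else
    phredToString(quals)
  res <- .cpp_classify(as.character(seq), qstr, index@bloom, index@m,
                       index@seed, index@k, index@boundary, index@geneIds,
                       length(index@geneNames), as.integer(q))
  ord <- order(res$gene)
  out <- res$card[ord]
  names(out) <- index@geneNames[res$gene[ord] + 1L]
  out
}

#' Assign a read from its shared-base counts
#'
#' A gene is a putative origin of the read iff its shared-base count is
#' maximal among all genes and the covered fraction of the read reaches
#' the confidence threshold: `card / readLength >= tau`.  In multiple
#' mode all qualifying genes are reported; in single mode a read with
#' more than one qualifying gene gets no assignment at all (ambiguous
#' assignments are discarded).
#'
#' @param cards Named numeric/integer vector of shared-base counts (as
#'   from [sharedCounts()]); may be empty.
#' @param readLength Read length in bases (the denominator of the
#'   confidence ratio is always the full read length, even when quality
#'   masking removed windows).
#' @param tau Confidence threshold in (0, 1]; default 0.6.
#' @param mode `"multiple"` (default) or `"single"`.
#' @return Named integer vector of the assigned genes' shared-base
#'   counts (empty when no gene qualifies).
#' @examples
#' assignRead(c(A = 60, B = 60), 100)                     # tie: both
#' assignRead(c(A = 60, B = 60), 100, mode = "single")    # tie: none
#' assignRead(c(A = 70, B = 50), 100)                     # strict max: A
#' @export
assignRead <- function(cards, readLength, tau = 0.6,
                       mode = c("multiple", "single")) {
  mode <- match.arg(mode)
  stopifnot(tau > 0, tau <= 1, readLength >= 1)
  if (length(cards) == 0L) return(integer(0))
  cstar <- max(cards)
  if (cstar / readLength < tau) return(integer(0))
  cand <- cards[cards == cstar]
  if (mode == "single" && length(cand) > 1L) return(integer(0))
  storage.mode(cand) <- "integer"
  cand
}

# FASTQ writer shared by the filtering and simulation outputs; silences
# the harmless Biostrings notice about dropped metadata columns when a
# QualityScaledDNAStringSet is written.
.writeFastq <- function(x, path, qualities = NULL) {
  if (is.null(qualities)) qualities <- Biostrings::quality(x)
  withCallingHandlers(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = qualities),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

# Quiet counterpart of .writeFastq for reading (same Biostrings notice).
.readFastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Load reads from a path / DNAStringSet / QualityScaledDNAStringSet into
# list(ids, seqs, quals ("" when absent), widths).
.loadReads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L) {
    if (!file.exists(reads)) stop("reads file not found: ", reads)
    reads <- tryCatch(
      .readFastq(reads),
      error = function(e) stop("malformed FASTQ '", reads, "': ",
                               conditionMessage(e)))
  }
  if (is(reads, "QualityScaledDNAStringSet")) {
    list(ids = sub("\\s.*$", "", names(reads)),
         seqs = as.character(reads),
         quals = as.character(Biostrings::quality(reads)),
         widths = Biostrings::width(reads))
  } else if (is(reads, "DNAStringSet")) {
    list(ids = sub("\\s.*$", "", names(reads)),
         seqs = as.character(reads),
         quals = rep("", length(reads)),
         widths = Biostrings::width(reads))
  } else stop("unsupported reads input of class ", class(reads)[1])
}

# Turn (read, gene, card) triples into the assignment table by the
# max-card + threshold criterion; vectorised over reads.
.applyAssignment <- function(tri, widths, ids, geneNames, tau, mode) {
  empty <- data.frame(read_id = character(0), gene_name = character(0),
                      shared_bases = integer(0), read_length = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE)
  if (length(tri$read) == 0L) return(empty)
  L <- widths[tri$read]
  maxc <- stats::ave(tri$card, tri$read, FUN = max)
  keep <- tri$card == maxc & (tri$card / L) >= tau
  if (mode == "single") {
    ncand <- stats::ave(as.integer(keep), tri$read, FUN = sum)
    keep <- keep & ncand == 1L
  }
  if (!any(keep)) return(empty)
  out <- data.frame(read_id = ids[tri$read[keep]],
                    gene_name = geneNames[tri$gene[keep] + 1L],
                    shared_bases = tri$card[keep],
                    read_length = L[keep],
                    ratio = tri$card[keep] / L[keep],
                    stringsAsFactors = FALSE)
  out[order(out$read_id, out$gene_name), , drop = FALSE]
}

#' Classify an RNA-seq sample against an indexed gene panel
#'
#' Computes, for every read, the shared-base count against each candidate
#' gene (see [sharedCounts()]) and applies the assignment criterion of
#' [assignRead()].  Output is deterministic and independent of the
#' `threads` batching: rows are sorted by `(read_id, gene_name)`.
#'
#' For paired-end input, `pairingPolicy = "separate"` classifies the two
#' mates as independent single-end reads (mate IDs are suffixed `/1`,
#' `/2` when the files use identical names); `"union"` (default) reports
#' one row per (pair, gene) for every gene either mate is assigned to,
#' with the larger mate shared-base count, and filtering utilities then
#' retain both mates of a retained pair.
#'
#' @param reads FASTQ path (optionally gzipped), `DNAStringSet` or
#'   `QualityScaledDNAStringSet`.
#' @param index A [GeneKmerIndex-class].
#' @param mates Optional second FASTQ (mate 2) for paired-end input.
#' @param tau Confidence threshold, default 0.6.
#' @param q Base-quality threshold, default 10 (`0` disables; ignored
#'   when the input carries no qualities).
#' @param mode `"multiple"` (default) or `"single"`.
#' @param pairingPolicy `"union"` (default) or `"separate"`.
#' @param threads Number of batches reads are processed in; results are
#'   identical for any value (kept for interface compatibility).
#' @return A `data.frame` with columns `read_id`, `gene_name`,
#'   `shared_bases`, `read_length`, `ratio` — one row per (read, gene)
#'   association.  A read may appear in several rows (multiple mode) or
#'   none: a gene assignment is not necessarily a partition of the
#'   sample.  The number of processed reads is attached as attribute
#'   `n_reads`.
#' @export
classifySample <- function(reads, index, mates = NULL, tau = 0.6, q = 10L,
                           mode = c("multiple", "single"),
                           pairingPolicy = c("union", "separate"),
                           threads = 1L) {
  mode <- match.arg(mode)
  pairingPolicy <- match.arg(pairingPolicy)
  stopifnot(is(index, "GeneKmerIndex"), tau > 0, tau <= 1)

  if (!is.null(mates)) {
    a1 <- classifySample(reads, index, tau = tau, q = q, mode = mode,
                         threads = threads)
    a2 <- classifySample(mates, index, tau = tau, q = q, mode = mode,
                         threads = threads)
    return(.combineMates(a1, a2, pairingPolicy))
  }

  rd <- .loadReads(reads)
  n <- length(rd$ids)
  nb <- max(1L, min(as.integer(threads), n))
  batches <- if (n == 0L) list() else
    split(seq_len(n), ceiling(seq_len(n) / ceiling(n / nb)))
  tris <- lapply(batches, function(ix) {
    res <- .cpp_classify(rd$seqs[ix], rd$quals[ix], index@bloom, index@m,
                         index@seed, index@k, index@boundary, index@geneIds,
                         length(index@geneNames), as.integer(q))
    res$read <- ix[res$read]  # map batch-local to global read index
    res
  })
  tri <- list(read = unlist(lapply(tris, `[[`, "read"), use.names = FALSE),
              gene = unlist(lapply(tris, `[[`, "gene"), use.names = FALSE),
              card = unlist(lapply(tris, `[[`, "card"), use.names = FALSE))
  out <- .applyAssignment(tri, rd$widths, rd$ids, index@geneNames, tau, mode)
  attr(out, "n_reads") <- n
  out
}

.combineMates <- function(a1, a2, pairingPolicy) {
  n1 <- attr(a1, "n_reads"); n2 <- attr(a2, "n_reads")
  if (pairingPolicy == "separate") {
    clash <- intersect(a1$read_id, a2$read_id)
    if (length(clash) > 0L) {
      a1$read_id <- paste0(a1$read_id, "/1")
      a2$read_id <- paste0(a2$read_id, "/2")
    }
    out <- rbind(a1, a2)
  } else {
    # union: key pairs by mate-1 ID stripped of a /1 /2 suffix
    strip <- function(x) sub("/[12]$", "", x)
    a1$read_id <- strip(a1$read_id); a2$read_id <- strip(a2$read_id)
    both <- rbind(a1, a2)
    if (nrow(both) > 0L) {
      key <- paste(both$read_id, both$gene_name, sep = "\r")
      best <- tapply(seq_len(nrow(both)),
                     factor(key, levels = unique(key)),
                     function(ix) ix[which.max(both$shared_bases[ix])])
      out <- both[as.integer(best), , drop = FALSE]
    } else out <- both
  }
  out <- out[order(out$read_id, out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_reads") <- n1 + n2
  out
}

#' Write an assignment table as TSV
#'
#' @param assignments Output of [classifySample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an assignment TSV written by [writeAssignments()]
#' @param path Path to the TSV.
#' @return The assignment `data.frame`.
#' @export
readAssignments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character", gene_name = "character"))
}

#' Write the filtered FASTQ of assigned reads
#'
#' Writes exactly the reads with at least one assignment.  For paired
#' input give both mate sets; with the `"union"` pairing policy used by
#' [classifySample()], a pair key occurring in the assignment table
#' retains both mates.
#'
#' @param reads FASTQ path or `QualityScaledDNAStringSet` (mate 1 for
#'   paired input).
#' @param assignments Assignment table from [classifySample()].
#' @param path Output FASTQ path (mate 1).
#' @param mates,matesPath Optional mate-2 input and output paths.
#' @return `path`, invisibly.
#' @export
writeFilteredFastq <- function(reads, assignments, path, mates = NULL,
                               matesPath = NULL) {
  keepIds <- unique(assignments$read_id)
  writeOne <- function(input, outPath) {
    x <- if (is.character(input)) .readFastq(input) else input
    ids <- sub("\\s.*$", "", names(x))
    sel <- ids %in% keepIds | sub("/[12]$", "", ids) %in% keepIds
    .writeFastq(x[sel], outPath)
  }
  writeOne(reads, path)
  if (!is.null(mates)) {
    if (is.null(matesPath)) stop("matesPath required with mates")
    writeOne(mates, matesPath)
  }
  invisible(path)
}

#' Write one FASTQ per gene with the reads assigned to it
#'
#' @param reads FASTQ path or `QualityScaledDNAStringSet`.
#' @param assignments Assignment table from [classifySample()].
#' @param dir Output directory (created if needed); files are named
#'   `<gene>.fastq`.
#' @return Named character vector of written paths, invisibly.
#' @export
writePerGeneFastq <- function(reads, assignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- if (is.character(reads)) .readFastq(reads) else reads
  ids <- sub("\\s.*$", "", names(x))
  paths <- character(0)
  for (g in unique(assignments$gene_name)) {
    keep <- ids %in% assignments$read_id[assignments$gene_name == g]
    p <- file.path(dir, paste0(g, ".fastq"))
    .writeFastq(x[keep], p)
    paths[g] <- p
  }
  invisible(paths)
}
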