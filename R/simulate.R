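#' Configuration of the synthetic gene / read simulator
#'
#' Defaults are the package's reference desk-scale study conditions: 50
#' gene loci of roughly 2 kb built from 2-5 exons, a 10-gene panel,
#' 50,000 single-end 100 bp reads with 0.2% per-base substitution error
#' and Phred-style qualities (mean 35, sd 3) carrying occasional
#' low-quality bases (1% of bases, Phred 2-9).
#'
#' @param nGenes Total number of gene loci simulated.
#' @param panelSize Number of genes in the panel of interest
#'   (`<= nGenes`).
#' @param exonsPerGene Length-2 integer range of exons per gene.
#' @param exonLength,intronLength Length-2 ranges (bases) from which
#'   exon/intron lengths are drawn uniformly.  Locus length emerges from
#'   the exon/intron structure (about 2 kb under the defaults).
#' @param nReads Number of simulated reads.
#' @param readLength Read length in bases.
#' @param errorRate Per-base substitution error probability.
#' @param meanQuality,sdQuality Normal model of per-base Phred scores
#'   (clamped to 2..40).
#' @param lowQualityRate Fraction of bases replaced by a low-quality
#'   score drawn uniformly from `lowQualityRange`.
#' @param lowQualityRange Length-2 Phred range of low-quality bases.
#' @param expressionWeights Optional per-transcript sampling weights
#'   (recycled/normalised); uniform when `NULL`.
#' @param plantShared Optional `list(genes = c(i, j), length = L)`
#'   copying an `L`-base segment of gene `i`'s first exon into gene
#'   `j`'s first exon, to emulate paralogous sharing.
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   under a fixed seed.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 50L, panelSize = 10L,
                      exonsPerGene = c(2L, 5L),
                      exonLength = c(250L, 600L),
                      intronLength = c(100L, 300L),
                      nReads = 50000L, readLength = 100L,
                      errorRate = 0.002, meanQuality = 35, sdQuality = 3,
                      lowQualityRate = 0.01, lowQualityRange = c(2L, 9L),
                      expressionWeights = NULL, plantShared = NULL,
                      seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), panelSize = as.integer(panelSize),
              exonsPerGene = as.integer(exonsPerGene),
              exonLength = as.integer(exonLength),
              intronLength = as.integer(intronLength),
              nReads = as.integer(nReads), readLength = as.integer(readLength),
              errorRate = errorRate, meanQuality = meanQuality,
              sdQuality = sdQuality, lowQualityRate = lowQualityRate,
              lowQualityRange = as.integer(lowQualityRange),
              expressionWeights = expressionWeights,
              plantShared = plantShared, seed = as.integer(seed))
  if (cfg$panelSize > cfg$nGenes)
    stop("config error: panelSize > nGenes")
  probs <- c(cfg$errorRate, cfg$lowQualityRate)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must be in [0, 1]")
  if (cfg$exonsPerGene[1] < 1L || diff(cfg$exonsPerGene) < 0L)
    stop("config error: bad exonsPerGene range")
  minTranscript <- cfg$exonsPerGene[1] * cfg$exonLength[1]
  if (cfg$readLength > minTranscript)
    stop("config error: readLength exceeds the minimum transcript length (",
         minTranscript, ")")
  class(cfg) <- "simConfig"
  cfg
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate gene loci, transcripts and a gene panel
#'
#' Gene loci are i.i.d. random DNA assembled as exon1 intron1 exon2 ...;
#' each gene's transcript is the concatenation of its exons (introns
#' spliced out).  A random subset of `panelSize` genes forms the panel
#' of interest; reads are later simulated from *all* genes, so some
#' reads originate outside the panel.  Deterministic under the config
#' seed (identical FASTA bytes across calls).
#'
#' @param config A [simConfig()].
#' @return A list with elements `genes` (named `DNAStringSet` of all
#'   loci), `transcripts` (named `DNAStringSet`), `exons` (`data.frame`
#'   gene/exon/start/end, 1-based locus coordinates), `junctions` (list
#'   of 0-based transcript cut points per gene), `panelNames`, `panel`
#'   (a [GenePanel-class] of the chosen genes) and `config`.
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  withr::with_seed(config$seed, {
    nms <- sprintf("gene%03d", seq_len(config$nGenes))
    exonSeqs <- vector("list", config$nGenes)
    loci <- character(config$nGenes)
    exonTab <- list()
    for (i in seq_len(config$nGenes)) {
      nEx <- sample(config$exonsPerGene[1]:config$exonsPerGene[2], 1L)
      exLen <- sample(config$exonLength[1]:config$exonLength[2], nEx,
                      replace = TRUE)
      inLen <- if (nEx > 1L)
        sample(config$intronLength[1]:config$intronLength[2], nEx - 1L,
               replace = TRUE) else integer(0)
      ex <- vapply(exLen, .randomDNA, character(1))
      intr <- vapply(inLen, .randomDNA, character(1))
      pieces <- character(2L * nEx - 1L)
      pieces[seq(1L, by = 2L, length.out = nEx)] <- ex
      if (nEx > 1L) pieces[seq(2L, by = 2L, length.out = nEx - 1L)] <- intr
      loci[i] <- paste(pieces, collapse = "")
      exonSeqs[[i]] <- ex
      starts <- cumsum(c(1L, head(exLen + c(inLen, 0L), -1L)))
      exonTab[[i]] <- data.frame(gene = nms[i], exon = seq_len(nEx),
                                 start = starts, end = starts + exLen - 1L,
                                 stringsAsFactors = FALSE)
    }
    if (!is.null(config$plantShared)) {
      ps <- config$plantShared
      src <- exonSeqs[[ps$genes[1]]][1]
      if (nchar(src) < ps$length ||
          nchar(exonSeqs[[ps$genes[2]]][1]) < ps$length)
        stop("config error: planted segment longer than first exon")
      seg <- substr(src, 1L, ps$length)
      dst <- exonSeqs[[ps$genes[2]]][1]
      exonSeqs[[ps$genes[2]]][1] <-
        paste0(seg, substr(dst, ps$length + 1L, nchar(dst)))
      # rebuild the destination locus with the planted exon
      j <- ps$genes[2]
      tab <- exonTab[[j]]
      locus <- loci[j]
      substr(locus, tab$start[1], tab$end[1]) <-
        substr(exonSeqs[[j]][1], 1L, tab$end[1] - tab$start[1] + 1L)
      loci[j] <- locus
    }
    transcripts <- vapply(exonSeqs, paste, character(1), collapse = "")
    genes <- Biostrings::DNAStringSet(loci)
    names(genes) <- nms
    tx <- Biostrings::DNAStringSet(transcripts)
    names(tx) <- nms
    junctions <- lapply(exonSeqs, function(e)
      if (length(e) > 1L) cumsum(nchar(e))[-length(e)] else integer(0))
    names(junctions) <- nms
    panelNames <- sort(sample(nms, config$panelSize))
    list(genes = genes, transcripts = tx,
         exons = do.call(rbind, exonTab), junctions = junctions,
         panelNames = panelNames,
         panel = GenePanel(genes[panelNames]), config = config)
  })
}

#' Simulate an RNA-seq sample from simulated transcripts
#'
#' Reads are drawn from transcripts (uniformly or by expression
#' weights), at uniform start positions and random strand, with i.i.d.
#' per-base substitution errors at the configured rate and Phred-style
#' quality strings from the quality model.  Read names encode nothing
#' about the truth; the per-read origin gene is returned separately.
#' Deterministic under the config seed (a stream distinct from
#' [simulatePanel()]'s is used so the two stages are independently
#' reproducible).
#'
#' @param sim Output of [simulatePanel()].
#' @param config A [simConfig()]; defaults to `sim$config`.
#' @return A list with `reads` (a `QualityScaledDNAStringSet`) and
#'   `truth` (`data.frame` with `read_id`, `origin_gene`, plus
#'   provenance columns `transcript`, `start` (0-based), `strand`,
#'   `n_errors`, `n_junctions` — the junction count lets recall be
#'   stratified by junction-spanning reads).
#' @export
simulateReads <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "simConfig"))
  txChar <- as.character(sim$transcripts)
  txLen <- nchar(txChar)
  L <- config$readLength
  if (any(txLen < L))
    stop("config error: readLength exceeds a transcript length")
  n <- config$nReads
  w <- config$expressionWeights
  if (!is.null(w)) w <- rep_len(w, length(txChar))
  withr::with_seed(config$seed + 1L, {
    tIdx <- sample.int(length(txChar), n, replace = TRUE, prob = w)
    start0 <- floor(runif(n) * (txLen[tIdx] - L + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(txChar[tIdx], start0 + 1, start0 + L)

    # substitution errors: per-read Binomial(L, errorRate) count, then
    # positions within the read; only reads with errors are touched
    nErr <- rbinom(n, L, config$errorRate)
    errReads <- which(nErr > 0L)
    for (i in errReads) {
      pos <- sample.int(L, nErr[i])
      s <- seqs[i]
      for (p in pos) {
        orig <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      }
      seqs[i] <- s
    }
    minus <- strand == "-"
    if (any(minus)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
      seqs[minus] <- rc
    }

    # quality model: clamped normal scores with occasional low-quality
    # bases; one big Phred+33 string cut into per-read strings
    qint <- as.integer(pmin(40, pmax(2, round(rnorm(n * L,
      config$meanQuality, config$sdQuality)))))
    low <- runif(n * L) < config$lowQualityRate
    if (any(low))
      qint[low] <- sample(config$lowQualityRange[1]:config$lowQualityRange[2],
                          sum(low), replace = TRUE)
    bigQ <- rawToChar(as.raw(qint + 33L))
    quals <- substring(bigQ, seq(1L, by = L, length.out = n),
                       seq(L, by = L, length.out = n))

    ids <- sprintf("read%07d", seq_len(n))
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(reads) <- ids
    cuts <- sim$junctions[names(txChar)[tIdx]]
    nJunc <- mapply(function(cu, s) sum(cu > s & cu < s + L), cuts, start0)
    truth <- data.frame(read_id = ids,
                        origin_gene = names(txChar)[tIdx],
                        transcript = names(txChar)[tIdx],
                        start = start0, strand = strand,
                        n_errors = nErr, n_junctions = as.integer(nJunc),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Run the full simulation scenario
#'
#' Convenience wrapper: [simulatePanel()] then [simulateReads()].
#'
#' @param config A [simConfig()].
#' @return The [simulatePanel()] list with `reads` and `truth` added.
#' @export
simulateScenario <- function(config = simConfig()) {
  sim <- simulatePanel(config)
  rd <- simulateReads(sim, config)
  c(sim, rd)
}

#' Write a simulation bundle to disk
#'
#' Writes `panel.fasta` (panel genes), `genes.fasta` (all loci),
#' `reads.fastq`, `truth.tsv` (`read_id`, `origin_gene`) and a
#' `config.yaml` echo of the simulation parameters.
#'
#' @param scenario Output of [simulateScenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.fasta"),
             genes = file.path(dir, "genes.fasta"),
             reads = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  Biostrings::writeXStringSet(panelSequences(scenario$panel), paths["panel"])
  Biostrings::writeXStringSet(scenario$genes, paths["genes"])
  .writeFastq(scenario$reads, paths["reads"])
  write.table(scenario$truth[, c("read_id", "origin_gene")], paths["truth"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- scenario$config
  class(cfg) <- NULL
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
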