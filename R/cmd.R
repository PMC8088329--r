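#' Run configuration with the recommended operating point
#'
#' Collects the tool parameters with defaults at the recommended
#' operating point: `k = 17`, `tau = 0.6`, `q = 10`, a 1 GB Bloom
#' filter (`2^33` bits), multiple mode.
#'
#' @param k k-mer length.
#' @param tau Confidence threshold.
#' @param q Base-quality threshold.
#' @param bloomBits Bloom filter size in bits.
#' @param mode `"multiple"` or `"single"`.
#' @param threads Batch count (output is identical for any value).
#' @param seed Hash seed.
#' @param pairingPolicy `"union"` or `"separate"` for paired input.
#' @param strict Abort on malformed records instead of skipping.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(k = 17L, tau = 0.6, q = 10L, bloomBits = 2^33,
                      mode = c("multiple", "single"), threads = 1L,
                      seed = defaultHashSeed(),
                      pairingPolicy = c("union", "separate"),
                      strict = FALSE) {
  structure(list(k = as.integer(k), tau = tau, q = as.integer(q),
                 bloomBits = bloomBits, mode = match.arg(mode),
                 threads = as.integer(threads), seed = as.integer(seed),
                 pairingPolicy = match.arg(pairingPolicy), strict = strict),
            class = "runConfig")
}

#' Build and save a panel index (command entry point)
#'
#' @param reference Panel FASTA path.
#' @param output Output index path.
#' @param config A [runConfig()].
#' @return The built [GeneKmerIndex-class], invisibly.
#' @export
cmdIndex <- function(reference, output, config = runConfig()) {
  panel <- readGenePanel(reference)
  idx <- buildIndex(panel, k = config$k, m = config$bloomBits,
                    seed = config$seed)
  message(sprintf("indexed %d genes: %s set Bloom bits, load factor %.3e",
                  length(panel), format(idx@onesCount, big.mark = ","),
                  idx@onesCount / idx@m))
  saveIndex(idx, output)
  invisible(idx)
}

#' Filter an RNA-seq sample against a panel (command entry point)
#'
#' Accepts either a prebuilt index (path or [GeneKmerIndex-class]) or a
#' panel FASTA, in which case the index is built on the fly.  Writes the
#' assignment TSV and, optionally, the filtered FASTQ of assigned reads.
#'
#' @param reference Panel FASTA path (ignored when `index` is given).
#' @param fastq1,fastq2 Sample FASTQ path(s); `fastq2` for paired-end.
#' @param outPrefix Output prefix: writes `<prefix>.assignments.tsv`
#'   and, when `writeFastq`, `<prefix>.filtered[_1|_2].fastq`.
#' @param index Optional prebuilt index (path or object).
#' @param config A [runConfig()].
#' @param writeFastq Also write the filtered FASTQ(s).
#' @return The assignment table, invisibly.
#' @export
cmdFilter <- function(reference = NULL, fastq1, fastq2 = NULL, outPrefix,
                      index = NULL, config = runConfig(),
                      writeFastq = TRUE) {
  idx <- if (is.null(index)) {
    if (is.null(reference)) stop("usage error: give a reference or an index")
    cfgPanel <- readGenePanel(reference)
    buildIndex(cfgPanel, k = config$k, m = config$bloomBits,
               seed = config$seed)
  } else if (is.character(index)) loadIndex(index) else index
  asg <- classifySample(fastq1, idx, mates = fastq2, tau = config$tau,
                        q = config$q, mode = config$mode,
                        pairingPolicy = config$pairingPolicy,
                        threads = config$threads)
  writeAssignments(asg, paste0(outPrefix, ".assignments.tsv"))
  if (writeFastq) {
    if (is.null(fastq2)) {
      writeFilteredFastq(fastq1, asg, paste0(outPrefix, ".filtered.fastq"))
    } else {
      writeFilteredFastq(fastq1, asg, paste0(outPrefix, ".filtered_1.fastq"),
                         mates = fastq2,
                         matesPath = paste0(outPrefix, ".filtered_2.fastq"))
    }
  }
  message(sprintf("%d of %d reads assigned to %d gene(s)",
                  length(unique(asg$read_id)), attr(asg, "n_reads"),
                  length(unique(asg$gene_name))))
  invisible(asg)
}

#' Simulate a benchmark scenario to disk (command entry point)
#'
#' @param outDir Output directory for the simulation bundle (see
#'   [writeSimulation()]).
#' @param config A [simConfig()].
#' @return The written paths, invisibly.
#' @export
cmdSimulate <- function(outDir, config = simConfig()) {
  scenario <- simulateScenario(config)
  paths <- writeSimulation(scenario, outDir)
  message("simulation written to ", outDir)
  invisible(paths)
}

#' Evaluate an assignment TSV against a truth TSV (command entry point)
#'
#' @param assignmentsTsv Path to the classifier's assignment TSV.
#' @param truthTsv Path to the truth TSV (`read_id`, `origin_gene`).
#' @param panel Panel gene names, or a panel FASTA path.
#' @param output Optional JSON output path (see [writeMetrics()]).
#' @return The `evalReport`, invisibly.
#' @export
cmdEvaluate <- function(assignmentsTsv, truthTsv, panel, output = NULL) {
  asg <- readAssignments(assignmentsTsv)
  truth <- read.delim(truthTsv, stringsAsFactors = FALSE,
                      colClasses = "character")
  panelGenes <- if (length(panel) == 1L && file.exists(panel))
    geneNames(readGenePanel(panel)) else panel
  rep <- evaluateAssignments(asg, truth, panelGenes)
  if (!is.null(output)) writeMetrics(rep, output)
  print(rep)
  invisible(rep)
}
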