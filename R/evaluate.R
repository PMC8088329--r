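#' Score read assignments against simulation truth
#'
#' Per-read accounting over an assignment table and the known origin
#' genes: an assignment of a read to its true origin gene (origin in the
#' panel) counts one true positive; every assignment of a read to a
#' panel gene that is not its origin counts one false positive — this
#' covers both misassignment of a panel-origin read and capture of a
#' read whose origin lies outside the panel; a read whose origin is in
#' the panel but that received no assignment to it counts one false
#' negative.  A read assigned to its origin plus another gene therefore
#' induces both a tp and an fp, and a read assigned only to a wrong gene
#' induces both an fp and an fn.  Precision is `tp/(tp+fp)` (NA when
#' undefined), recall `tp/(tp+fn)`; recall's denominator is the number
#' of reads simulated from panel genes, and each read contributes at
#' most one fn.
#'
#' @param assignments Assignment table from [classifySample()] (or read
#'   back with [readAssignments()]); every `gene_name` must be in
#'   `panelGenes`.
#' @param truth `data.frame` with columns `read_id` and `origin_gene`
#'   (one origin per read), as produced by [simulateReads()].
#' @param panelGenes Character vector of panel gene names.
#' @return A list of class `evalReport`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @examples
#' truth <- data.frame(read_id = "r1", origin_gene = "g1")
#' both <- data.frame(read_id = "r1", gene_name = c("g1", "g2"))
#' evaluateAssignments(both, truth, c("g1", "g2"))  # tp 1, fp 1, fn 0
#' @export
evaluateAssignments <- function(assignments, truth, panelGenes) {
  stopifnot(all(c("read_id", "gene_name") %in% names(assignments)),
            all(c("read_id", "origin_gene") %in% names(truth)))
  if (anyDuplicated(truth$read_id))
    stop("data error: duplicated read_id in truth")
  unknown <- setdiff(assignments$read_id, truth$read_id)
  if (length(unknown) > 0L)
    stop("data error: assignment references unknown read(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  if (!all(assignments$gene_name %in% panelGenes))
    stop("data error: assignment to a gene outside the panel")

  origin <- truth$origin_gene[match(assignments$read_id, truth$read_id)]
  tp <- sum(assignments$gene_name == origin)
  fp <- sum(assignments$gene_name != origin)
  panelReads <- truth$read_id[truth$origin_gene %in% panelGenes]
  correctlyAssigned <- assignments$read_id[assignments$gene_name == origin]
  fn <- sum(!(panelReads %in% correctlyAssigned))
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("gene-assignment evaluation: tp %d, fp %d, fn %d\n",
              x$tp, x$fp, x$fn))
  cat(sprintf("  precision %s  recall %s\n",
              if (is.na(x$precision)) "NA" else sprintf("%.4f", x$precision),
              if (is.na(x$recall)) "NA" else sprintf("%.4f", x$recall)))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Counts and metrics are written as bare JSON numbers; an undefined
#' precision or recall is written as `null`.
#'
#' @param report An `evalReport` from [evaluateAssignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(report, path) {
  x <- unclass(report)
  x$precision <- if (is.na(x$precision)) NULL else x$precision
  x$recall <- if (is.na(x$recall)) NULL else x$recall
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
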