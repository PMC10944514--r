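#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

#' TranscriptAnnotation: transcript models and reference junctions
#'
#' Container produced by [loadAnnotation()]. Holds the per-transcript exon
#' models (with CDS bounds and canonical flags), the reference exon-exon
#' junction set implied by consecutive exons of every transcript, and the
#' gene footprints (min start to max end over all transcript exons) used for
#' gene assignment of junctions.
#'
#' @slot models Named list of transcript models (see [loadAnnotation()]).
#' @slot refJunctions `GRanges` of reference intron intervals (unique).
#' @slot genes `GRanges` of gene footprints with `gene_id`/`gene_symbol`.
#' @export
setClass("TranscriptAnnotation",
         representation(models = "list",
                        refJunctions = "GRanges",
                        genes = "GRanges"))

#' JunctionCatalog: a junction x sample count matrix with metadata
#'
#' Extends `RangedSummarizedExperiment`. Rows are unique splice junctions
#' (intron intervals as `rowRanges`, keyed `chrom:start-end:strand`), columns
#' are samples, and the `"counts"` assay holds unique-read junction counts.
#' `colData` carries the sample manifest; `rowData` gains `annotated`,
#' `gene_id`, `gene_symbol` and `ambiguous` columns as the catalog is
#' annotated with [flagAnnotated()] and [assignGenes()].
#'
#' The junction universe of a catalog built by the [JunctionCatalog()]
#' constructor is the set of junctions reaching the detection floor
#' (default 10 unique reads) in at least one tumor sample; counts below the
#' floor in other samples are still recorded because they feed read-depth
#' and frequency computations.
#'
#' @export
setClass("JunctionCatalog", contains = "RangedSummarizedExperiment")

setValidity("JunctionCatalog", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    k <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(k)) msg <- c(msg, "counts must not contain NA")
    else if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "junction keys (rownames) must be unique")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"cohort" %in% names(cd) ||
      !all(cd$cohort %in% c("tumor", "normal"))) {
    msg <- c(msg, "colData$cohort must be 'tumor' or 'normal'")
  }
  if (is.null(msg)) TRUE else msg
})

#' PositivityCalls: per junction x sample positivity evaluation
#'
#' Produced by [positivityCalls()]. For every junction and sample it records
#' the supportive read count, the count of the most dominant overlapping
#' junction, the read depth (their sum), the supportive read frequency
#' (count / depth) and the boolean positivity call under cohort-specific
#' thresholds.
#'
#' @slot positive Logical matrix of calls (junctions x samples).
#' @slot count,dominant_count,depth Integer matrices.
#' @slot frequency Numeric matrix; 0 where depth is 0.
#' @slot dominant `DataFrame` with, per junction, the dominant overlapping
#'   junction key (or `NA`) and whether it is annotated.
#' @slot thresholds List of cohort threshold sets (see
#'   [positivityThresholds()]).
#' @export
setClass("PositivityCalls",
         representation(positive = "matrix",
                        count = "matrix",
                        dominant_count = "matrix",
                        depth = "matrix",
                        frequency = "matrix",
                        dominant = "DataFrame",
                        thresholds = "list"))

#' ScreenResult: outcome of the screening cascade
#'
#' Produced by [runScreen()]. Carries the per-junction candidate table with
#' per-stage pass/fail flags and first-failure reasons, the stage-count
#' ledger, the per-template consequence reports, the positivity calls and
#' PSR table, and the configuration used.
#'
#' @slot candidates `DataFrame`, one row per non-annotated junction.
#' @slot ledger `data.frame` of stage counts (non-increasing).
#' @slot consequences `DataFrame`, one row per junction x template evaluated.
#' @slot calls `PositivityCalls`.
#' @slot psr Numeric matrix of positive-sample rates (junctions x groups).
#' @slot config List of thresholds used.
#' @slot catalog `JunctionCatalog` the screen was run on.
#' @export
setClass("ScreenResult",
         representation(candidates = "DataFrame",
                        ledger = "data.frame",
                        consequences = "DataFrame",
                        calls = "PositivityCalls",
                        psr = "matrix",
                        config = "list",
                        catalog = "JunctionCatalog"))
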