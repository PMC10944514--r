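#' Build a junction catalog from per-sample junction tables
#'
#' Assembles the cohort junction count matrix. The junction universe is the
#' set of junctions with at least `detection_min_count` unique supporting
#' reads in at least one *tumor* sample; normal-cohort tables never expand
#' the universe (the normal cohort is only interrogated at the
#' tumor-detected junctions). Counts below the detection floor in other
#' samples are retained, since they feed read-depth and frequency
#' computations.
#'
#' @param tables Named list (names are sample ids) of junction tables as
#'   returned by [readSJTab()]: `GRanges` with a `count` metadata column.
#' @param manifest Manifest `data.frame` (see [loadManifest()]) covering at
#'   least the samples in `tables`.
#' @param detection_min_count Detection floor, default 10 unique reads.
#' @return A [JunctionCatalog-class].
#' @export
JunctionCatalog <- function(tables, manifest, detection_min_count = 10L) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("'tables' must be a named list (sample ids)")
  }
  if (anyDuplicated(names(tables))) {
    stop("duplicate sample id in tables: ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "))
  }
  missing <- setdiff(names(tables), manifest$sample_id)
  if (length(missing)) {
    stop("sample(s) absent from manifest: ", paste(missing, collapse = ", "))
  }
  manifest <- manifest[match(names(tables), manifest$sample_id), , drop = FALSE]
  is_tumor <- manifest$cohort == "tumor"

  keys_per <- lapply(tables, junctionKeyFromRanges)
  counts_per <- lapply(tables, function(t) t$count)

  tumor_keys <- unlist(keys_per[is_tumor], use.names = FALSE)
  tumor_counts <- unlist(counts_per[is_tumor], use.names = FALSE)
  universe <- unique(tumor_keys[tumor_counts >= detection_min_count])
  rr <- .keyToGRanges(universe)
  o <- .orderJunctions(rr)
  rr <- rr[o]
  universe <- universe[o]

  k <- matrix(0L, nrow = length(universe), ncol = length(tables),
              dimnames = list(universe, names(tables)))
  for (j in seq_along(tables)) {
    idx <- match(keys_per[[j]], universe)
    hit <- !is.na(idx)
    if (any(counts_per[[j]][hit] < 0)) {
      stop("negative junction count in sample ", names(tables)[j])
    }
    k[idx[hit], j] <- as.integer(counts_per[[j]][hit])
  }

  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    annotated = rep(NA, length(rr)),
    gene_id = NA_character_,
    gene_symbol = NA_character_,
    ambiguous = FALSE)
  names(rr) <- universe
  cd <- S4Vectors::DataFrame(manifest, row.names = manifest$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = k), rowRanges = rr, colData = cd)
  new("JunctionCatalog", se)
}

#' @rdname JunctionCatalog-class
#' @export
setMethod("junctionKeys", "JunctionCatalog", function(x) rownames(x))

#' @rdname JunctionCatalog-class
#' @export
setMethod("isAnnotated", "JunctionCatalog", function(x) {
  SummarizedExperiment::rowData(x)$annotated
})

#' @rdname JunctionCatalog-class
#' @export
setMethod("hostGene", "JunctionCatalog", function(x) {
  SummarizedExperiment::rowData(x)$gene_id
})

#' @rdname JunctionCatalog-class
#' @param object A `JunctionCatalog`.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "JunctionCatalog", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "JunctionCatalog", function(object) {
  ann <- isAnnotated(object)
  cat("JunctionCatalog:", nrow(object), "junctions x", ncol(object),
      "samples\n")
  cat("  tumor samples:",
      sum(SummarizedExperiment::colData(object)$cohort == "tumor"),
      " normal samples:",
      sum(SummarizedExperiment::colData(object)$cohort == "normal"), "\n")
  if (!all(is.na(ann))) {
    cat("  annotated:", sum(ann, na.rm = TRUE),
        " non-annotated:", sum(!ann, na.rm = TRUE), "\n")
  }
})

#' Flag annotated junctions
#'
#' A junction is annotated when its (chromosome, intron start, intron end)
#' coordinates match a reference junction derived from the GTF. Strand
#' participates only when both the junction and the reference carry a
#' defined strand; a junction with undefined strand matches a reference
#' junction at the same coordinates on either strand.
#'
#' @param catalog A [JunctionCatalog-class].
#' @param annotation A [TranscriptAnnotation-class].
#' @return The catalog with `rowData$annotated` filled in.
#' @export
flagAnnotated <- function(catalog, annotation) {
  rr <- SummarizedExperiment::rowRanges(catalog)
  ref <- refJunctions(annotation)
  ann <- rep(FALSE, length(rr))
  if (length(ref)) {
    hits <- GenomicRanges::findOverlaps(rr, ref, type = "equal",
                                        ignore.strand = TRUE)
    qs <- as.character(GenomicRanges::strand(rr))[S4Vectors::queryHits(hits)]
    ss <- as.character(GenomicRanges::strand(ref))[S4Vectors::subjectHits(hits)]
    ok <- .strandCompatible(qs, ss)
    ann[unique(S4Vectors::queryHits(hits)[ok])] <- TRUE
  }
  SummarizedExperiment::rowData(catalog)$annotated <- ann
  catalog
}

#' Assign junctions to surfaceome genes
#'
#' A junction is assigned to a surfaceome gene when its intron interval
#' overlaps any portion of the gene's genomic footprint on a compatible
#' strand. When a junction overlaps two or more surfaceome genes the gene
#' with the larger overlap is assigned; exact ties are reported in
#' `gene_id` as a comma-separated list and flagged `ambiguous` rather than
#' silently resolved.
#'
#' Junctions with undefined strand inherit the strand of their overlapping
#' gene(s); when the overlapping genes disagree on strand the junction is
#' dropped from the catalog with a log entry.
#'
#' @param catalog A [JunctionCatalog-class].
#' @param annotation A [TranscriptAnnotation-class].
#' @param surfaceome Surfaceome table from [loadSurfaceome()]; assignment is
#'   restricted to these genes. Pass `NULL` to assign against all annotated
#'   genes.
#' @return The catalog with `rowData$gene_id`, `gene_symbol` and `ambiguous`
#'   filled in (possibly with strand-conflicted junctions removed).
#' @export
assignGenes <- function(catalog, annotation, surfaceome = NULL) {
  genes <- geneFootprints(annotation)
  if (!is.null(surfaceome)) {
    genes <- genes[genes$gene_id %in% unique(surfaceome$gene_id)]
  }
  rr <- SummarizedExperiment::rowRanges(catalog)
  hits <- GenomicRanges::findOverlaps(rr, genes, ignore.strand = TRUE)
  qs <- as.character(GenomicRanges::strand(rr))[S4Vectors::queryHits(hits)]
  ss <- as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(hits)]
  hits <- hits[.strandCompatible(qs, ss)]

  gene_id <- rep(NA_character_, length(rr))
  gene_symbol <- rep(NA_character_, length(rr))
  ambiguous <- rep(FALSE, length(rr))
  drop <- logical(length(rr))
  new_strand <- as.character(GenomicRanges::strand(rr))

  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ow <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(rr)[q], IRanges::ranges(genes)[s]))
    for (i in unique(q)) {
      sel <- which(q == i)
      gs <- as.character(GenomicRanges::strand(genes))[s[sel]]
      if (new_strand[i] == "*") {
        us <- unique(gs[gs != "*"])
        if (length(us) > 1L) {
          drop[i] <- TRUE
          next
        }
        if (length(us) == 1L) new_strand[i] <- us
      }
      best <- max(ow[sel])
      top <- sel[ow[sel] == best]
      ids <- sort(genes$gene_id[s[top]])
      if (length(ids) > 1L) {
        ambiguous[i] <- TRUE
        gene_id[i] <- paste(ids, collapse = ",")
        gene_symbol[i] <- paste(
          genes$gene_symbol[s[top]][order(genes$gene_id[s[top]])],
          collapse = ",")
      } else {
        gene_id[i] <- ids
        gene_symbol[i] <- genes$gene_symbol[s[top][1]]
      }
    }
  }
  if (any(drop)) {
    .njxLog("dropping ", sum(drop),
            " junction(s) with undefined strand overlapping genes on both strands: ",
            paste(head(rownames(catalog)[drop], 5), collapse = ", "))
  }
  GenomicRanges::strand(rr) <- new_strand
  SummarizedExperiment::rowRanges(catalog) <- rr
  SummarizedExperiment::rowData(catalog)$gene_id <- gene_id
  SummarizedExperiment::rowData(catalog)$gene_symbol <- gene_symbol
  SummarizedExperiment::rowData(catalog)$ambiguous <- ambiguous
  if (any(drop)) catalog <- catalog[!drop, ]
  catalog
}
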