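#' Cohort-specific positivity thresholds
#'
#' A junction is called positive in a sample when (1) its supportive read
#' count, (2) the read depth at the junction (supportive count plus the
#' count of the most dominant overlapping junction) and (3) the supportive
#' read frequency (count / depth) all reach their thresholds. The tumor
#' cohort uses count >= 10, depth >= 20, frequency >= 0.01; the normal
#' cohort, whose libraries are smaller, uses count >= 2, depth >= 10,
#' frequency >= 0.01.
#'
#' @param tumor_min_count,tumor_min_depth Tumor thresholds.
#' @param normal_min_count,normal_min_depth Normal thresholds.
#' @param min_frequency Frequency threshold shared by both cohorts.
#' @return A list with `tumor` and `normal` threshold sets.
#' @export
positivityThresholds <- function(tumor_min_count = 10L, tumor_min_depth = 20L,
                                 normal_min_count = 2L, normal_min_depth = 10L,
                                 min_frequency = 0.01) {
  list(tumor = list(min_count = tumor_min_count, min_depth = tumor_min_depth,
                    min_frequency = min_frequency),
       normal = list(min_count = normal_min_count, min_depth = normal_min_depth,
                     min_frequency = min_frequency))
}

#' Most dominant overlapping junction
#'
#' For every junction in the catalog, selects the most dominant overlapping
#' junction: among junctions whose intron intervals intersect the query on
#' the same chromosome and a compatible strand (the query itself excluded),
#' the annotated junction with the largest total count over the tumor
#' cohort; if no annotated junction overlaps, the overlapping junction with
#' the largest tumor total. The selection is computed once on tumor totals
#' and reused unchanged for every cohort, so tumor and normal samples of
#' one junction are always evaluated against the same competitor. Ties are
#' broken by lexicographic junction key, making the choice deterministic.
#'
#' @param catalog A [JunctionCatalog-class] with `annotated` flags set (see
#'   [flagAnnotated()]).
#' @param allow_self If `TRUE`, a junction may be selected as its own
#'   dominant junction (in which case depth doubles its count). Default
#'   `FALSE`: with no overlapping junction at all, depth equals the
#'   junction's own count and the frequency is 1, so isolated novel
#'   junctions remain callable.
#' @return A `DataFrame` with one row per junction: `dominant_index`
#'   (row index into the catalog, `NA` if nothing overlaps),
#'   `dominant_key`, and `dominant_annotated`.
#' @export
dominantJunctions <- function(catalog, allow_self = FALSE) {
  ann <- isAnnotated(catalog)
  if (all(is.na(ann))) {
    stop("catalog has no annotation flags; run flagAnnotated() first")
  }
  k <- counts(catalog)
  tumor <- SummarizedExperiment::colData(catalog)$cohort == "tumor"
  totals <- rowSums(k[, tumor, drop = FALSE])
  rr <- SummarizedExperiment::rowRanges(catalog)
  hits <- GenomicRanges::findOverlaps(rr, drop.self = !allow_self,
                                      ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  n <- nrow(catalog)
  dom <- rep(NA_integer_, n)
  if (length(q)) {
    keys <- rownames(catalog)
    # prefer annotated, then larger tumor total, then lexicographic key
    o <- order(q, !ann[s], -totals[s], keys[s], method = "radix")
    first <- !duplicated(q[o])
    dom[q[o][first]] <- s[o][first]
  }
  S4Vectors::DataFrame(
    dominant_index = dom,
    dominant_key = ifelse(is.na(dom), NA_character_, rownames(catalog)[dom]),
    dominant_annotated = ifelse(is.na(dom), NA, ann[dom]),
    row.names = rownames(catalog))
}

#' Per-sample positivity calls
#'
#' Evaluates every junction in every sample against the cohort-specific
#' thresholds: read depth is the junction's supportive count plus the
#' per-sample count of its precomputed dominant overlapping junction, and
#' frequency is count / depth. A junction with no overlapping junction has
#' depth equal to its own count (frequency 1 when the count is non-zero;
#' with depth 0 the call is negative).
#'
#' @param catalog A [JunctionCatalog-class] with annotation flags.
#' @param dominant Optional result of [dominantJunctions()]; computed when
#'   omitted.
#' @param thresholds Threshold sets from [positivityThresholds()].
#' @return A [PositivityCalls-class].
#' @export
positivityCalls <- function(catalog, dominant = NULL,
                            thresholds = positivityThresholds()) {
  if (is.null(dominant)) dominant <- dominantJunctions(catalog)
  k <- counts(catalog)
  if (any(k < 0)) stop("negative junction counts")
  dom_idx <- dominant$dominant_index
  d <- matrix(0L, nrow(k), ncol(k), dimnames = dimnames(k))
  has <- !is.na(dom_idx)
  d[has, ] <- k[dom_idx[has], , drop = FALSE]
  depth <- k + d
  freq <- matrix(0, nrow(k), ncol(k), dimnames = dimnames(k))
  nz <- depth > 0
  freq[nz] <- k[nz] / depth[nz]

  cohort <- SummarizedExperiment::colData(catalog)$cohort
  min_count <- ifelse(cohort == "tumor", thresholds$tumor$min_count,
                      thresholds$normal$min_count)
  min_depth <- ifelse(cohort == "tumor", thresholds$tumor$min_depth,
                      thresholds$normal$min_depth)
  min_freq <- ifelse(cohort == "tumor", thresholds$tumor$min_frequency,
                     thresholds$normal$min_frequency)
  pos <- sweep(k, 2, min_count, ">=") &
    sweep(depth, 2, min_depth, ">=") &
    sweep(freq, 2, min_freq, ">=")

  new("PositivityCalls", positive = pos, count = k, dominant_count = d,
      depth = depth, frequency = freq, dominant = dominant,
      thresholds = thresholds)
}

#' @rdname PositivityCalls-class
#' @export
setMethod("isPositive", "PositivityCalls", function(x) x@positive)

setMethod("show", "PositivityCalls", function(object) {
  cat("PositivityCalls:", nrow(object@positive), "junctions x",
      ncol(object@positive), "samples;",
      sum(object@positive), "positive calls\n")
})

#' Positive-sample rates per group
#'
#' The positive-sample rate (PSR) of a junction in a sample group is the
#' number of positive samples divided by the total number of samples in the
#' group — the full, fixed group size from the manifest, not the number of
#' callable samples. Tumor samples are grouped by their disease-group label;
#' all normal samples are additionally pooled into a single `normal` column
#' (the GTEx-style pooled rate used by the tumor-specificity filter).
#'
#' @param calls A [PositivityCalls-class].
#' @param manifest Manifest rows for the call matrix columns (defaults must
#'   be supplied by the caller; typically `colData(catalog)`).
#' @param by_tissue If `TRUE`, adds one `normal:<tissue>` column per normal
#'   group label (per-tissue PSR breakdown).
#' @return Numeric matrix, junctions x groups, with a `"denominators"`
#'   attribute giving each group's size.
#' @export
positiveSampleRate <- function(calls, manifest, by_tissue = FALSE) {
  pos <- isPositive(calls)
  manifest <- as.data.frame(manifest)
  if (nrow(manifest) != ncol(pos)) {
    stop("manifest must have one row per sample in the call matrix")
  }
  tumor <- manifest$cohort == "tumor"
  groups <- list()
  for (g in unique(manifest$group[tumor])) {
    groups[[g]] <- which(tumor & manifest$group == g)
  }
  groups[["normal"]] <- which(!tumor)
  if (by_tissue) {
    for (g in unique(manifest$group[!tumor])) {
      groups[[paste0("normal:", g)]] <- which(!tumor & manifest$group == g)
    }
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) {
    stop("empty sample group(s): ",
         paste(names(groups)[sizes == 0L], collapse = ", "))
  }
  psr <- vapply(groups, function(idx)
    rowSums(pos[, idx, drop = FALSE]) / length(idx),
    numeric(nrow(pos)))
  psr <- matrix(psr, nrow = nrow(pos),
                dimnames = list(rownames(pos), names(groups)))
  attr(psr, "denominators") <- sizes
  psr
}
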