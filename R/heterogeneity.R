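#' Spatial (multi-region) positivity summary
#'
#' Summarises, for each tumor and candidate event, in how many spatially
#' mapped pieces of the tumor the event is positive. An event is tumor-wide
#' when it is positive in 100% of the tumor's gated pieces — the stringent
#' pattern an antigen-directed therapy would want, and empirically the rare
#' one.
#'
#' @param positive Logical matrix, events x samples (e.g.
#'   `isPositive(calls)` subset to the tracked events).
#' @param manifest Manifest rows covering the columns of `positive`, with
#'   `patient_id` identifying the tumor and `piece_id` the piece.
#' @param gate Apply spatial purity gating ([gateSamples()] `mode =
#'   "spatial"`) before summarising. Default `TRUE`.
#' @param ... Passed to [gateSamples()].
#' @return A `data.frame` with one row per tumor x event: `tumor_id`,
#'   `event`, `n_pieces`, `n_positive`, `fraction`, `tumor_wide`.
#' @export
spatialSummary <- function(positive, manifest, gate = TRUE, ...) {
  manifest <- as.data.frame(manifest)
  pre <- manifest[manifest$cohort == "tumor" &
                    manifest$sample_id %in% colnames(positive), , drop = FALSE]
  if (gate) manifest <- gateSamples(manifest, mode = "spatial", ...)
  manifest <- manifest[manifest$cohort == "tumor" &
                         manifest$sample_id %in% colnames(positive), ,
                       drop = FALSE]
  tumors <- unique(manifest$patient_id)
  empty <- setdiff(unique(pre$patient_id), tumors)
  if (length(empty)) {
    warning("tumor(s) with no gated pieces omitted: ",
            paste(empty, collapse = ", "))
  }
  rows <- lapply(tumors, function(tid) {
    pieces <- manifest$sample_id[manifest$patient_id == tid]
    np <- length(pieces)
    pos <- rowSums(positive[, pieces, drop = FALSE])
    data.frame(tumor_id = tid, event = rownames(positive),
               n_pieces = np, n_positive = as.integer(pos),
               fraction = pos / np, tumor_wide = pos == np,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Longitudinal (primary/recurrent) positivity classification
#'
#' Classifies each event in each patient with paired primary and recurrent
#' samples. A timepoint is positive when the fraction of its positive
#' pieces is at least `piece_majority` (default 0.5, boundary inclusive;
#' for a single-piece timepoint this is that piece's call). The status is
#' the truth table of the two timepoint booleans: `shared`, `primary_only`,
#' `recurrent_only` or `absent`. Patients missing either timepoint are
#' omitted with a warning.
#'
#' @param positive Logical matrix, events x samples.
#' @param manifest Manifest rows covering the columns of `positive`, with
#'   `patient_id` and `timepoint` (`primary`/`recurrent`).
#' @param piece_majority Positivity fraction threshold applied symmetrically
#'   to both timepoints.
#' @return A `data.frame` with one row per patient x event: `patient_id`,
#'   `event`, `primary_positive`, `recurrent_positive`, `status`.
#' @export
longitudinalClassify <- function(positive, manifest, piece_majority = 0.5) {
  manifest <- as.data.frame(manifest)
  manifest <- manifest[manifest$cohort == "tumor" &
                         manifest$sample_id %in% colnames(positive) &
                         !is.na(manifest$timepoint), , drop = FALSE]
  patients <- unique(manifest$patient_id)
  complete <- vapply(patients, function(p) {
    tp <- manifest$timepoint[manifest$patient_id == p]
    all(c("primary", "recurrent") %in% tp)
  }, logical(1))
  if (any(!complete)) {
    warning("patient(s) missing a timepoint omitted: ",
            paste(patients[!complete], collapse = ", "))
  }
  rows <- lapply(patients[complete], function(p) {
    tp_pos <- vapply(c("primary", "recurrent"), function(tp) {
      pieces <- manifest$sample_id[manifest$patient_id == p &
                                     manifest$timepoint == tp]
      rowMeans(positive[, pieces, drop = FALSE]) >= piece_majority
    }, logical(nrow(positive)))
    tp_pos <- matrix(tp_pos, nrow = nrow(positive), ncol = 2)
    status <- ifelse(tp_pos[, 1] & tp_pos[, 2], "shared",
                     ifelse(tp_pos[, 1], "primary_only",
                            ifelse(tp_pos[, 2], "recurrent_only", "absent")))
    data.frame(patient_id = p, event = rownames(positive),
               primary_positive = tp_pos[, 1],
               recurrent_positive = tp_pos[, 2],
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), event = character(0),
                      primary_positive = logical(0),
                      recurrent_positive = logical(0),
                      status = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
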