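#' Screening configuration
#'
#' Bundles every threshold of the screening cascade. Defaults follow the
#' glioma screen: a detection floor of 10 unique reads, surfaceome gene
#' mean TPM >= 10 across the tumor cohort, pooled-normal PSR < 0.01
#' (strict) for tumor-specificity, and a disease-group PSR >= 0.10 in at
#' least one group for sharedness. The expression statistic is configurable
#' (`"mean"` or `"median"`). `per_tissue_normal_gate` optionally adds the
#' stricter per-normal-tissue PSR < `max_tissue_psr` gate. `exclude` is a
#' machine-readable exclusion list of junction keys standing in for the
#' final manual-review step, so the pipeline stays deterministic.
#'
#' @param detection_min_count Detection floor for the junction universe.
#' @param min_mean_tpm Expression gate on the host surfaceome gene.
#' @param expression_stat `"mean"` or `"median"`.
#' @param max_normal_psr Pooled-normal PSR bound (strict `<`).
#' @param min_group_psr Disease-group PSR bound (inclusive `>=`).
#' @param per_tissue_normal_gate Apply the per-tissue normal gate.
#' @param max_tissue_psr Per-tissue PSR bound (strict `<`).
#' @param thresholds Positivity thresholds, see [positivityThresholds()].
#' @param allow_self_dominant See [dominantJunctions()].
#' @param exclude Character vector of junction keys to drop at the final
#'   (manual-review) stage.
#' @return A named list.
#' @export
screenConfig <- function(detection_min_count = 10L,
                         min_mean_tpm = 10,
                         expression_stat = c("mean", "median"),
                         max_normal_psr = 0.01,
                         min_group_psr = 0.10,
                         per_tissue_normal_gate = FALSE,
                         max_tissue_psr = 0.01,
                         thresholds = positivityThresholds(),
                         allow_self_dominant = FALSE,
                         exclude = character(0)) {
  list(detection_min_count = detection_min_count,
       min_mean_tpm = min_mean_tpm,
       expression_stat = match.arg(expression_stat),
       max_normal_psr = max_normal_psr,
       min_group_psr = min_group_psr,
       per_tissue_normal_gate = per_tissue_normal_gate,
       max_tissue_psr = max_tissue_psr,
       thresholds = thresholds,
       allow_self_dominant = allow_self_dominant,
       exclude = exclude)
}

#' Read a screening configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [screenConfig()]
#' (positivity thresholds under `thresholds: tumor_min_count`,
#' `tumor_min_depth`, `normal_min_count`, `normal_min_depth`,
#' `min_frequency`). Unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A configuration list as from [screenConfig()].
#' @export
readScreenConfig <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(positivityThresholds, y$thresholds %||% list())
  y$thresholds <- NULL
  args <- y[names(y) %in% names(formals(screenConfig))]
  do.call(screenConfig, c(args, list(thresholds = th)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expression summary per gene over the tumor cohort.
.geneExpressionStat <- function(expression, tumor_samples, stat) {
  cols <- intersect(tumor_samples, colnames(expression))
  if (!length(cols)) stop("no tumor samples found in expression matrix")
  f <- if (stat == "median") stats::median else mean
  apply(expression[, cols, drop = FALSE], 1, f)
}

#' Expression and surfaceome membership filter
#'
#' Keeps junctions assigned to a surfaceome gene whose mean (or median)
#' TPM across the tumor cohort reaches `min_mean_tpm`. Junctions on genes
#' absent from the expression matrix fail with a logged reason.
#'
#' @param gene_ids Host gene per junction (`NA` for unassigned junctions).
#' @param expression TPM matrix from [loadExpression()].
#' @param tumor_samples Tumor sample ids defining the averaging cohort.
#' @param min_mean_tpm Gate value (inclusive).
#' @param stat `"mean"` or `"median"`.
#' @return Logical keep vector with a `"gene_stat"` attribute.
#' @export
filterExpressionSurfaceome <- function(gene_ids, expression, tumor_samples,
                                       min_mean_tpm = 10,
                                       stat = c("mean", "median")) {
  stat <- match.arg(stat)
  gstat <- .geneExpressionStat(expression, tumor_samples, stat)
  has_gene <- !is.na(gene_ids) & !grepl(",", gene_ids)
  in_expr <- has_gene & gene_ids %in% names(gstat)
  missing <- unique(gene_ids[has_gene & !in_expr])
  if (length(missing)) {
    .njxLog("gene(s) missing from expression matrix, candidates fail: ",
            paste(missing, collapse = ", "))
  }
  keep <- in_expr
  keep[in_expr] <- gstat[gene_ids[in_expr]] >= min_mean_tpm
  attr(keep, "gene_stat") <- gstat
  keep
}

#' Tumor-specificity filter
#'
#' Keeps events whose pooled-normal positive-sample rate is strictly below
#' `max_normal_psr` (< 1% of the normal cohort by default).
#'
#' @param psr PSR matrix from [positiveSampleRate()].
#' @param max_normal_psr Strict upper bound.
#' @return Logical keep vector.
#' @export
filterTumorSpecific <- function(psr, max_normal_psr = 0.01) {
  psr[, "normal"] < max_normal_psr
}

#' Sharedness filter
#'
#' Keeps events reaching a positive-sample rate of at least `min_group_psr`
#' in at least one tumor disease group.
#'
#' @param psr PSR matrix from [positiveSampleRate()].
#' @param min_group_psr Inclusive lower bound on the best group PSR.
#' @return Logical keep vector.
#' @export
filterShared <- function(psr, min_group_psr = 0.10) {
  grp <- setdiff(colnames(psr), grep("^normal", colnames(psr), value = TRUE))
  apply(psr[, grp, drop = FALSE], 1, max) >= min_group_psr
}

#' Extracellular-consequence filter
#'
#' Keeps junctions for which the host protein is single-pass and at least
#' one canonical template predicts an alteration affecting the
#' extracellular region, with the transmembrane segment intact and no
#' premature termination codon. The two sub-criteria are also exposed
#' separately (`stage = "extracellular"` keeps any-template extracellular
#' impact; `stage = "protein"` additionally requires no PTC, intact TM and
#' a single-pass host), matching the two counted steps of the cascade.
#'
#' @param keys Junction keys to evaluate.
#' @param consequences Consequence table from [predictConsequences()].
#' @param stage `"combined"`, `"extracellular"` or `"protein"`.
#' @return Logical keep vector aligned with `keys`.
#' @export
filterExtracellular <- function(keys, consequences,
                                stage = c("combined", "extracellular",
                                          "protein")) {
  stage <- match.arg(stage)
  cq <- as.data.frame(consequences)
  ext <- function(k) {
    r <- cq[cq$junction == k & isTRUE_v(cq$assessable), , drop = FALSE]
    any(isTRUE_v(r$affects_extracellular))
  }
  prot <- function(k) {
    r <- cq[cq$junction == k & isTRUE_v(cq$assessable), , drop = FALSE]
    any(isTRUE_v(r$pass))
  }
  vapply(keys, switch(stage, extracellular = ext, protein = prot,
                      combined = prot),
         logical(1), USE.NAMES = FALSE)
}

# element-wise isTRUE for possibly-NA logical vectors
isTRUE_v <- function(x) !is.na(x) & x

#' Run the screening cascade
#'
#' Executes the eight screening steps in order on a junction catalog:
#' (1) the detected junction universe, (2) exclusion of annotated
#' junctions, (3) restriction to expressed surfaceome genes, (4)
#' tumor-specificity against the pooled normal cohort, (5) sharedness
#' across disease groups, (6) extracellular impact, (7) in-silico
#' translation verdict (no PTC, intact transmembrane segment, single-pass
#' host) and (8) the machine-readable exclusion list standing in for manual
#' review. The per-stage surviving counts are recorded in a ledger, and
#' every dropped junction carries exactly one first-failure reason.
#' Re-running with identical inputs and configuration is deterministic.
#'
#' @param catalog A [JunctionCatalog-class] (universe already reflects the
#'   detection floor).
#' @param annotation A [TranscriptAnnotation-class].
#' @param expression TPM matrix from [loadExpression()].
#' @param surfaceome Surfaceome table from [loadSurfaceome()].
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @param config Configuration from [screenConfig()].
#' @return A [ScreenResult-class].
#' @export
runScreen <- function(catalog, annotation, expression, surfaceome, genome,
                      config = screenConfig()) {
  stages <- c("detected", "non_annotated", "expression_surfaceome",
              "tumor_specific", "shared", "extracellular", "protein",
              "final")
  catalog <- flagAnnotated(catalog, annotation)
  catalog <- assignGenes(catalog, annotation, surfaceome)
  cd <- SummarizedExperiment::colData(catalog)

  dominant <- dominantJunctions(catalog,
                                allow_self = config$allow_self_dominant)
  calls <- positivityCalls(catalog, dominant, config$thresholds)
  psr <- positiveSampleRate(calls, cd,
                            by_tissue = config$per_tissue_normal_gate)

  ann <- isAnnotated(catalog)
  keys <- junctionKeys(catalog)
  cand_idx <- which(!ann)
  n <- length(cand_idx)
  ck <- keys[cand_idx]
  gene_ids <- hostGene(catalog)[cand_idx]

  alive <- rep(TRUE, n)
  first_fail <- rep(NA_character_, n)
  flags <- matrix(NA, nrow = n, ncol = 6,
                  dimnames = list(ck, stages[3:8]))
  fail_at <- function(stage, keep) {
    idx <- which(alive)[!keep[alive]]
    first_fail[idx] <<- stage
    flags[, stage] <<- alive & keep
    alive <<- alive & keep
  }

  # stage 3: expressed surfaceome gene
  keep3 <- filterExpressionSurfaceome(
    gene_ids, expression, cd$sample_id[cd$cohort == "tumor"],
    min_mean_tpm = config$min_mean_tpm, stat = config$expression_stat)
  gene_stat <- attr(keep3, "gene_stat")
  fail_at("expression_surfaceome", as.logical(keep3))

  # stage 4: tumor-specific vs pooled normal (plus optional per-tissue gate)
  keep4 <- filterTumorSpecific(psr[cand_idx, , drop = FALSE],
                               config$max_normal_psr)
  if (config$per_tissue_normal_gate) {
    tcols <- grep("^normal:", colnames(psr), value = TRUE)
    if (length(tcols)) {
      keep4 <- keep4 & apply(psr[cand_idx, tcols, drop = FALSE], 1,
                             max) < config$max_tissue_psr
    }
  }
  fail_at("tumor_specific", keep4)

  # stage 5: shared across disease groups
  keep5 <- filterShared(psr[cand_idx, , drop = FALSE], config$min_group_psr)
  fail_at("shared", keep5)

  # stages 6-7: consequence prediction on the survivors only
  surv <- which(alive)
  consequences <- predictConsequences(ck[surv], gene_ids[surv], annotation,
                                      genome, surfaceome)
  keep6 <- rep(TRUE, n)
  keep6[surv] <- filterExtracellular(ck[surv], consequences,
                                     stage = "extracellular")
  fail_at("extracellular", keep6)

  surv <- which(alive)
  keep7 <- rep(TRUE, n)
  keep7[surv] <- filterExtracellular(ck[surv], consequences,
                                     stage = "protein")
  fail_at("protein", keep7)

  # stage 8: exclusion list (manual review, reified)
  keep8 <- !(ck %in% config$exclude)
  fail_at("final", keep8)

  ledger <- data.frame(
    stage = seq_along(stages), label = stages,
    n = c(length(keys), n, sapply(stages[3:8], function(s)
      sum(flags[, s], na.rm = TRUE))),
    row.names = NULL)

  pattern <- rep(NA_character_, n)
  if (nrow(consequences)) {
    cq <- as.data.frame(consequences)
    # candidate-level pattern: label on the passing template when one
    # exists, otherwise on the first evaluated template
    for (i in seq_len(n)) {
      r <- cq[cq$junction == ck[i], , drop = FALSE]
      if (!nrow(r)) next
      p <- r$pattern[isTRUE_v(r$pass)]
      pattern[i] <- if (length(p)) p[1] else r$pattern[1]
    }
  }
  psr_df <- as.data.frame(psr[cand_idx, , drop = FALSE])
  names(psr_df) <- paste0("psr_", colnames(psr))
  cand <- S4Vectors::DataFrame(
    data.frame(
      junction = ck,
      gene_id = gene_ids,
      gene_symbol = SummarizedExperiment::rowData(catalog)$gene_symbol[cand_idx],
      pattern = pattern,
      mean_tumor_tpm = ifelse(
        !is.na(gene_ids) & gene_ids %in% names(gene_stat),
        gene_stat[gene_ids], NA_real_),
      psr_df,
      as.data.frame(flags),
      first_fail = first_fail,
      pass_all = alive,
      check.names = FALSE, stringsAsFactors = FALSE),
    row.names = ck, check.names = FALSE)

  new("ScreenResult", candidates = cand, ledger = ledger,
      consequences = consequences, calls = calls, psr = psr,
      config = config, catalog = catalog)
}

#' @rdname ScreenResult-class
#' @export
setMethod("candidates", "ScreenResult", function(x) x@candidates)

#' @rdname ScreenResult-class
#' @export
setMethod("screenLedger", "ScreenResult", function(x) x@ledger)

#' @rdname ScreenResult-class
#' @export
setMethod("consequenceReports", "ScreenResult", function(x) x@consequences)

#' @rdname ScreenResult-class
#' @export
setMethod("finalCandidates", "ScreenResult", function(x) {
  x@candidates$junction[x@candidates$pass_all]
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult\n")
  l <- object@ledger
  for (i in seq_len(nrow(l))) {
    cat(sprintf("  stage %d %-22s %d\n", l$stage[i], l$label[i], l$n[i]))
  }
})

#' Write the candidate report
#'
#' Writes the screening outcome as a TSV (one row per candidate x
#' consequence template, or one row per candidate when no template was
#' evaluated) plus a JSON sidecar carrying full provenance: thresholds,
#' stage ledger, and input hashes when file paths are supplied.
#'
#' @param result A [ScreenResult-class].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param inputs Optional named character vector of input file paths to
#'   hash (md5) into the sidecar.
#' @return Invisibly, the TSV path.
#' @export
writeCandidateReport <- function(result, path, inputs = NULL) {
  cand <- as.data.frame(candidates(result))
  cq <- as.data.frame(consequenceReports(result))
  if (nrow(cq)) {
    keep <- c("junction", "pattern", "transcript_id", "frame_status",
              "nt_delta", "aa_deleted", "aa_inserted", "ptc_introduced",
              "affects_extracellular", "tm_intact", "single_pass", "pass")
    cq <- cq[, intersect(keep, names(cq)), drop = FALSE]
    names(cq)[names(cq) == "pattern"] <- "template_pattern"
    out <- merge(cand, cq, by = "junction", all.x = TRUE, sort = FALSE)
  } else {
    out <- cand
  }
  out <- out[order(out$junction), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  sidecar <- list(
    config = result@config,
    ledger = result@ledger,
    n_candidates = nrow(cand),
    n_final = sum(cand$pass_all))
  if (!is.null(inputs)) {
    sidecar$input_md5 <- as.list(tools::md5sum(inputs))
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Re-read a candidate report
#'
#' Round-trip companion of [writeCandidateReport()].
#'
#' @param path TSV path written by [writeCandidateReport()].
#' @return A list with `table` (data.frame) and `provenance` (the parsed
#'   JSON sidecar).
#' @export
readCandidateReport <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  prov <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(table = tab, provenance = prov)
}
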