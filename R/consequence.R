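# Coerce a junction given as a key string or length-1 GRanges to a list.
.asJunction <- function(junction) {
  if (is.character(junction)) junction <- .keyToGRanges(junction)
  if (length(junction) != 1L) stop("expected a single junction")
  list(chrom = as.character(GenomicRanges::seqnames(junction)),
       start = GenomicRanges::start(junction),
       end = GenomicRanges::end(junction),
       strand = as.character(GenomicRanges::strand(junction)))
}

#' Classify the splicing pattern of a junction on a template
#'
#' A non-annotated junction is classified relative to one template
#' transcript by where its two intron ends fall. With both ends strictly
#' inside one annotated exon the junction excises a novel (cryptic) intron.
#' With the donor and acceptor both at annotated intron boundaries and at
#' least one whole exon inside the intron, it skips the enclosed exon(s).
#' With the donor at an annotated boundary and the acceptor shifted, the
#' acceptor (3') splice site is alternative; the mirror case is an
#' alternative donor (5') site. Donor and acceptor are oriented by the
#' template strand. Anything else is reported as complex; because the
#' comparison is template-relative, one junction may receive different
#' labels on different templates.
#'
#' @param junction Junction key string or length-1 `GRanges`.
#' @param model A transcript model from [loadAnnotation()].
#' @return One of `"cryptic_intron"`, `"exon_skip"`, `"alt_3ss"`,
#'   `"alt_5ss"`, `"complex"`.
#' @export
classifySplicePattern <- function(junction, model) {
  j <- .asJunction(junction)
  ex <- model$exons
  if (j$chrom != model$chrom ||
      j$end < min(IRanges::start(ex)) || j$start > max(IRanges::end(ex))) {
    stop("junction ", junctionKey(j$chrom, j$start, j$end, j$strand),
         " lies outside the footprint of transcript ", model$transcript_id)
  }
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  # both ends (and the flanking spliced bases) inside a single exon
  inside <- which(st < j$start & en > j$end)
  if (length(inside)) return("cryptic_intron")

  introns <- .modelIntrons(model)
  if (!length(introns)) return("complex")
  istart <- IRanges::start(introns); iend <- IRanges::end(introns)
  if (model$strand == "-") {
    donor_anno <- j$end %in% iend
    acceptor_anno <- j$start %in% istart
  } else {
    donor_anno <- j$start %in% istart
    acceptor_anno <- j$end %in% iend
  }
  skipped <- any(st > j$start & en < j$end)
  if (donor_anno && acceptor_anno && skipped) return("exon_skip")
  if (donor_anno && !acceptor_anno) return("alt_3ss")
  if (acceptor_anno && !donor_anno) return("alt_5ss")
  "complex"
}

#' Rebuild a template transcript under a splice event
#'
#' Applies a novel junction to a template: every template intron the novel
#' intron overlaps is merged into the locus and the novel intron's bases are
#' excised, so exonic bases inside the novel intron are removed (cryptic
#' intron, exon skip, alternative sites shifting into an exon) and template
#' intron bases outside it become exonic (alternative sites shifting into an
#' intron). The altered mature mRNA is assembled from the genome
#' (reverse-complemented for minus-strand templates) and the coding sequence
#' is re-extracted from the annotated start codon; an event that removes the
#' start codon renders the template non-translatable.
#'
#' @param junction Junction key string or length-1 `GRanges`.
#' @param model Transcript model (must have an annotated CDS).
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @return A list: `altered_exons` (`IRanges`), `altered_seq` (`DNAString`,
#'   mature mRNA), `translatable`, `alt_cds` (`DNAString` from the start
#'   codon to the transcript 3' end; `NULL` when non-translatable) and
#'   `nt_delta` (signed change in spliced CDS length).
#' @export
applyEventToTranscript <- function(junction, model, genome) {
  j <- .asJunction(junction)
  ex <- model$exons
  if (j$chrom != model$chrom ||
      j$end < min(IRanges::start(ex)) || j$start > max(IRanges::end(ex))) {
    stop("junction lies outside the footprint of transcript ",
         model$transcript_id)
  }
  novel <- IRanges::IRanges(j$start, j$end)
  introns <- .modelIntrons(model)
  merged <- IRanges::reduce(c(ex, introns[IRanges::overlapsAny(introns, novel)]))
  altered <- IRanges::setdiff(merged, novel)
  altered_seq <- .exonSeq(altered, model$chrom, model$strand, genome)

  cds_span <- IRanges::IRanges(model$cds_start, model$cds_end)
  nt_delta <- sum(IRanges::width(IRanges::intersect(altered, cds_span))) -
    sum(IRanges::width(IRanges::intersect(ex, cds_span)))

  gstart <- if (model$strand == "-") model$cds_end else model$cds_start
  tpos <- .genomicToTx(gstart, altered, model$strand)
  translatable <- !is.na(tpos)
  alt_cds <- NULL
  if (translatable) {
    alt_cds <- Biostrings::subseq(altered_seq, tpos, length(altered_seq))
  }
  list(altered_exons = altered, altered_seq = altered_seq,
       translatable = translatable, alt_cds = alt_cds,
       nt_delta = as.integer(nt_delta))
}

#' Translate an altered coding sequence and flag its consequence
#'
#' Translates the altered CDS (standard genetic code) with every
#' termination codon, including premature ones, marked `*`. The frame
#' status follows the signed nucleotide change (`in_frame` iff
#' `nt_delta %% 3 == 0`); a premature termination codon (PTC) is an
#' in-frame stop strictly upstream of the position aligned with the
#' template's canonical stop. Amino-acid deletion/insertion counts are
#' derived from the longest common prefix and suffix against the wild-type
#' protein, which also locates the affected wild-type residue interval.
#' As a self-check, translating the unaltered template must reproduce the
#' reference protein (no internal stops); a warning is raised otherwise.
#'
#' @param event Result of [applyEventToTranscript()].
#' @param model The template transcript model.
#' @param genome Named `DNAStringSet`.
#' @return A one-row `data.frame`: `transcript_id`, `frame_status`,
#'   `nt_delta`, `aa_deleted`, `aa_inserted`, `ptc_introduced`,
#'   `translatable`, `altered_protein` (through the first stop, `*`-marked),
#'   `wt_protein`, `affected_aa_start`, `affected_aa_end` (wild-type protein
#'   coordinates; `NA` when the protein is unchanged).
#' @export
translateAndFlag <- function(event, model, genome) {
  b <- .cdsTxBounds(model, genome)
  wt_cds_len <- as.integer(b["tend"] - b["tstart"] + 1L)
  txseq <- .transcriptSeq(model, genome)
  wt_aa_full <- .translateNt(Biostrings::subseq(txseq, b["tstart"], b["tend"]))
  wt_protein <- sub("\\*$", "", wt_aa_full)
  if (!endsWith(wt_aa_full, "*") || grepl("\\*", wt_protein)) {
    warning("wild-type self-check failed for transcript ",
            model$transcript_id,
            ": translation does not yield a clean reference protein")
  }

  if (!event$translatable) {
    return(data.frame(
      transcript_id = model$transcript_id, frame_status = NA_character_,
      nt_delta = event$nt_delta, aa_deleted = NA_integer_,
      aa_inserted = NA_integer_, ptc_introduced = NA,
      translatable = FALSE, altered_protein = NA_character_,
      wt_protein = wt_protein,
      affected_aa_start = NA_integer_, affected_aa_end = NA_integer_,
      stringsAsFactors = FALSE))
  }
  if (length(event$alt_cds) < 3L) stop("altered CDS shorter than one codon")

  aa <- .translateNt(event$alt_cds)
  stop_idx <- regexpr("*", aa, fixed = TRUE)
  canonical_stop_nt <- wt_cds_len + event$nt_delta
  if (stop_idx > 0L) {
    ptc <- (3L * stop_idx) < canonical_stop_nt
    alt_marked <- substr(aa, 1L, stop_idx)
  } else {
    ptc <- FALSE  # stop lost; runs into the 3' UTR
    alt_marked <- aa
  }
  alt_protein <- sub("\\*$", "", alt_marked)

  ps <- .commonPrefixSuffix(wt_protein, alt_protein)
  aa_deleted <- nchar(wt_protein) - ps["prefix"] - ps["suffix"]
  aa_inserted <- nchar(alt_protein) - ps["prefix"] - ps["suffix"]
  if (aa_deleted == 0L && aa_inserted == 0L) {
    aff_start <- aff_end <- NA_integer_
  } else if (aa_deleted > 0L) {
    aff_start <- ps["prefix"] + 1L
    aff_end <- nchar(wt_protein) - ps["suffix"]
  } else {
    # pure insertion: the affected site is the flanking residue pair
    aff_start <- max(ps["prefix"], 1L)
    aff_end <- min(ps["prefix"] + 1L, nchar(wt_protein))
  }
  data.frame(
    transcript_id = model$transcript_id,
    frame_status = if (event$nt_delta %% 3L == 0L) "in_frame" else "frameshift",
    nt_delta = event$nt_delta,
    aa_deleted = as.integer(aa_deleted),
    aa_inserted = as.integer(aa_inserted),
    ptc_introduced = ptc,
    translatable = TRUE,
    altered_protein = alt_marked,
    wt_protein = wt_protein,
    affected_aa_start = as.integer(aff_start),
    affected_aa_end = as.integer(aff_end),
    stringsAsFactors = FALSE)
}

#' Assess a consequence report against surfaceome topology
#'
#' Decides whether the predicted protein change affects the extracellular
#' region while leaving the transmembrane (TM) segment intact. Topology
#' segments are defined on one named reference isoform; for any other
#' template they are transferred by locating the reference TM amino-acid
#' sequence in the template's wild-type protein by exact subsequence match
#' (non-assessable when absent). TM integrity requires each TM segment's
#' sequence to be present unchanged in the altered protein; the
#' extracellular test intersects the affected wild-type residue interval
#' with the extracellular segments. The overall verdict passes only for
#' single-pass proteins with an extracellular alteration, intact TM and no
#' premature termination codon.
#'
#' @param report One-row report from [translateAndFlag()].
#' @param topology Per-gene topology, as `.surfaceomeTopology()` builds from
#'   [loadSurfaceome()]: list with `ref_transcript`, `n_tm`, `segments`.
#' @param ref_protein Wild-type protein of the reference isoform (used to
#'   anchor segment coordinates); defaults to the report's own wild-type
#'   protein when the template is the reference isoform.
#' @return The report row with columns `assessable`, `affects_extracellular`,
#'   `tm_intact`, `single_pass` and `pass` appended.
#' @export
assessCandidate <- function(report, topology, ref_protein = NULL) {
  fail <- function(reason, assessable = FALSE) {
    sp <- if (is.null(topology)) NA else topology$n_tm == 1L
    cbind(report,
          data.frame(assessable = assessable, affects_extracellular = NA,
                     tm_intact = NA, single_pass = sp,
                     pass = FALSE, reason = reason, stringsAsFactors = FALSE))
  }
  if (is.null(topology)) return(fail("no surfaceome topology for gene"))
  if (!isTRUE(report$translatable)) return(fail("start codon lost"))

  is_ref <- report$transcript_id == topology$ref_transcript
  if (is.null(ref_protein)) {
    if (!is_ref) stop("ref_protein required when assessing a non-reference template")
    ref_protein <- report$wt_protein
  }
  seg <- topology$segments
  if (max(seg$aa_end) > nchar(ref_protein)) {
    return(fail("topology exceeds reference protein length"))
  }
  offset <- 0L
  if (!identical(report$wt_protein, ref_protein)) {
    tm1 <- seg[seg$kind == "transmembrane", ][1, ]
    tm_seq <- substr(ref_protein, tm1$aa_start, tm1$aa_end)
    pos <- regexpr(tm_seq, report$wt_protein, fixed = TRUE)
    if (pos < 0L) return(fail("topology not transferable to template"))
    offset <- as.integer(pos) - tm1$aa_start
  }
  # clip transferred segments to the template protein; a transmembrane
  # segment that does not survive the transfer intact makes the template
  # non-assessable
  orig_w <- seg$aa_end - seg$aa_start + 1L
  seg$aa_start <- pmax(seg$aa_start + offset, 1L)
  seg$aa_end <- pmin(seg$aa_end + offset, nchar(report$wt_protein))
  new_w <- seg$aa_end - seg$aa_start + 1L
  if (any(seg$kind == "transmembrane" & new_w < orig_w)) {
    return(fail("transmembrane topology not transferable to template"))
  }
  seg <- seg[new_w > 0L, , drop = FALSE]

  alt <- sub("\\*$", "", report$altered_protein)
  tm <- seg[seg$kind == "transmembrane", , drop = FALSE]
  tm_intact <- all(vapply(seq_len(nrow(tm)), function(i) {
    grepl(substr(report$wt_protein, tm$aa_start[i], tm$aa_end[i]), alt,
          fixed = TRUE)
  }, logical(1)))

  ext <- seg[seg$kind == "extracellular", , drop = FALSE]
  affects_ext <- if (is.na(report$affected_aa_start)) FALSE else
    any(report$affected_aa_start <= ext$aa_end &
          report$affected_aa_end >= ext$aa_start)

  single_pass <- topology$n_tm == 1L
  pass <- isTRUE(affects_ext) && isTRUE(tm_intact) &&
    !isTRUE(report$ptc_introduced) && single_pass
  cbind(report,
        data.frame(assessable = TRUE, affects_extracellular = affects_ext,
                   tm_intact = tm_intact, single_pass = single_pass,
                   pass = pass,
                   reason = NA_character_, stringsAsFactors = FALSE))
}

#' Predict protein consequences for candidate junctions
#'
#' For each junction, evaluates every canonical template of its host gene:
#' classifies the splicing pattern, rebuilds the altered transcript,
#' translates it and assesses the result against the gene's surfaceome
#' topology. A candidate is considered to pass the protein-level filter
#' when any of its templates passes; all per-template reports are returned.
#'
#' @param keys Character vector of junction keys.
#' @param gene_ids Host gene per junction (same length as `keys`).
#' @param annotation A [TranscriptAnnotation-class].
#' @param genome Named `DNAStringSet`.
#' @param surfaceome Surfaceome table from [loadSurfaceome()].
#' @return A `DataFrame` with one row per junction x canonical template:
#'   pattern label, translation report and topology verdicts.
#' @export
predictConsequences <- function(keys, gene_ids, annotation, genome,
                                surfaceome) {
  models <- transcriptModels(annotation)
  gene_of <- vapply(models, `[[`, character(1), "gene_id")
  canon <- vapply(models, `[[`, logical(1), "canonical")
  ref_cache <- new.env()

  rows <- list()
  for (i in seq_along(keys)) {
    gid <- gene_ids[i]
    topo <- if (is.na(gid)) NULL else .surfaceomeTopology(surfaceome, gid)
    templates <- models[!is.na(gid) & gene_of == gid & canon &
                          !vapply(models, function(m) is.na(m$cds_start),
                                  logical(1))]
    if (!length(templates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction = keys[i], gene_id = gid, pattern = NA_character_,
        transcript_id = NA_character_, frame_status = NA_character_,
        nt_delta = NA_integer_, aa_deleted = NA_integer_,
        aa_inserted = NA_integer_, ptc_introduced = NA, translatable = NA,
        altered_protein = NA_character_, wt_protein = NA_character_,
        affected_aa_start = NA_integer_, affected_aa_end = NA_integer_,
        assessable = FALSE, affects_extracellular = NA, tm_intact = NA,
        single_pass = NA, pass = FALSE,
        reason = "no canonical coding template", stringsAsFactors = FALSE)
      next
    }
    ref_protein <- NULL
    if (!is.null(topo) && topo$ref_transcript %in% names(models)) {
      if (!is.null(ref_cache[[topo$ref_transcript]])) {
        ref_protein <- ref_cache[[topo$ref_transcript]]
      } else {
        ref_protein <- sub("\\*$", "",
                           .wtProtein(models[[topo$ref_transcript]], genome))
        ref_cache[[topo$ref_transcript]] <- ref_protein
      }
    }
    for (m in templates) {
      pattern <- tryCatch(classifySplicePattern(keys[i], m),
                          error = function(e) NA_character_)
      if (is.na(pattern)) next  # junction outside this template's footprint
      ev <- applyEventToTranscript(keys[i], m, genome)
      rep1 <- suppressWarnings(translateAndFlag(ev, m, genome))
      verdict <- assessCandidate(rep1, topo, ref_protein = ref_protein)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(junction = keys[i], gene_id = gid, pattern = pattern,
                   stringsAsFactors = FALSE),
        verdict)
    }
  }
  if (!length(rows)) {
    return(S4Vectors::DataFrame(junction = character(0)))
  }
  S4Vectors::DataFrame(do.call(rbind, rows))
}
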