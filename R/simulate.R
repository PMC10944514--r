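# ---- synthetic reference ---------------------------------------------------

# Fixed transcript architecture of every simulated gene: six exons carrying a
# 60 nt 5' UTR, a 300-codon CDS (901-903 = stop), and a 90 nt 3' UTR.
# Transcript-space exon spans: 1-120, 121-270, 271-390, 391-480, 481-630,
# 631-1053; CDS spans transcript 61-963. Exons 2-4 code amino acids 21-140,
# comfortably inside the extracellular segment (aa 1-180) of the single-pass
# topology, so in-frame events planted there alter the extracellular region
# while leaving the transmembrane segment (aa 181-203) untouched.
.SIM_EXON_W <- c(120L, 150L, 120L, 90L, 150L, 423L)
.SIM_UTR5 <- 60L
.SIM_UTR3 <- 90L
.SIM_N_AA <- 300L

#' Generate a synthetic reference: annotation, genome and surfaceome
#'
#' Builds a deterministic (seeded) desk-scale reference: multi-exon
#' protein-coding genes on both strands with valid start/stop codons and no
#' internal stop codons, a genome FASTA backing them, and a surfaceome
#' topology table assigning extracellular/transmembrane/intracellular
#' segments (single-pass for all surfaceome genes except the last, which is
#' emitted multi-pass as a screening control). The first gene carries a
#' second canonical isoform (an in-frame skip of its fourth exon) so that
#' multi-template consequence evaluation is exercised.
#'
#' Every gene's CDS is additionally constrained so that a frameshifting
#' deletion planted at the standard position (CDS nucleotide 148, 31 nt)
#' produces an early in-frame stop, guaranteeing that frameshift decoy
#' events carry a premature termination codon; sequences failing the
#' constraint are resampled (up to `max_tries`, then an error is raised).
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_genes Number of genes (>= 4; the default event plan needs 13
#'   surfaceome genes, hence the default of 16).
#' @param surfaceome_fraction Fraction of genes included in the surfaceome.
#' @param intron_range Range of intron lengths to draw from.
#' @param max_tries Resampling cap per gene.
#' @return An object of class `njx_reference`: a list with `annotation`
#'   ([TranscriptAnnotation-class]), `genome` (`DNAStringSet`), `gtf`
#'   (`GRanges` ready for export), `surfaceome` (validated segment table),
#'   `gene_ids`, `multipass_gene` and `seed`.
#' @export
generateReference <- function(seed, n_genes = 16L, surfaceome_fraction = 0.8,
                              intron_range = c(200L, 500L), max_tries = 50L) {
  if (n_genes < 4L) stop("n_genes must be >= 4")
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  aa2codon <- split(names(gc_tab), unname(gc_tab))
  aa2codon[["*"]] <- NULL
  aas <- names(aa2codon)
  gene_ids <- sprintf("GENE%02d", seq_len(n_genes))
  n_surf <- max(1L, round(n_genes * surfaceome_fraction))

  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  revcomp <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  sample_cds <- function() {
    prot <- c("M", sample(aas, .SIM_N_AA - 1L, replace = TRUE))
    codons <- vapply(prot, function(a) sample(aa2codon[[a]], 1L),
                     character(1))
    paste0(paste(codons, collapse = ""), "TAA")
  }
  has_early_ptc <- function(cds, del_from = 148L, del_len = 31L) {
    mut <- paste0(substr(cds, 1L, del_from - 1L),
                  substr(cds, del_from + del_len, nchar(cds)))
    aa <- .translateNt(Biostrings::DNAString(mut))
    st <- regexpr("*", aa, fixed = TRUE)
    st > 0L && st < (del_from %/% 3L + 61L)
  }

  exon_w <- .SIM_EXON_W
  tx_len <- sum(exon_w)
  ex_off <- c(0L, cumsum(exon_w))[seq_along(exon_w)]
  chrom_pieces <- list()
  chrom_cursor <- list()
  gtf_rows <- list()
  surf_rows <- list()
  models_meta <- list()

  for (i in seq_len(n_genes)) {
    tries <- 0L
    repeat {
      cds <- sample_cds()
      if (has_early_ptc(cds)) break
      tries <- tries + 1L
      if (tries >= max_tries) {
        stop("could not generate a CDS meeting the frameshift-stop ",
             "constraint for gene ", gene_ids[i])
      }
    }
    txseq <- paste0(rand_nt(.SIM_UTR5), cds, rand_nt(.SIM_UTR3))
    stopifnot(nchar(txseq) == tx_len)
    ilen <- sample(seq(intron_range[1], intron_range[2]), length(exon_w) - 1L,
                   replace = TRUE)
    strand <- if (i %% 2L == 1L) "+" else "-"
    chrom <- as.character(ceiling(i / 2))

    chunks <- substring(txseq, ex_off + 1L, ex_off + exon_w)
    asm <- character(2L * length(exon_w) - 1L)
    asm[seq(1L, length(asm), 2L)] <- chunks
    asm[seq(2L, length(asm), 2L)] <- vapply(ilen, rand_nt, character(1))
    assembly <- paste(asm, collapse = "")
    G <- nchar(assembly)
    # assembly positions of exon starts
    a_start <- cumsum(c(1L, head(exon_w, -1L) + ilen))
    a_end <- a_start + exon_w - 1L

    if (is.null(chrom_cursor[[chrom]])) {
      chrom_cursor[[chrom]] <- 0L
      chrom_pieces[[chrom]] <- list()
    }
    pad <- if (chrom_cursor[[chrom]] == 0L) 2000L else 3000L
    chrom_pieces[[chrom]] <- c(chrom_pieces[[chrom]], rand_nt(pad))
    chrom_cursor[[chrom]] <- chrom_cursor[[chrom]] + pad
    g0 <- chrom_cursor[[chrom]] + 1L
    seg <- if (strand == "-") revcomp(assembly) else assembly
    chrom_pieces[[chrom]] <- c(chrom_pieces[[chrom]], seg)
    chrom_cursor[[chrom]] <- chrom_cursor[[chrom]] + G

    asm_to_genomic <- function(p) {
      if (strand == "-") g0 + G - p else g0 + p - 1L
    }
    ex_g1 <- asm_to_genomic(if (strand == "-") a_end else a_start)
    ex_g2 <- asm_to_genomic(if (strand == "-") a_start else a_end)
    exons_g <- IRanges::IRanges(ex_g1, ex_g2)  # transcript order
    tx_to_asm <- function(tp) {
      k <- findInterval(tp, ex_off + 1L)
      a_start[k] + (tp - ex_off[k]) - 1L
    }
    cds_tx <- c(.SIM_UTR5 + 1L, .SIM_UTR5 + 3L * .SIM_N_AA + 3L)
    cds_g <- asm_to_genomic(tx_to_asm(cds_tx))
    cds_lo <- min(cds_g); cds_hi <- max(cds_g)

    tx_id <- sprintf("TX%02dA", i)
    sym <- sprintf("SG%02d", i)
    exons_sorted <- IRanges::IRanges(sort(IRanges::start(exons_g)),
                                     sort(IRanges::end(exons_g)))
    add_tx <- function(tx_id, exon_idx) {
      ex <- exons_sorted[sort(exon_idx)]
      cds_ex <- IRanges::intersect(ex, IRanges::IRanges(cds_lo, cds_hi))
      # GFF phase: bases to skip at the start of each CDS piece, in
      # transcript order
      tx_ord <- if (strand == "-") rev(seq_along(cds_ex)) else
        seq_along(cds_ex)
      cum_before <- cumsum(c(0L, IRanges::width(cds_ex)[tx_ord]))[
        seq_along(cds_ex)]
      phase <- integer(length(cds_ex))
      phase[tx_ord] <- (3L - cum_before %% 3L) %% 3L
      list(
        data.frame(chrom = chrom, start = min(IRanges::start(ex)),
                   end = max(IRanges::end(ex)), strand = strand,
                   type = "transcript", gene_id = gene_ids[i],
                   transcript_id = tx_id, gene_name = sym,
                   tag = "canonical", phase = NA_integer_,
                   stringsAsFactors = FALSE),
        data.frame(chrom = chrom, start = IRanges::start(ex),
                   end = IRanges::end(ex), strand = strand, type = "exon",
                   gene_id = gene_ids[i], transcript_id = tx_id,
                   gene_name = sym, tag = NA_character_,
                   phase = NA_integer_, stringsAsFactors = FALSE),
        data.frame(chrom = chrom, start = IRanges::start(cds_ex),
                   end = IRanges::end(cds_ex), strand = strand, type = "CDS",
                   gene_id = gene_ids[i], transcript_id = tx_id,
                   gene_name = sym, tag = NA_character_, phase = phase,
                   stringsAsFactors = FALSE))
    }
    gtf_rows <- c(gtf_rows, add_tx(tx_id, seq_along(exon_w)))
    if (i == 1L) {
      # second canonical isoform: in-frame skip of the fourth exon
      skip_idx <- if (strand == "-") length(exon_w) - 4L + 1L else 4L
      gtf_rows <- c(gtf_rows,
                    add_tx(sprintf("TX%02dB", i),
                           setdiff(seq_along(exon_w), skip_idx)))
    }

    if (i <= n_surf) {
      if (i == n_surf && n_surf >= 2L) {
        seg_df <- data.frame(
          kind = c("extracellular", "transmembrane", "intracellular",
                   "transmembrane", "extracellular"),
          aa_start = c(1L, 101L, 124L, 151L, 174L),
          aa_end = c(100L, 123L, 150L, 173L, 300L))
      } else {
        seg_df <- data.frame(
          kind = c("extracellular", "transmembrane", "intracellular"),
          aa_start = c(1L, 181L, 204L),
          aa_end = c(180L, 203L, 300L))
      }
      surf_rows[[i]] <- data.frame(
        gene_id = gene_ids[i], gene_symbol = sym, ref_transcript = tx_id,
        seg_df, stringsAsFactors = FALSE)
    }
    models_meta[[i]] <- list(gene_id = gene_ids[i], chrom = chrom,
                             strand = strand)
  }

  chrom_strings <- vapply(names(chrom_pieces), function(ch) {
    paste(c(unlist(chrom_pieces[[ch]]), rand_nt(2000L)), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(chrom_strings)
  names(genome) <- names(chrom_pieces)

  gtf_df <- do.call(rbind, gtf_rows)
  gtf <- GenomicRanges::GRanges(
    seqnames = gtf_df$chrom,
    ranges = IRanges::IRanges(gtf_df$start, gtf_df$end),
    strand = gtf_df$strand,
    type = gtf_df$type, gene_id = gtf_df$gene_id,
    transcript_id = gtf_df$transcript_id, gene_name = gtf_df$gene_name,
    tag = gtf_df$tag, phase = gtf_df$phase)
  surfaceome <- loadSurfaceome(do.call(rbind, surf_rows))

  ref <- list(seed = seed, gene_ids = gene_ids, n_surf = n_surf,
              multipass_gene = if (n_surf >= 2L) gene_ids[n_surf] else NA,
              gtf = gtf, genome = genome, surfaceome = surfaceome,
              annotation = loadAnnotation(gtf))
  class(ref) <- "njx_reference"
  ref
}

#' @export
print.njx_reference <- function(x, ...) {
  cat("Synthetic reference:", length(x$gene_ids), "genes (",
      x$n_surf, "surfaceome ) on", length(x$genome), "chromosomes\n")
  invisible(x)
}

#' Write a synthetic reference to disk
#'
#' Emits the dialects the pipeline readers consume: `genome.fa`,
#' `annotation.gtf` and `surfaceome.tsv`.
#'
#' @param reference An `njx_reference` from [generateReference()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeReference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(reference$gtf, file.path(dir, "annotation.gtf"),
                      format = "gtf")
  surf <- reference$surfaceome
  write.table(surf[, setdiff(names(surf), "n_tm")],
              file.path(dir, "surfaceome.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- junction planting helpers ---------------------------------------------

# transcript coordinate of the first CDS base
.cdsT1 <- function(model) {
  gstart <- if (model$strand == "-") model$cds_end else model$cds_start
  .genomicToTx(gstart, model$exons, model$strand)
}

.crypticFromCdsNt <- function(model, nt_from, nt_len) {
  t1 <- .cdsT1(model)
  tpos <- t1 + (nt_from - 1L) + seq_len(nt_len) - 1L
  g <- .txToGenomic(tpos, model$exons, model$strand)
  if (anyNA(g) || max(g) - min(g) + 1L != nt_len) {
    stop("cryptic intron would cross an exon boundary")
  }
  GenomicRanges::GRanges(model$chrom, IRanges::IRanges(min(g), max(g)),
                         strand = model$strand)
}

#' Construct planted junctions on a transcript model
#'
#' Helpers used by the cohort simulator (and useful for building fixtures):
#' `crypticJunction` excises the codons for amino acids `aa_from` to
#' `aa_from + n_aa - 1` as a novel intron within one exon;
#' `altSpliceJunction` shifts the acceptor or donor of the `intron`-th
#' intron (transcript order) by `shift` nucleotides into the adjacent exon;
#' `exonSkipJunction` bridges from the end of the exon preceding `exon`
#' (transcript order) to the start of the exon following it. All
#' coordinates are strand-aware.
#'
#' @param model A transcript model from [loadAnnotation()].
#' @param aa_from,n_aa Amino-acid range to delete.
#' @return A length-1 `GRanges` junction (intron interval).
#' @export
crypticJunction <- function(model, aa_from, n_aa) {
  .crypticFromCdsNt(model, 3L * (aa_from - 1L) + 1L, 3L * n_aa)
}

#' @rdname crypticJunction
#' @param intron Intron index in transcript order.
#' @param side `"acceptor"` (3' shift) or `"donor"` (5' shift).
#' @param shift Shift into the adjacent exon, in nucleotides.
#' @export
altSpliceJunction <- function(model, intron, side = c("acceptor", "donor"),
                              shift = 3L) {
  side <- match.arg(side)
  introns <- .modelIntrons(model)
  n_i <- length(introns)
  gi <- if (model$strand == "-") n_i - intron + 1L else intron
  gs <- IRanges::start(introns)[gi]; ge <- IRanges::end(introns)[gi]
  minus <- model$strand == "-"
  r <- if (side == "acceptor") {
    if (minus) IRanges::IRanges(gs - shift, ge) else
      IRanges::IRanges(gs, ge + shift)
  } else {
    if (minus) IRanges::IRanges(gs, ge + shift) else
      IRanges::IRanges(gs - shift, ge)
  }
  GenomicRanges::GRanges(model$chrom, r, strand = model$strand)
}

#' @rdname crypticJunction
#' @param exon Exon index in transcript order (not first or last).
#' @export
exonSkipJunction <- function(model, exon) {
  n_e <- length(model$exons)
  gi <- if (model$strand == "-") n_e - exon + 1L else exon
  if (gi <= 1L || gi >= n_e) stop("cannot skip a terminal exon")
  GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(IRanges::end(model$exons)[gi - 1L] + 1L,
                     IRanges::start(model$exons)[gi + 1L] - 1L),
    strand = model$strand)
}

# the gi-th (transcript order) annotated intron as a junction
.annotatedIntron <- function(model, intron) {
  introns <- .modelIntrons(model)
  gi <- if (model$strand == "-") length(introns) - intron + 1L else intron
  GenomicRanges::GRanges(model$chrom, introns[gi], strand = model$strand)
}

# ---- cohort designs --------------------------------------------------------

#' Default cohort simulation design
#'
#' The default study conditions: three tumor disease groups (IDHwt, IDH-A,
#' IDH-O) of 20 samples each, 300 pooled normal samples across eight tissue
#' labels, negative-binomial locus depths (mean 600, dispersion size 8;
#' mean 4000 for the highly expressed locus hosting the low-frequency
#' decoy), and log-normal TPM spread around designed gene means (200 for
#' surfaceome genes, 50 otherwise, 2 for the low-expression decoy host).
#'
#' @param n_per_group Tumor samples per disease group.
#' @param n_normal Normal samples.
#' @return A design list consumed by [simulateCohort()].
#' @export
defaultCohortDesign <- function(n_per_group = 20L, n_normal = 300L) {
  list(groups = c(IDHwt = n_per_group, `IDH-A` = n_per_group,
                  `IDH-O` = n_per_group),
       n_normal = n_normal,
       normal_tissues = c("Brain", "Cerebellum", "Lung", "Liver", "Heart",
                          "Kidney", "Muscle", "Skin"),
       depth_mean = 600, depth_size = 8, high_depth_mean = 4000,
       tpm_mean_surfaceome = 200, tpm_mean_other = 50, tpm_mean_low = 2,
       tpm_sd_log = 0.2,
       events = NULL)
}

# The default planted-event plan: five pass-filter events with distinct
# splice patterns plus one decoy per failure class, each decoy constructed
# to fail at exactly one cascade stage.
.defaultEventPlan <- function(reference) {
  n_surf <- reference$n_surf
  if (length(reference$gene_ids) < 13L || n_surf < 13L) {
    stop("the default event plan needs at least 13 surfaceome genes; ",
         "generate the reference with n_genes >= 16, ",
         "surfaceome_fraction >= 0.8")
  }
  gid <- reference$gene_ids
  plan <- data.frame(
    event_id = sprintf("EV%02d", 1:13),
    gene_id = gid[c(1:12, n_surf)],
    class = c("none", "none", "none", "none", "none",
              "rare", "low_frequency", "normal_shared", "frameshift_ptc",
              "intracellular", "annotated", "low_expression", "multi_pass"),
    pattern = c("cryptic_intron", "cryptic_intron", "alt_3ss", "alt_5ss",
                "exon_skip", "alt_3ss", "alt_3ss", "alt_3ss",
                "cryptic_intron", "cryptic_intron", "annotated",
                "cryptic_intron", "cryptic_intron"),
    frequency = c(0.06, 0.06, 0.05, 0.05, 0.08,
                  0.05, 0.005, 0.05, 0.06, 0.06, NA, 0.06, 0.06),
    p_normal = c(0, 0, 0, 0, 0, 0, 0, 0.05, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  plan$p_groups <- list(
    c(0.30, 0.40, 0.45), c(0.20, 0.35, 0.30), c(0.40, 0.20, 0.25),
    c(0.25, 0.25, 0.40), c(0.35, 0.15, 0.20),
    c(0.05, 0.05, 0.05), c(0.40, 0.40, 0.40), c(0.30, 0.30, 0.30),
    c(0.30, 0.30, 0.30), c(0.30, 0.30, 0.30), c(0, 0, 0),
    c(0.30, 0.30, 0.30), c(0.30, 0.30, 0.30))
  plan
}

.EXPECTED_FAIL_STAGE <- c(
  none = NA_character_, annotated = "non_annotated",
  low_expression = "expression_surfaceome", normal_shared = "tumor_specific",
  rare = "shared", low_frequency = "shared",
  intracellular = "extracellular", frameshift_ptc = "protein",
  multi_pass = "protein")

# junction GRanges for one plan row
.planJunction <- function(row, reference) {
  m <- transcriptModels(reference$annotation)[[
    paste0(sub("GENE", "TX", row$gene_id), "A")]]
  if (is.null(m)) stop("no transcript model for gene ", row$gene_id)
  switch(row$pattern,
         cryptic_intron = switch(row$class,
                                 frameshift_ptc = .crypticFromCdsNt(m, 148L, 31L),
                                 intracellular = crypticJunction(m, 210L, 20L),
                                 crypticJunction(m, 30L, 10L)),
         alt_3ss = altSpliceJunction(m, 2L, "acceptor", 3L),
         alt_5ss = altSpliceJunction(m, 3L, "donor", 3L),
         exon_skip = exonSkipJunction(m, 4L),
         annotated = .annotatedIntron(m, 2L),
         stop("unknown pattern ", row$pattern))
}

# ---- count machinery -------------------------------------------------------

# Generate per-sample junction tables: annotated junction counts drawn from
# a negative binomial, planted events switched on in designated samples with
# counts tied to the realized count of their dominant overlapping junction
# so that designed supportive-read frequencies are met by construction.
.generateCounts <- function(reference, manifest, plan, on, design) {
  ann <- reference$annotation
  R <- refJunctions(ann)
  R_keys <- junctionKeyFromRanges(R)
  genesR <- geneFootprints(ann)
  g_hit <- GenomicRanges::findOverlaps(R, genesR, ignore.strand = TRUE,
                                       select = "first")
  gene_of_R <- genesR$gene_id[g_hit]

  mu <- rep(design$depth_mean, length(R))
  high <- plan$gene_id[plan$class == "low_frequency"]
  mu[gene_of_R %in% high] <- design$high_depth_mean

  n_s <- nrow(manifest)
  is_tumor <- manifest$cohort == "tumor"
  A <- matrix(rnbinom(length(R) * n_s, mu = rep(mu, n_s),
                      size = design$depth_size),
              nrow = length(R), dimnames = list(R_keys, manifest$sample_id))
  tumor_tot <- rowSums(A[, is_tumor, drop = FALSE])

  ev_gr <- lapply(seq_len(nrow(plan)), function(e)
    .planJunction(plan[e, ], reference))
  ev_keys <- vapply(ev_gr, junctionKeyFromRanges, character(1))
  E <- matrix(0L, nrow(plan), n_s,
              dimnames = list(plan$event_id, manifest$sample_id))
  q_floor <- 0.0102 / (1 - 0.0102)  # frequency guard with 2% headroom

  for (e in seq_len(nrow(plan))) {
    if (plan$class[e] == "annotated") next
    s_on <- which(on[e, ])
    if (!length(s_on)) next
    ov <- GenomicRanges::findOverlaps(ev_gr[[e]], R, ignore.strand = FALSE)
    f <- plan$frequency[e]
    if (!length(ov)) {
      # no overlapping junction: depth is the event's own count
      tum <- is_tumor[s_on]
      base <- ifelse(tum, 40L, 10L)
      E[e, s_on] <- base + rnbinom(length(s_on),
                                   mu = ifelse(tum, 20, 5), size = 10)
    } else {
      cand <- S4Vectors::subjectHits(ov)
      dom <- cand[order(-tumor_tot[cand], R_keys[cand])][1]
      d <- A[dom, s_on]
      if (plan$class[e] == "low_frequency") {
        E[e, s_on] <- as.integer(floor(f / (1 - f) * d))
      } else {
        mc <- ifelse(is_tumor[s_on], 10L, 2L)
        md <- ifelse(is_tumor[s_on], 20L, 10L)
        E[e, s_on] <- as.integer(pmax(ceiling(f / (1 - f) * d), mc, md - d,
                                      ceiling(q_floor * d)))
      }
    }
  }

  tables <- lapply(seq_len(n_s), function(j) {
    keep_a <- A[, j] > 0L
    keep_e <- E[, j] > 0L
    gr <- R[keep_a]
    gr$count <- unname(A[keep_a, j])
    if (any(keep_e)) {
      eg <- suppressWarnings(do.call(c, unname(ev_gr[keep_e])))
      eg$count <- unname(E[keep_e, j])
      gr <- suppressWarnings(c(gr, eg))
    }
    gr
  })
  names(tables) <- manifest$sample_id
  list(tables = tables, event_keys = setNames(ev_keys, plan$event_id))
}

# exact-count positivity assignment: round(p * n) members of each block
.assignOn <- function(plan, manifest, groups, normal_p_col = "p_normal") {
  on <- matrix(FALSE, nrow(plan), nrow(manifest),
               dimnames = list(plan$event_id, manifest$sample_id))
  for (e in seq_len(nrow(plan))) {
    if (plan$class[e] == "annotated") next
    pg <- plan$p_groups[[e]]
    for (gi in seq_along(groups)) {
      ids <- manifest$sample_id[manifest$cohort == "tumor" &
                                  manifest$group == names(groups)[gi]]
      n_on <- round(pg[gi] * length(ids))
      if (n_on > 0L) on[e, sample(ids, n_on)] <- TRUE
    }
    nids <- manifest$sample_id[manifest$cohort == "normal"]
    n_on <- round(plan[[normal_p_col]][e] * length(nids))
    if (n_on > 0L) on[e, sample(nids, n_on)] <- TRUE
  }
  on
}

#' Simulate a cohort with planted splice events
#'
#' Generates a complete desk-scale cohort over a synthetic reference:
#' per-sample junction tables (annotated junctions at negative-binomial
#' locus depths plus planted events), a matched TPM matrix, a sample
#' manifest and a machine-readable ground truth. Each planted event is
#' switched on in exactly `round(p * n)` samples of each group (drawn
#' without replacement), so realized positive-sample rates equal the
#' designed probabilities up to rounding; "on" counts are derived from the
#' realized count of the event's dominant overlapping junction so that
#' designed supportive-read frequencies hold by construction, with floors
#' guaranteeing that pass-class events clear every positivity threshold
#' and that decoy classes miss their designated one.
#'
#' @param seed Integer seed.
#' @param reference An `njx_reference` from [generateReference()].
#' @param design Design list, see [defaultCohortDesign()]. `design$events`
#'   may carry a custom plan (same columns as the default).
#' @return An object of class `njx_cohort`: list with `tables` (named list
#'   of junction `GRanges` with counts), `manifest`, `tpm`, `truth`
#'   (planted events with expected screening outcome), `design` and
#'   `reference`.
#' @export
simulateCohort <- function(seed, reference, design = defaultCohortDesign()) {
  set.seed(seed)
  plan <- design$events %||% .defaultEventPlan(reference)
  probs <- c(unlist(plan$p_groups), plan$p_normal)
  if (any(probs < 0 | probs > 1)) {
    stop("design probabilities must lie in [0, 1]")
  }
  groups <- design$groups
  n_t <- sum(groups)
  tumor_ids <- sprintf("TS%03d", seq_len(n_t))
  group_lab <- rep(names(groups), groups)
  normal_ids <- sprintf("NS%03d", seq_len(design$n_normal))
  manifest <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    cohort = c(rep("tumor", n_t), rep("normal", design$n_normal)),
    group = c(group_lab, rep_len(design$normal_tissues, design$n_normal)),
    purity = c(runif(n_t, 0.70, 0.98), rep(NA_real_, design$n_normal)),
    vaf = c(ifelse(group_lab == "IDH-A", runif(n_t, 0.30, 0.50), NA_real_),
            rep(NA_real_, design$n_normal)),
    patient_id = c(tumor_ids, normal_ids),
    piece_id = NA_character_, timepoint = NA_character_,
    stringsAsFactors = FALSE)

  on <- .assignOn(plan, manifest, groups)
  cnt <- .generateCounts(reference, manifest, plan, on, design)

  surf_genes <- unique(reference$surfaceome$gene_id)
  low_genes <- plan$gene_id[plan$class == "low_expression"]
  tpm_mean <- ifelse(reference$gene_ids %in% low_genes, design$tpm_mean_low,
                     ifelse(reference$gene_ids %in% surf_genes,
                            design$tpm_mean_surfaceome,
                            design$tpm_mean_other))
  sdl <- design$tpm_sd_log
  tpm <- matrix(
    rep(tpm_mean, nrow(manifest)) *
      exp(rnorm(length(tpm_mean) * nrow(manifest), 0, sdl) - sdl^2 / 2),
    nrow = length(tpm_mean),
    dimnames = list(reference$gene_ids, manifest$sample_id))

  truth <- data.frame(
    event_id = plan$event_id,
    junction = unname(cnt$event_keys),
    gene_id = plan$gene_id,
    class = plan$class,
    pattern = plan$pattern,
    frequency = plan$frequency,
    p_groups = vapply(plan$p_groups, paste, character(1), collapse = ","),
    p_normal = plan$p_normal,
    n_on = rowSums(on),
    expected_final_pass = plan$class == "none",
    expected_fail_stage = unname(.EXPECTED_FAIL_STAGE[plan$class]),
    stringsAsFactors = FALSE)

  out <- list(tables = cnt$tables, manifest = manifest, tpm = tpm,
              truth = truth, design = design, reference = reference,
              seed = seed)
  class(out) <- "njx_cohort"
  out
}

#' @export
print.njx_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$manifest$cohort == "tumor"), "tumor /",
      sum(x$manifest$cohort == "normal"), "normal samples;",
      nrow(x$truth), "planted events (",
      sum(x$truth$expected_final_pass), "expected to pass )\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-sample `<sample>.SJ.out.tab` files, `manifest.tsv`, `tpm.tsv`
#' and the ground truth as `truth.json`.
#'
#' @param cohort An `njx_cohort` from [simulateCohort()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$tables)) {
    writeSJTab(cohort$tables[[s]], file.path(dir, paste0(s, ".SJ.out.tab")))
  }
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  tpm <- data.frame(gene_id = rownames(cohort$tpm), cohort$tpm,
                    check.names = FALSE)
  write.table(tpm, file.path(dir, "tpm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(dir)
}

# ---- spatial and longitudinal cohorts --------------------------------------

#' Default multi-region (spatial) design
#'
#' Six tumors (two per disease group) with 4-8 spatially mapped pieces
#' each; the five pass-class events are planted at piece-positive fractions
#' spanning absent, focal, majority and tumor-wide (100%) patterns.
#'
#' @return A design list for [simulateSpatialCohort()].
#' @export
defaultSpatialDesign <- function() {
  tumors <- data.frame(
    tumor_id = sprintf("T%02d", 1:6),
    group = c("IDHwt", "IDHwt", "IDH-A", "IDH-A", "IDH-O", "IDH-O"),
    n_pieces = c(4L, 6L, 7L, 5L, 8L, 6L),
    stringsAsFactors = FALSE)
  events <- sprintf("EV%02d", 1:5)
  fractions <- matrix(c(
    1.00, 0.50, 3 / 7, 0.00, 1.00, 0.50,
    0.75, 0.00, 2 / 7, 0.40, 0.25, 1.00,
    0.00, 1 / 3, 1.00, 0.20, 0.50, 1 / 6,
    0.50, 0.50, 0.00, 1.00, 0.125, 0.50,
    0.25, 1 / 6, 4 / 7, 0.60, 0.00, 1 / 3),
    nrow = 5, byrow = TRUE, dimnames = list(events, tumors$tumor_id))
  list(tumors = tumors, events = events, fractions = fractions,
       depth_mean = 600, depth_size = 8, high_depth_mean = 4000)
}

#' Simulate a spatially mapped multi-region cohort
#'
#' Generates per-piece junction tables for multi-region tumors, planting
#' each tracked event in exactly `round(fraction * n_pieces)` pieces of
#' each tumor. Piece purity/VAF values are drawn to pass the spatial
#' gating rule.
#'
#' @param seed Integer seed.
#' @param reference An `njx_reference`.
#' @param design See [defaultSpatialDesign()].
#' @return List with `tables`, `manifest`, `event_keys` (event id ->
#'   junction key) and `truth` (designed and realized per-tumor fractions).
#' @export
simulateSpatialCohort <- function(seed, reference,
                                  design = defaultSpatialDesign()) {
  set.seed(seed)
  plan <- .defaultEventPlan(reference)
  plan <- plan[plan$event_id %in% design$events, , drop = FALSE]
  tu <- design$tumors
  manifest <- do.call(rbind, lapply(seq_len(nrow(tu)), function(i) {
    n <- tu$n_pieces[i]
    idha <- tu$group[i] == "IDH-A"
    data.frame(
      sample_id = sprintf("%sP%d", tu$tumor_id[i], seq_len(n)),
      cohort = "tumor", group = tu$group[i],
      purity = if (idha) NA_real_ else runif(n, 0.55, 0.95),
      vaf = if (idha) runif(n, 0.30, 0.45) else NA_real_,
      patient_id = tu$tumor_id[i],
      piece_id = sprintf("P%d", seq_len(n)),
      timepoint = NA_character_, stringsAsFactors = FALSE)
  }))
  on <- matrix(FALSE, nrow(plan), nrow(manifest),
               dimnames = list(plan$event_id, manifest$sample_id))
  n_pos <- matrix(0L, nrow(plan), nrow(tu),
                  dimnames = list(plan$event_id, tu$tumor_id))
  for (e in seq_len(nrow(plan))) {
    for (i in seq_len(nrow(tu))) {
      ids <- manifest$sample_id[manifest$patient_id == tu$tumor_id[i]]
      k <- round(design$fractions[plan$event_id[e], tu$tumor_id[i]] *
                   length(ids))
      n_pos[e, i] <- as.integer(k)
      if (k > 0L) on[e, sample(ids, k)] <- TRUE
    }
  }
  cnt <- .generateCounts(reference, manifest, plan, on, design)
  truth <- expand.grid(event = plan$event_id, tumor_id = tu$tumor_id,
                       stringsAsFactors = FALSE)
  truth$n_pieces <- tu$n_pieces[match(truth$tumor_id, tu$tumor_id)]
  truth$n_positive <- mapply(function(e, t) n_pos[e, t],
                             truth$event, truth$tumor_id)
  truth$fraction <- truth$n_positive / truth$n_pieces
  truth$tumor_wide <- truth$n_positive == truth$n_pieces
  list(tables = cnt$tables, manifest = manifest,
       event_keys = cnt$event_keys, truth = truth)
}

#' Default longitudinal (primary/recurrent) design
#'
#' Six patients with paired primary and recurrent tumors (two with
#' multi-piece timepoints); the five pass-class events are planted so that
#' the four longitudinal statuses (shared, primary-only, recurrent-only,
#' absent) and the inclusive 50% piece-majority boundary are all realized.
#'
#' @return A design list for [simulateLongitudinalCohort()].
#' @export
defaultLongitudinalDesign <- function() {
  patients <- data.frame(
    patient_id = sprintf("L%02d", 1:6),
    group = c("IDHwt", "IDHwt", "IDH-A", "IDH-O", "IDH-O", "IDHwt"),
    n_primary = c(1L, 1L, 4L, 3L, 1L, 1L),
    n_recurrent = c(1L, 1L, 3L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
  events <- sprintf("EV%02d", 1:5)
  primary <- matrix(c(
    1, 1, 0.5, 1, 0, 0,
    0, 1, 0.25, 2 / 3, 1, 0,
    1, 0, 1, 0, 1, 1,
    0, 0, 0.75, 1 / 3, 0, 1,
    1, 1, 0, 0, 0, 0),
    nrow = 5, byrow = TRUE, dimnames = list(events, patients$patient_id))
  recurrent <- matrix(c(
    1, 0, 0, 1, 0, 1,
    1, 1, 2 / 3, 1 / 3, 0, 0,
    0, 0, 1, 1, 1, 0,
    0, 1, 1 / 3, 0, 0, 1,
    0, 0, 2 / 3, 1, 0, 0),
    nrow = 5, byrow = TRUE, dimnames = list(events, patients$patient_id))
  list(patients = patients, events = events,
       primary = primary, recurrent = recurrent,
       depth_mean = 600, depth_size = 8, high_depth_mean = 4000)
}

#' Simulate a longitudinal primary/recurrent cohort
#'
#' @param seed Integer seed.
#' @param reference An `njx_reference`.
#' @param design See [defaultLongitudinalDesign()].
#' @return List with `tables`, `manifest`, `event_keys` and `truth`
#'   (expected status per patient x event under the 50% piece-majority
#'   rule).
#' @export
simulateLongitudinalCohort <- function(seed, reference,
                                       design = defaultLongitudinalDesign()) {
  set.seed(seed)
  plan <- .defaultEventPlan(reference)
  plan <- plan[plan$event_id %in% design$events, , drop = FALSE]
  pa <- design$patients
  manifest <- do.call(rbind, lapply(seq_len(nrow(pa)), function(i) {
    do.call(rbind, lapply(c("primary", "recurrent"), function(tp) {
      n <- if (tp == "primary") pa$n_primary[i] else pa$n_recurrent[i]
      data.frame(
        sample_id = sprintf("%s%s%d", pa$patient_id[i],
                            toupper(substr(tp, 1, 3)), seq_len(n)),
        cohort = "tumor", group = pa$group[i],
        purity = runif(n, 0.65, 0.95), vaf = NA_real_,
        patient_id = pa$patient_id[i],
        piece_id = sprintf("%s%d", substr(tp, 1, 1), seq_len(n)),
        timepoint = tp, stringsAsFactors = FALSE)
    }))
  }))
  on <- matrix(FALSE, nrow(plan), nrow(manifest),
               dimnames = list(plan$event_id, manifest$sample_id))
  frac_real <- array(0, c(nrow(plan), nrow(pa), 2),
                     dimnames = list(plan$event_id, pa$patient_id,
                                     c("primary", "recurrent")))
  for (e in seq_len(nrow(plan))) {
    for (i in seq_len(nrow(pa))) {
      for (tp in c("primary", "recurrent")) {
        ids <- manifest$sample_id[manifest$patient_id == pa$patient_id[i] &
                                    manifest$timepoint == tp]
        fr <- design[[tp]][plan$event_id[e], pa$patient_id[i]]
        k <- round(fr * length(ids))
        frac_real[e, i, tp] <- k / length(ids)
        if (k > 0L) on[e, sample(ids, k)] <- TRUE
      }
    }
  }
  cnt <- .generateCounts(reference, manifest, plan, on, design)
  truth <- expand.grid(event = plan$event_id, patient_id = pa$patient_id,
                       stringsAsFactors = FALSE)
  pp <- mapply(function(e, p) frac_real[e, p, "primary"] >= 0.5,
               truth$event, truth$patient_id)
  rp <- mapply(function(e, p) frac_real[e, p, "recurrent"] >= 0.5,
               truth$event, truth$patient_id)
  truth$primary_positive <- pp
  truth$recurrent_positive <- rp
  truth$status <- ifelse(pp & rp, "shared",
                         ifelse(pp, "primary_only",
                                ifelse(rp, "recurrent_only", "absent")))
  list(tables = cnt$tables, manifest = manifest,
       event_keys = cnt$event_keys, truth = truth)
}

#' Event-level positivity matrix
#'
#' Extracts the positivity calls of tracked events (screened candidates
#' plus any user-supplied junction list) as an events x samples logical
#' matrix suitable for [spatialSummary()] and [longitudinalClassify()].
#'
#' @param calls A [PositivityCalls-class].
#' @param event_keys Named character vector, event id -> junction key.
#' @return Logical matrix with event ids as rownames. Events absent from
#'   the call matrix are reported negative everywhere.
#' @export
eventPositivity <- function(calls, event_keys) {
  pos <- isPositive(calls)
  out <- matrix(FALSE, length(event_keys), ncol(pos),
                dimnames = list(names(event_keys), colnames(pos)))
  hit <- event_keys %in% rownames(pos)
  out[hit, ] <- pos[event_keys[hit], , drop = FALSE]
  out
}
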