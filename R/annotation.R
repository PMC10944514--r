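#' Load transcript annotation from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based, inclusive coordinates; `exon` and
#' `CDS` features carrying `gene_id`/`transcript_id` attributes) into
#' transcript models, derives the reference exon-exon junction set, and
#' records gene footprints.
#'
#' For every transcript the reference junctions are the intron intervals
#' between consecutive exons in genomic order, `(exon_i_end + 1,
#' exon_(i+1)_start - 1)`; the reference set is the union over all
#' transcripts. Single-exon transcripts contribute no junctions. A gene's
#' footprint is the interval from the minimum start to the maximum end over
#' all its transcript exons, the "any portion of the genomic coordinates"
#' interval used when junctions are assigned to surfaceome genes.
#'
#' A transcript is flagged canonical when its features carry a `tag`
#' attribute containing `"canonical"`; when the GTF has no `tag` attribute,
#' every transcript with a CDS is treated as canonical. Canonical
#' transcripts serve as the templates for in-silico translation.
#'
#' @param gtf Path to a GTF file, or a `GRanges` as returned by
#'   `rtracklayer::import()`.
#' @return A [TranscriptAnnotation-class] object. Each transcript model is a
#'   list with elements `transcript_id`, `gene_id`, `gene_symbol`, `chrom`,
#'   `strand`, `exons` (`IRanges`, sorted by genomic start), `cds_start`,
#'   `cds_end` (genomic CDS bounds, `NA` for non-coding) and `canonical`.
#' @export
loadAnnotation <- function(gtf) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf, format = "gtf") else gtf
  GenomeInfoDb::seqlevels(gr) <- .normChrom(GenomeInfoDb::seqlevels(gr))
  mc <- S4Vectors::mcols(gr)
  has_tag <- "tag" %in% names(mc)
  has_name <- "gene_name" %in% names(mc)

  ex <- gr[mc$type == "exon"]
  if (!length(ex)) stop("GTF contains no exon features")
  exm <- S4Vectors::mcols(ex)
  tx_ids <- as.character(exm$transcript_id)
  if (anyNA(tx_ids)) stop("exon features must carry transcript_id attributes")
  ex_by_tx <- split(seq_along(ex), tx_ids)

  cds <- gr[mc$type == "CDS"]
  cds_by_tx <- split(seq_along(cds), as.character(S4Vectors::mcols(cds)$transcript_id))

  canon_tags <- character(0)
  if (has_tag) {
    tag <- as.character(mc$tag)
    canon_tags <- unique(as.character(mc$transcript_id[
      !is.na(tag) & grepl("canonical", tag)]))
  }

  models <- lapply(names(ex_by_tx), function(tx) {
    idx <- ex_by_tx[[tx]]
    e <- ex[idx]
    o <- order(GenomicRanges::start(e))
    e <- e[o]
    st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    if (length(e) > 1L && any(st[-1] <= en[-length(en)])) {
      stop("overlapping exons within transcript ", tx)
    }
    ci <- cds_by_tx[[tx]]
    cds_start <- cds_end <- NA_integer_
    if (!is.null(ci) && length(ci)) {
      cds_start <- min(GenomicRanges::start(cds[ci]))
      cds_end <- max(GenomicRanges::end(cds[ci]))
    }
    gene_id <- as.character(S4Vectors::mcols(e)$gene_id[1])
    list(transcript_id = tx,
         gene_id = gene_id,
         gene_symbol = if (has_name && !is.na(S4Vectors::mcols(e)$gene_name[1]))
           as.character(S4Vectors::mcols(e)$gene_name[1]) else gene_id,
         chrom = as.character(GenomicRanges::seqnames(e))[1],
         strand = as.character(GenomicRanges::strand(e))[1],
         exons = IRanges::IRanges(st, en),
         cds_start = cds_start, cds_end = cds_end,
         canonical = if (has_tag) tx %in% canon_tags else !is.na(cds_start))
  })
  names(models) <- names(ex_by_tx)

  jx <- lapply(models, function(m) {
    n <- length(m$exons)
    if (n < 2L) return(NULL)
    GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(IRanges::end(m$exons)[-n] + 1L,
                                IRanges::start(m$exons)[-1] - 1L),
      strand = m$strand)
  })
  jx <- jx[!vapply(jx, is.null, logical(1))]
  ref <- if (length(jx)) suppressWarnings(unique(do.call(c, unname(jx)))) else
    GenomicRanges::GRanges()

  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  genes <- GenomicRanges::GRanges(
    seqnames = vapply(by_gene, function(ms) ms[[1]]$chrom, character(1)),
    ranges = IRanges::IRanges(
      vapply(by_gene, function(ms)
        min(vapply(ms, function(m) min(IRanges::start(m$exons)), integer(1))),
        integer(1)),
      vapply(by_gene, function(ms)
        max(vapply(ms, function(m) max(IRanges::end(m$exons)), integer(1))),
        integer(1))),
    strand = vapply(by_gene, function(ms) {
      s <- unique(vapply(ms, `[[`, character(1), "strand"))
      if (length(s) == 1L) s else "*"
    }, character(1)),
    gene_id = names(by_gene),
    gene_symbol = vapply(by_gene, function(ms) ms[[1]]$gene_symbol,
                         character(1)))
  names(genes) <- names(by_gene)

  new("TranscriptAnnotation", models = models, refJunctions = ref,
      genes = genes)
}

#' @rdname TranscriptAnnotation-class
#' @export
setMethod("transcriptModels", "TranscriptAnnotation", function(x) x@models)

#' @rdname TranscriptAnnotation-class
#' @export
setMethod("refJunctions", "TranscriptAnnotation", function(x) x@refJunctions)

#' @rdname TranscriptAnnotation-class
#' @export
setMethod("geneFootprints", "TranscriptAnnotation", function(x) x@genes)

setMethod("show", "TranscriptAnnotation", function(object) {
  cat("TranscriptAnnotation:", length(object@models), "transcripts,",
      length(object@genes), "genes,",
      length(object@refJunctions), "reference junctions\n")
})

# ---- transcript coordinate machinery ---------------------------------------

# Intron intervals of a model (genomic order).
.modelIntrons <- function(model) {
  n <- length(model$exons)
  if (n < 2L) return(IRanges::IRanges())
  IRanges::IRanges(IRanges::end(model$exons)[-n] + 1L,
                   IRanges::start(model$exons)[-1] - 1L)
}

# Transcript coordinate (1 = 5' end of the mature transcript) of genomic
# positions lying in the given exon set; NA when a position is intronic.
.genomicToTx <- function(gpos, exons, strand) {
  st <- IRanges::start(exons); en <- IRanges::end(exons); w <- IRanges::width(exons)
  cum <- cumsum(w)
  total <- sum(w)
  vapply(gpos, function(g) {
    k <- which(g >= st & g <= en)
    if (!length(k)) return(NA_integer_)
    if (strand == "-") {
      after <- if (k == length(w)) 0L else sum(w[(k + 1L):length(w)])
      as.integer(after + (en[k] - g + 1L))
    } else {
      before <- if (k == 1L) 0L else cum[k - 1L]
      as.integer(before + (g - st[k] + 1L))
    }
  }, integer(1))
}

# Genomic position of transcript coordinates (inverse of .genomicToTx).
.txToGenomic <- function(tpos, exons, strand) {
  st <- IRanges::start(exons); en <- IRanges::end(exons); w <- IRanges::width(exons)
  nex <- length(w)
  vapply(tpos, function(tp) {
    if (strand == "-") {
      after <- c(rev(cumsum(rev(w)))[-1], 0L)
      k <- which(tp > after & tp <= after + w)
      if (!length(k)) return(NA_integer_)
      as.integer(en[k] - (tp - after[k]) + 1L)
    } else {
      before <- c(0L, cumsum(w)[-nex])
      k <- which(tp > before & tp <= before + w)
      if (!length(k)) return(NA_integer_)
      as.integer(st[k] + (tp - before[k]) - 1L)
    }
  }, integer(1))
}

# Mature transcript sequence (DNAString) of an exon set on the genome.
.exonSeq <- function(exons, chrom, strand, genome) {
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  chunks <- lapply(seq_along(exons), function(i) {
    Biostrings::subseq(genome[[chrom]], IRanges::start(exons)[i],
                       IRanges::end(exons)[i])
  })
  s <- do.call(Biostrings::xscat, chunks)
  if (strand == "-") Biostrings::reverseComplement(s) else s
}

.transcriptSeq <- function(model, genome) {
  .exonSeq(model$exons, model$chrom, model$strand, genome)
}

# CDS bounds in transcript coordinates. GTFs differ on whether the stop
# codon is part of the CDS features; when the annotated span does not end in
# a stop codon the span is extended by 3 nt in transcript space (clipped to
# the transcript) so that downstream bookkeeping always includes the stop.
.cdsTxBounds <- function(model, genome) {
  if (is.na(model$cds_start)) stop("transcript ", model$transcript_id,
                                   " has no annotated CDS")
  tp <- .genomicToTx(c(model$cds_start, model$cds_end), model$exons,
                     model$strand)
  if (anyNA(tp)) stop("CDS bounds of ", model$transcript_id,
                      " do not fall in its exons")
  tstart <- min(tp); tend <- max(tp)
  txseq <- .transcriptSeq(model, genome)
  aa <- .translateNt(Biostrings::subseq(txseq, tstart, tend))
  if (!endsWith(aa, "*") && tend + 3L <= length(txseq)) tend <- tend + 3L
  c(tstart = tstart, tend = tend)
}

# Standard-code translation of a DNAString; incomplete trailing codon
# dropped; stops rendered '*'.
.translateNt <- function(nt) {
  n <- 3L * (length(nt) %/% 3L)
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::subseq(nt, 1L, n),
                                     no.init.codon = TRUE))
}

# Wild-type protein of a canonical template, including the trailing '*'.
.wtProtein <- function(model, genome) {
  b <- .cdsTxBounds(model, genome)
  txseq <- .transcriptSeq(model, genome)
  .translateNt(Biostrings::subseq(txseq, b["tstart"], b["tend"]))
}
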