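# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A tiny hand-enumerable annotation: three genes, seven transcripts.
#   GENEA (+, chr1): TA1 exons 100-200, 301-400, 501-600 -> introns
#     (201,300), (401,500); TA2 exons 100-200, 501-600 -> intron (201,500);
#     TA3 single exon 100-600 (no junctions)
#   GENEB (-, chr1): TB1 exons 1000-1100, 1201-1300 -> intron (1101,1200);
#     TB2 exons 1000-1100, 1251-1300 -> intron (1101,1250)
#   GENEC (+, chr2): TC1 exons 50-150, 250-350 -> intron (151,249);
#     TC2 exons 50-150, 250-350 (same junction, counted once)
toy_gtf <- function() {
  row <- function(chrom, start, end, strand, type, gid, tid) {
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               type = type, gene_id = gid, transcript_id = tid,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    row("1", 100, 200, "+", "exon", "GENEA", "TA1"),
    row("1", 301, 400, "+", "exon", "GENEA", "TA1"),
    row("1", 501, 600, "+", "exon", "GENEA", "TA1"),
    row("1", 100, 200, "+", "exon", "GENEA", "TA2"),
    row("1", 501, 600, "+", "exon", "GENEA", "TA2"),
    row("1", 100, 600, "+", "exon", "GENEA", "TA3"),
    row("1", 1000, 1100, "-", "exon", "GENEB", "TB1"),
    row("1", 1201, 1300, "-", "exon", "GENEB", "TB1"),
    row("1", 1000, 1100, "-", "exon", "GENEB", "TB2"),
    row("1", 1251, 1300, "-", "exon", "GENEB", "TB2"),
    row("2", 50, 150, "+", "exon", "GENEC", "TC1"),
    row("2", 250, 350, "+", "exon", "GENEC", "TC1"),
    row("2", 50, 150, "+", "exon", "GENEC", "TC2"),
    row("2", 250, 350, "+", "exon", "GENEC", "TC2"))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, type = df$type,
                         gene_id = df$gene_id, transcript_id = df$transcript_id)
}

# Hand-enumerated reference junctions of toy_gtf()
toy_ref_junctions <- function() {
  GenomicRanges::GRanges(
    c("1", "1", "1", "1", "1", "2"),
    IRanges::IRanges(c(201, 401, 201, 1101, 1101, 151),
                     c(300, 500, 500, 1200, 1250, 249)),
    strand = c("+", "+", "+", "-", "-", "+"))
}

# Write a GRanges junction table as an SJ.out.tab file and return the path.
write_sj_fixture <- function(gr, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".SJ.out.tab")
  neojx::writeSJTab(gr, path)
  path
}

sj_granges <- function(chrom, start, end, strand, count) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, count = count)
}

simple_manifest <- function(tumor_ids, normal_ids = character(0),
                            groups = "G1") {
  data.frame(
    sample_id = c(tumor_ids, normal_ids),
    cohort = c(rep("tumor", length(tumor_ids)),
               rep("normal", length(normal_ids))),
    group = c(rep_len(groups, length(tumor_ids)),
              rep("Tissue", length(normal_ids))),
    purity = c(rep(0.9, length(tumor_ids)), rep(NA_real_, length(normal_ids))),
    vaf = NA_real_,
    patient_id = c(tumor_ids, normal_ids),
    piece_id = NA_character_, timepoint = NA_character_,
    stringsAsFactors = FALSE)
}

# Build a JunctionCatalog directly from a count matrix (rows keyed
# "chrom:start-end:strand"), with annotation flags set explicitly. Used for
# positivity tests where exact counts matter.
catalog_from_matrix <- function(keys, count_matrix, manifest, annotated) {
  tables <- lapply(seq_len(ncol(count_matrix)), function(j) {
    nz <- count_matrix[, j] > 0
    gr <- neojx:::.keyToGRanges(keys[nz])
    gr$count <- count_matrix[nz, j]
    gr
  })
  names(tables) <- colnames(count_matrix)
  cat_ <- neojx::JunctionCatalog(tables, manifest, detection_min_count = 0L)
  ord <- match(rownames(cat_), keys)
  SummarizedExperiment::rowData(cat_)$annotated <- annotated[ord]
  cat_
}

# Naive per-pair positivity oracle: for each junction and sample, find the
# dominant overlapping junction by scanning all others, then apply the
# three thresholds. Independent of the vectorized implementation.
brute_force_positivity <- function(keys, count_matrix, annotated, cohort,
                                   thresholds = neojx::positivityThresholds()) {
  gr <- neojx:::.keyToGRanges(keys)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sd <- as.character(GenomicRanges::strand(gr))
  tumor_tot <- rowSums(count_matrix[, cohort == "tumor", drop = FALSE])
  n <- length(keys)
  pos <- matrix(FALSE, n, ncol(count_matrix), dimnames = dimnames(count_matrix))
  dom_key <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ov <- which(chrom == chrom[i] & st <= en[i] & en >= st[i] &
                  (sd == "*" | sd[i] == "*" | sd == sd[i]))
    ov <- setdiff(ov, i)
    dom <- NA_integer_
    if (length(ov)) {
      pool <- if (any(annotated[ov])) ov[annotated[ov]] else ov
      pool <- pool[order(-tumor_tot[pool], keys[pool])]
      dom <- pool[1]
      dom_key[i] <- keys[dom]
    }
    for (j in seq_len(ncol(count_matrix))) {
      cj <- count_matrix[i, j]
      dj <- if (is.na(dom)) 0 else count_matrix[dom, j]
      depth <- cj + dj
      freq <- if (depth > 0) cj / depth else 0
      th <- if (cohort[j] == "tumor") thresholds$tumor else thresholds$normal
      pos[i, j] <- cj >= th$min_count && depth >= th$min_depth &&
        freq >= th$min_frequency
    }
  }
  list(positive = pos, dominant_key = dom_key)
}

# Character-by-character codon-walk translation oracle (standard code),
# independent of the Biostrings-based implementation path.
codon_walk <- function(nt) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  aa <- character(n)
  for (k in seq_len(n)) {
    aa[k] <- gc_tab[[substr(nt, 3 * k - 2, 3 * k)]]
  }
  paste(aa, collapse = "")
}
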