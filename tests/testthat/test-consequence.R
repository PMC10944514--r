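# shared fixture: a generated reference provides coding multi-exon
# templates on both strands with known topology
ref <- generateReference(11, n_genes = 6)
models <- transcriptModels(ref$annotation)
m_plus <- models[["TX01A"]]   # + strand, two isoforms
m_minus <- models[["TX02A"]]  # - strand

test_that("splice patterns are classified by junction geometry", {
  for (m in list(m_plus, m_minus)) {
    expect_equal(classifySplicePattern(crypticJunction(m, 30, 10), m),
                 "cryptic_intron")
    expect_equal(classifySplicePattern(exonSkipJunction(m, 4), m),
                 "exon_skip")
    expect_equal(classifySplicePattern(
      altSpliceJunction(m, 2, "acceptor", 3), m), "alt_3ss")
    expect_equal(classifySplicePattern(
      altSpliceJunction(m, 3, "donor", 3), m), "alt_5ss")
  }
  # a junction skipping several exons is still one exon-skip event
  expect_equal(classifySplicePattern(
    GenomicRanges::GRanges(m_plus$chrom,
                           IRanges::IRanges(IRanges::end(m_plus$exons)[1] + 1,
                                            IRanges::start(m_plus$exons)[5] - 1),
                           strand = "+"), m_plus), "exon_skip")
  # both ends shifted -> complex
  j <- altSpliceJunction(m_plus, 2, "acceptor", 3)
  GenomicRanges::start(j) <- GenomicRanges::start(j) - 2
  expect_equal(classifySplicePattern(j, m_plus), "complex")
  # outside the footprint -> error
  expect_error(classifySplicePattern(
    GenomicRanges::GRanges("21", IRanges::IRanges(1, 100), strand = "+"),
    m_plus), "outside the footprint")
})

test_that("event application conserves length bookkeeping", {
  for (m in list(m_plus, m_minus)) {
    # cryptic intron of length L -> CDS shorter by exactly L
    ev <- applyEventToTranscript(crypticJunction(m, 30, 10), m, ref$genome)
    expect_equal(ev$nt_delta, -30L)
    # exon skip: exon 4 carries 90 coding nt
    ev <- applyEventToTranscript(exonSkipJunction(m, 4), m, ref$genome)
    expect_equal(ev$nt_delta, -90L)
    # acceptor shift of 3 nt
    ev <- applyEventToTranscript(altSpliceJunction(m, 2, "acceptor", 3), m,
                                 ref$genome)
    expect_equal(ev$nt_delta, -3L)
    # shifting the donor INTO the intron lengthens the transcript
    ev <- applyEventToTranscript(
      GenomicRanges::GRanges(m$chrom, IRanges::IRanges(
        IRanges::start(neojx:::.modelIntrons(m))[2] + 12,
        IRanges::end(neojx:::.modelIntrons(m))[2]),
        strand = m$strand), m, ref$genome)
    expect_equal(abs(ev$nt_delta), 12L)
  }
})

test_that("an alternative-acceptor event equals a hand-spliced sequence", {
  m <- m_plus
  ev <- applyEventToTranscript(altSpliceJunction(m, 2, "acceptor", 6), m,
                               ref$genome)
  # hand splice: drop the first 6 bases of the third exon
  ex <- m$exons
  hand <- IRanges::IRanges(
    c(IRanges::start(ex)[1:2], IRanges::start(ex)[3] + 6,
      IRanges::start(ex)[4:6]),
    IRanges::end(ex))
  hand_seq <- neojx:::.exonSeq(hand, m$chrom, m$strand, ref$genome)
  expect_equal(as.character(ev$altered_seq), as.character(hand_seq))
})

test_that("in-frame deletions are counted in amino acids, PTC-free", {
  rep1 <- translateAndFlag(
    applyEventToTranscript(crypticJunction(m_plus, 30, 1), m_plus,
                           ref$genome), m_plus, ref$genome)
  expect_equal(rep1$frame_status, "in_frame")
  expect_equal(rep1$nt_delta, -3L)
  expect_equal(rep1$aa_deleted, 1L)
  expect_equal(rep1$aa_inserted, 0L)
  expect_false(rep1$ptc_introduced)
  expect_equal(rep1$affected_aa_start, 30L)
  expect_equal(rep1$affected_aa_end, 30L)

  rep2 <- translateAndFlag(
    applyEventToTranscript(crypticJunction(m_minus, 145, 40), m_minus,
                           ref$genome), m_minus, ref$genome)
  expect_equal(rep2$aa_deleted, 40L)
  expect_equal(rep2$affected_aa_start, 145L)
})

test_that("frameshifts introduce PTCs found by the codon-walk oracle", {
  ev <- applyEventToTranscript(neojx:::.crypticFromCdsNt(m_plus, 148, 31),
                               m_plus, ref$genome)
  rep1 <- translateAndFlag(ev, m_plus, ref$genome)
  expect_equal(rep1$frame_status, "frameshift")
  expect_true(rep1$ptc_introduced)
  # codon-walk oracle on the altered CDS finds the same first stop
  oracle <- codon_walk(as.character(ev$alt_cds))
  expect_equal(regexpr("*", oracle, fixed = TRUE)[1],
               nchar(rep1$altered_protein))
  expect_true(endsWith(rep1$altered_protein, "*"))
})

test_that("events removing the start codon are non-translatable", {
  # cryptic deletion spanning CDS nt 1 (tx position of the start codon)
  m <- m_plus
  t1 <- neojx:::.cdsT1(m)
  g <- neojx:::.txToGenomic(c(t1 - 2, t1 + 4), m$exons, m$strand)
  j <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(min(g), max(g)),
                              strand = m$strand)
  ev <- applyEventToTranscript(j, m, ref$genome)
  expect_false(ev$translatable)
  rep1 <- translateAndFlag(ev, m, ref$genome)
  expect_false(rep1$translatable)
  topo <- neojx:::.surfaceomeTopology(ref$surfaceome, m$gene_id)
  verdict <- assessCandidate(rep1, topo)
  expect_false(verdict$pass)
})

test_that("wild-type round trip holds for every fixture template", {
  for (m in models) {
    b <- neojx:::.cdsTxBounds(m, ref$genome)
    txseq <- neojx:::.transcriptSeq(m, ref$genome)
    cds <- Biostrings::subseq(txseq, b["tstart"], b["tend"])
    walked <- codon_walk(as.character(cds))
    expect_identical(neojx:::.wtProtein(m, ref$genome), walked)
    expect_true(endsWith(walked, "*"))
    expect_false(grepl("[*]", substr(walked, 1, nchar(walked) - 1)))
  }
})

test_that("frame law and deletion arithmetic hold over randomized events", {
  set.seed(202)
  mods <- models[vapply(models, function(m) length(m$exons) == 6, logical(1))]
  n_iter <- 250
  for (it in seq_len(n_iter)) {
    m <- mods[[sample(length(mods), 1)]]
    # random deletion inside the coding part of one exon
    nt_from <- sample(4:800, 1)
    nt_len <- sample(1:45, 1)
    j <- tryCatch(neojx:::.crypticFromCdsNt(m, nt_from, nt_len),
                  error = function(e) NULL)
    if (is.null(j)) next  # crossed an exon boundary; resample
    ev <- applyEventToTranscript(j, m, ref$genome)
    expect_equal(ev$nt_delta, -nt_len)
    rep1 <- translateAndFlag(ev, m, ref$genome)
    expect_equal(rep1$frame_status == "frameshift", nt_len %% 3 != 0)
    if (nt_len %% 3 == 0 && (nt_from - 1) %% 3 == 0 && !rep1$ptc_introduced) {
      expect_equal(rep1$aa_deleted, nt_len / 3)
    }
    # agreement with the codon-walk oracle on the full altered CDS
    expect_identical(.translated <- neojx:::.translateNt(ev$alt_cds),
                     codon_walk(as.character(ev$alt_cds)))
  }
})

test_that("topology verdicts separate extracellular, TM and intracellular hits", {
  topo <- neojx:::.surfaceomeTopology(ref$surfaceome, m_plus$gene_id)
  verdict_for <- function(j, m = m_plus) {
    assessCandidate(translateAndFlag(
      applyEventToTranscript(j, m, ref$genome), m, ref$genome),
      neojx:::.surfaceomeTopology(ref$surfaceome, m$gene_id))
  }
  # extracellular in-frame deletion upstream of the TM: pass
  v <- verdict_for(crypticJunction(m_plus, 30, 10))
  expect_true(v$affects_extracellular && v$tm_intact && v$pass)
  # deletion overlapping the TM segment (aa 181-203): TM not intact
  v <- verdict_for(crypticJunction(m_plus, 185, 5))
  expect_false(v$tm_intact)
  expect_false(v$pass)
  # intracellular-only deletion: extracellular untouched
  v <- verdict_for(crypticJunction(m_plus, 220, 10))
  expect_false(v$affects_extracellular)
  expect_true(v$tm_intact)
  expect_false(v$pass)
  # missing topology fails with a logged reason
  v <- assessCandidate(translateAndFlag(
    applyEventToTranscript(crypticJunction(m_plus, 30, 10), m_plus,
                           ref$genome), m_plus, ref$genome), NULL)
  expect_false(v$pass)
  expect_match(v$reason, "topology")
})

test_that("multi-pass proteins are excluded at the protein verdict", {
  mp_gene <- ref$multipass_gene
  m <- models[[paste0(sub("GENE", "TX", mp_gene), "A")]]
  topo <- neojx:::.surfaceomeTopology(ref$surfaceome, mp_gene)
  expect_equal(topo$n_tm, 2L)
  v <- assessCandidate(translateAndFlag(
    applyEventToTranscript(crypticJunction(m, 30, 10), m, ref$genome),
    m, ref$genome), topo)
  expect_true(v$affects_extracellular)
  expect_true(v$tm_intact)
  expect_false(v$single_pass)
  expect_false(v$pass)
})

test_that("topology transfers to a non-reference template by TM match", {
  # TX01B skips exon 4 (aa 111-140); topology is defined on TX01A
  m_b <- models[["TX01B"]]
  topo <- neojx:::.surfaceomeTopology(ref$surfaceome, "GENE01")
  ref_protein <- sub("[*]$", "",
                     neojx:::.wtProtein(models[["TX01A"]], ref$genome))
  rep1 <- translateAndFlag(
    applyEventToTranscript(crypticJunction(m_b, 30, 10), m_b, ref$genome),
    m_b, ref$genome)
  v <- assessCandidate(rep1, topo, ref_protein = ref_protein)
  expect_true(v$assessable)
  expect_true(v$pass)
})

test_that("predictConsequences evaluates all canonical templates per junction", {
  j <- crypticJunction(m_plus, 30, 10)
  out <- as.data.frame(predictConsequences(
    junctionKeyFromRanges(j), "GENE01", ref$annotation, ref$genome,
    ref$surfaceome))
  expect_setequal(out$transcript_id, c("TX01A", "TX01B"))
  expect_true(all(out$pass))
  expect_true(all(out$pattern == "cryptic_intron"))
})
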