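test_that("the junction universe is defined by tumor samples only", {
  tables <- list(
    T1 = sj_granges("1", c(100, 900), c(200, 950), "+", c(12L, 9L)),
    T2 = sj_granges("1", 100, 200, "+", 3L),
    N1 = sj_granges("1", c(100, 5000), c(200, 5100), "+", c(50L, 99L)))
  man <- simple_manifest(c("T1", "T2"), "N1")
  cat_ <- JunctionCatalog(tables, man)
  # junction at 100-200 reaches the floor in T1; sub-floor counts kept
  expect_equal(rownames(cat_), "1:100-200:+")
  expect_equal(unname(counts(cat_)["1:100-200:+", ]), c(12L, 3L, 50L))
  # 900-950 never reaches 10 in a tumor; 5000-5100 is normal-only
  expect_false(any(grepl("900|5000", rownames(cat_))))
})

test_that("duplicate sample ids and unknown samples are rejected", {
  gr <- sj_granges("1", 100, 200, "+", 20L)
  man <- simple_manifest("T1")
  expect_error(JunctionCatalog(list(T1 = gr, T1 = gr), man), "duplicate")
  expect_error(JunctionCatalog(list(TX = gr), man), "absent from manifest")
})

test_that("the catalog universe equals a brute-force scan on a random cohort", {
  set.seed(42)
  n_j <- 60; n_s <- 20
  keys_pool <- junctionKey("1", seq(100, by = 500, length.out = n_j),
                           seq(300, by = 500, length.out = n_j), "+")
  counts_pool <- matrix(rpois(n_j * n_s, 6), n_j, n_s,
                        dimnames = list(keys_pool, sprintf("S%02d", 1:n_s)))
  cohort <- rep(c("tumor", "normal"), c(14, 6))
  man <- simple_manifest(sprintf("S%02d", 1:14), sprintf("S%02d", 15:20))
  tables <- lapply(seq_len(n_s), function(j) {
    nz <- counts_pool[, j] > 0
    gr <- neojx:::.keyToGRanges(keys_pool[nz])
    gr$count <- counts_pool[nz, j]
    gr
  })
  names(tables) <- colnames(counts_pool)
  cat_ <- JunctionCatalog(tables, man, detection_min_count = 10L)
  expected <- keys_pool[apply(counts_pool[, cohort == "tumor"], 1,
                              function(x) any(x >= 10))]
  expect_setequal(rownames(cat_), expected)
  expect_equal(counts(cat_)[sort(rownames(cat_)), ],
               counts_pool[sort(expected), ])
})

test_that("annotation flagging is exact-match with strand as soft constraint", {
  ann <- loadAnnotation(toy_gtf())
  tables <- list(T1 = sj_granges(
    "1", c(201, 202, 201, 1101), c(300, 300, 300, 1200), c("+", "+", "*", "+"),
    rep(20L, 4)))
  man <- simple_manifest("T1")
  cat_ <- flagAnnotated(JunctionCatalog(tables, man), ann)
  flags <- setNames(isAnnotated(cat_), rownames(cat_))
  expect_true(flags[["1:201-300:+"]])
  expect_false(flags[["1:202-300:+"]])   # 1-nt shift is non-annotated
  expect_true(flags[["1:201-300:*"]])    # undefined strand matches either
  expect_false(flags[["1:1101-1200:+"]]) # wrong strand vs the minus intron
  # partition property
  expect_equal(sum(flags) + sum(!flags), nrow(cat_))
})

test_that("gene assignment uses any-portion footprint overlap", {
  ann <- loadAnnotation(toy_gtf())
  surf <- data.frame(gene_id = c("GENEA", "GENEB"),
                     gene_symbol = c("A", "B"),
                     ref_transcript = c("TA1", "TB1"),
                     kind = "extracellular", aa_start = 1, aa_end = 10)
  tables <- list(T1 = sj_granges(
    "1", c(210, 595, 700, 990), c(290, 650, 800, 1500), "+", rep(20L, 4)))
  cat_ <- flagAnnotated(JunctionCatalog(tables, simple_manifest("T1")), ann)
  cat_ <- assignGenes(cat_, ann, surf)
  gid <- setNames(hostGene(cat_), rownames(cat_))
  expect_equal(gid[["1:210-290:+"]], "GENEA")   # fully inside
  expect_equal(gid[["1:595-650:+"]], "GENEA")   # straddles the 3' end
  expect_true(is.na(gid[["1:700-800:+"]]))      # between genes
  # strand-incompatible with GENEB (-), so no assignment
  expect_true(is.na(gid[["1:990-1500:+"]]))
})

test_that("multi-gene overlaps pick the larger overlap and report exact ties", {
  gtf <- c(toy_gtf(), GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(550, 650), c(620, 720)), strand = "+",
    type = "exon", gene_id = "GENED", transcript_id = "TD1"))
  ann <- loadAnnotation(gtf)
  surf <- data.frame(gene_id = c("GENEA", "GENED"),
                     gene_symbol = c("A", "D"),
                     ref_transcript = c("TA1", "TD1"),
                     kind = "extracellular", aa_start = 1, aa_end = 10)
  # GENEA spans 100-600, GENED 550-720; junction 560-640 overlaps A by 41
  # and D by 81 -> assigned to D, unambiguously
  tables <- list(T1 = sj_granges("1", 560, 640, "+", 20L))
  cat_ <- flagAnnotated(JunctionCatalog(tables, simple_manifest("T1")), ann)
  cat_ <- assignGenes(cat_, ann, surf)
  rd <- SummarizedExperiment::rowData(cat_)
  expect_equal(rd["1:560-640:+", "gene_id"], "GENED")
  expect_false(any(rd$ambiguous))

  # identical footprints make an exact tie: reported, marked ambiguous
  gtf2 <- c(toy_gtf(), GenomicRanges::GRanges(
    "1", IRanges::IRanges(100, 600), strand = "+", type = "exon",
    gene_id = "GENEE", transcript_id = "TE1"))
  ann2 <- loadAnnotation(gtf2)
  surf2 <- data.frame(gene_id = c("GENEA", "GENEE"),
                      gene_symbol = c("A", "E"),
                      ref_transcript = c("TA1", "TE1"),
                      kind = "extracellular", aa_start = 1, aa_end = 10)
  tables2 <- list(T1 = sj_granges("1", 210, 290, "+", 20L))
  cat3 <- flagAnnotated(JunctionCatalog(tables2, simple_manifest("T1")), ann2)
  cat3 <- assignGenes(cat3, ann2, surf2)
  rd3 <- SummarizedExperiment::rowData(cat3)
  expect_true(rd3[1, "ambiguous"])
  expect_equal(rd3[1, "gene_id"], "GENEA,GENEE")
})

test_that("gene assignment is invariant to gene load order", {
  ann <- loadAnnotation(toy_gtf())
  surf <- data.frame(gene_id = c("GENEA", "GENEB", "GENEC"),
                     gene_symbol = c("A", "B", "C"),
                     ref_transcript = c("TA1", "TB1", "TC1"),
                     kind = "extracellular", aa_start = 1, aa_end = 10)
  tables <- list(T1 = sj_granges("1", c(210, 1150), c(290, 1210),
                                 c("+", "-"), c(20L, 20L)))
  cat_ <- flagAnnotated(JunctionCatalog(tables, simple_manifest("T1")), ann)
  a <- hostGene(assignGenes(cat_, ann, surf))
  b <- hostGene(assignGenes(cat_, ann, surf[3:1, ]))
  expect_equal(a, b)
})

test_that("undefined-strand junctions inherit the gene strand or are dropped on conflict", {
  # two overlapping genes on opposite strands
  gtf <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(100, 150), c(400, 500)), strand = c("+", "-"),
    type = "exon", gene_id = c("GP", "GM"), transcript_id = c("TP", "TM"))
  ann <- loadAnnotation(gtf)
  surf <- data.frame(gene_id = c("GP", "GM"), gene_symbol = c("p", "m"),
                     ref_transcript = c("TP", "TM"),
                     kind = "extracellular", aa_start = 1, aa_end = 10)
  tables <- list(T1 = sj_granges("1", c(200, 450), c(300, 480), "*",
                                 c(20L, 20L)))
  cat_ <- flagAnnotated(JunctionCatalog(tables, simple_manifest("T1")), ann)
  expect_message(cat2 <- assignGenes(cat_, ann, surf), "dropping")
  # 200-300 overlaps both strands -> dropped; 450-480 only GM -> resolved to -
  expect_equal(rownames(cat2), "1:450-480:*")
  expect_equal(as.character(GenomicRanges::strand(
    SummarizedExperiment::rowRanges(cat2))), "-")
  expect_equal(hostGene(cat2), "GM")
})
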