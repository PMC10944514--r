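#' Read a STAR SJ.out.tab junction table
#'
#' Parses the 9-column whitespace-delimited splice-junction table emitted by
#' STAR. Columns 1-4 identify the junction (chromosome, first and last base
#' of the intron, strand encoded 0 = undefined, 1 = `+`, 2 = `-`); column 7
#' holds the count of uniquely mapped reads crossing the junction, the only
#' count used downstream (multi-mapped reads in column 8 are ignored).
#' Junctions on chromosomes other than 1-22, X and Y are dropped.
#'
#' @param path Path to an `SJ.out.tab` file.
#' @param min_count Minimum unique-read count (column 7) for a junction to be
#'   returned. Default 0 keeps everything; the cohort-level detection floor is
#'   applied later when the catalog is built.
#' @return A `GRanges` over intron intervals (1-based, inclusive) with a
#'   `count` metadata column. Undefined strand becomes `*`.
#' @examples
#' f <- tempfile()
#' writeLines("7\t121599\t121700\t1\t1\t0\t44\t3\t98", f)
#' readSJTab(f)
#' @export
readSJTab <- function(path, min_count = 0L) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(GenomicRanges::GRanges(count = integer(0)))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 9L)) {
    stop("malformed SJ.out.tab record at line ", lineno[which(nf < 9L)[1]],
         " of ", path, ": expected 9 columns, found ", nf[which(nf < 9L)[1]])
  }
  getcol <- function(i) vapply(fields, `[`, character(1), i)
  ints <- lapply(c(2, 3, 4, 7), function(i) {
    v <- suppressWarnings(as.integer(getcol(i)))
    if (anyNA(v)) {
      stop("malformed SJ.out.tab record at line ", lineno[which(is.na(v))[1]],
           " of ", path, ": non-integer value in column ", i)
    }
    v
  })
  chrom <- .normChrom(getcol(1))
  istart <- ints[[1]]; iend <- ints[[2]]; scode <- ints[[3]]; count <- ints[[4]]
  if (any(scode < 0L | scode > 2L)) {
    stop("malformed SJ.out.tab record at line ",
         lineno[which(scode < 0L | scode > 2L)[1]], " of ", path,
         ": strand code must be 0, 1 or 2")
  }
  if (any(istart > iend)) {
    stop("malformed SJ.out.tab record at line ",
         lineno[which(istart > iend)[1]], " of ", path,
         ": intron start exceeds intron end")
  }
  sel <- chrom %in% .ALLOWED_CHROMS & count >= min_count
  strand <- c("*", "+", "-")[scode + 1L]
  GenomicRanges::GRanges(
    seqnames = chrom[sel],
    ranges = IRanges::IRanges(istart[sel], iend[sel]),
    strand = strand[sel],
    count = count[sel])
}

#' Write junction tables in STAR SJ.out.tab layout
#'
#' Inverse of [readSJTab()]: writes a `GRanges` with a `count` column as a
#' 9-column tab-delimited table (motif, annotation flag, multi-mapped count
#' and overhang columns are filled with placeholder values, as only columns
#' 1-4 and 7 carry information for this pipeline).
#'
#' @param gr `GRanges` with `count` metadata column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSJTab <- function(gr, path) {
  scode <- match(as.character(GenomicRanges::strand(gr)), c("*", "+", "-")) - 1L
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = scode,
    motif = 0L,
    annotated = 0L,
    unique_count = gr$count,
    multi_count = 0L,
    overhang = 50L)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a gene-level expression matrix
#'
#' Reads a tab-delimited genes x samples matrix of expression values. The
#' UCSC Xena/Toil distribution encodes expression as `log2(TPM + 0.001)`;
#' with `encoding = "log2_tpm_plus_0.001"` each value is transformed back to
#' the TPM scale as `2^x - 0.001`, clipped at zero against negative
#' round-off.
#'
#' @param path Path to a TSV with gene identifiers in the first column and a
#'   header row of sample identifiers.
#' @param encoding Either `"tpm"` (values used as-is) or
#'   `"log2_tpm_plus_0.001"` (Xena encoding, back-transformed).
#' @return A numeric matrix (genes x samples) of TPM values.
#' @seealso [xenaToTPM()]
#' @export
loadExpression <- function(path, encoding = c("tpm", "log2_tpm_plus_0.001")) {
  encoding <- match.arg(encoding)
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  bad <- rownames(m)[apply(m, 1, function(r) any(is.na(r) | is.nan(r)))]
  if (length(bad)) {
    stop("expression matrix contains NA/NaN values for gene(s): ",
         paste(bad, collapse = ", "))
  }
  if (encoding == "log2_tpm_plus_0.001") m <- xenaToTPM(m)
  if (any(m < 0)) stop("expression matrix contains negative values")
  m
}

#' Back-transform Xena log2(TPM + 0.001) values
#'
#' @param x Numeric vector or matrix of `log2(TPM + 0.001)` values.
#' @return Values on the TPM scale, `2^x - 0.001`, clipped at 0.
#' @examples
#' xenaToTPM(0)                 # 0.999
#' xenaToTPM(log2(1000.001))    # 1000
#' @export
xenaToTPM <- function(x) {
  pmax(2^x - 0.001, 0)
}

.MANIFEST_COLS <- c("sample_id", "cohort", "group", "purity", "vaf",
                    "patient_id", "piece_id", "timepoint")

#' Load a sample manifest
#'
#' The manifest is a TSV with one row per sequenced sample. Required columns
#' are `sample_id` and `cohort` (`tumor` or `normal`); optional columns are
#' `group` (disease group for tumors, tissue label for normals), `purity`
#' (tumor-purity fraction), `vaf` (IDH1 R132 variant allele fraction),
#' `patient_id`, `piece_id` and `timepoint` (`primary`/`recurrent`). Missing
#' optional columns are filled with `NA`.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` with the standard manifest columns.
#' @export
loadManifest <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (!all(c("sample_id", "cohort") %in% names(df))) {
    stop("manifest must contain 'sample_id' and 'cohort' columns")
  }
  for (col in .MANIFEST_COLS) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df <- df[, .MANIFEST_COLS]
  df$purity <- as.numeric(df$purity)
  df$vaf <- as.numeric(df$vaf)
  .validateManifest(df)
  df
}

.validateManifest <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$cohort %in% c("tumor", "normal"))) {
    stop("manifest cohort must be 'tumor' or 'normal'")
  }
  ok <- is.na(df$purity) | (df$purity >= 0 & df$purity <= 1)
  if (!all(ok)) stop("manifest purity values must lie in [0, 1]")
  ok <- is.na(df$vaf) | (df$vaf >= 0 & df$vaf <= 1)
  if (!all(ok)) stop("manifest vaf values must lie in [0, 1]")
  ppt <- df[!is.na(df$patient_id), c("patient_id", "piece_id", "timepoint")]
  if (nrow(ppt) && anyDuplicated(ppt)) {
    stop("manifest (patient_id, piece_id, timepoint) combinations must be unique")
  }
  invisible(df)
}

#' Gate samples on tumor purity
#'
#' Two gating rules are supported. Cohort-level gating retains tumor samples
#' with known purity at or above `purity_min` (ABSOLUTE-style estimates;
#' samples with unknown purity are excluded with a warning). Spatial-dataset
#' gating retains pieces with purity at or above `spatial_purity_min` for
#' IDH-wildtype and IDH-O cases, and pieces with IDH1 R132 VAF strictly above
#' `vaf_min` for IDH-A cases. Normal samples are always retained.
#'
#' @param manifest Manifest `data.frame` as from [loadManifest()].
#' @param mode `"cohort"` or `"spatial"`.
#' @param purity_min Cohort purity floor (inclusive), default 0.6.
#' @param spatial_purity_min Spatial purity floor (inclusive), default 0.5.
#' @param vaf_min Spatial IDH-A VAF floor (exclusive), default 0.25.
#' @return The retained manifest rows.
#' @export
gateSamples <- function(manifest, mode = c("cohort", "spatial"),
                        purity_min = 0.6, spatial_purity_min = 0.5,
                        vaf_min = 0.25) {
  mode <- match.arg(mode)
  tum <- manifest$cohort == "tumor"
  if (mode == "cohort") {
    unknown <- tum & is.na(manifest$purity) & is.na(manifest$vaf)
    keep <- !tum | (!is.na(manifest$purity) & manifest$purity >= purity_min)
  } else {
    idha <- !is.na(manifest$group) & manifest$group == "IDH-A"
    unknown <- tum & ((idha & is.na(manifest$vaf)) |
                        (!idha & is.na(manifest$purity)))
    keep <- !tum |
      (idha & !is.na(manifest$vaf) & manifest$vaf > vaf_min) |
      (!idha & !is.na(manifest$purity) &
         manifest$purity >= spatial_purity_min)
  }
  if (any(unknown)) {
    warning("excluding tumor sample(s) with unknown purity: ",
            paste(manifest$sample_id[unknown], collapse = ", "))
  }
  manifest[keep, , drop = FALSE]
}

#' Load a surfaceome topology table
#'
#' The surfaceome table lists, for each cell-surface gene, the topology
#' segments of one named reference isoform in 1-based protein coordinates:
#' one row per segment with columns `gene_id`, `gene_symbol`,
#' `ref_transcript`, `kind` (`extracellular`, `transmembrane` or
#' `intracellular`), `aa_start`, `aa_end`. The transmembrane segment count
#' per gene (`n_tm`) distinguishes single-pass from multi-pass proteins.
#'
#' @param path Path to the TSV, or a `data.frame` already in that layout.
#' @return A `data.frame` of segments, validated (segments sorted and
#'   non-overlapping within each gene), with an `n_tm` column added.
#' @export
loadSurfaceome <- function(path) {
  df <- if (is.data.frame(path)) path else read.delim(path, check.names = FALSE)
  need <- c("gene_id", "gene_symbol", "ref_transcript", "kind",
            "aa_start", "aa_end")
  if (!all(need %in% names(df))) {
    stop("surfaceome table must contain columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$kind %in% c("extracellular", "transmembrane", "intracellular"))) {
    stop("surfaceome segment kind must be extracellular, transmembrane or intracellular")
  }
  df$aa_start <- as.integer(df$aa_start)
  df$aa_end <- as.integer(df$aa_end)
  if (any(df$aa_start < 1L | df$aa_start > df$aa_end)) {
    stop("surfaceome segment coordinates must satisfy 1 <= aa_start <= aa_end")
  }
  df <- df[order(df$gene_id, df$aa_start), , drop = FALSE]
  for (g in unique(df$gene_id)) {
    seg <- df[df$gene_id == g, ]
    if (nrow(seg) > 1L && any(seg$aa_start[-1] <= seg$aa_end[-nrow(seg)])) {
      stop("overlapping topology segments for surfaceome gene ", g)
    }
  }
  ntm <- tapply(df$kind == "transmembrane", df$gene_id, sum)
  df$n_tm <- as.integer(ntm[df$gene_id])
  rownames(df) <- NULL
  df
}

# Topology of one gene as used by the consequence module.
.surfaceomeTopology <- function(surfaceome, gene_id) {
  seg <- surfaceome[surfaceome$gene_id == gene_id, , drop = FALSE]
  if (!nrow(seg)) return(NULL)
  list(gene_id = gene_id,
       ref_transcript = seg$ref_transcript[1],
       n_tm = seg$n_tm[1],
       segments = seg[, c("kind", "aa_start", "aa_end")])
}
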