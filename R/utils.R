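#' @import methods
#' @importFrom stats rnbinom rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Chromosomes retained throughout the screen: autosomes 1-22 plus X and Y.
.ALLOWED_CHROMS <- c(as.character(1:22), "X", "Y")

# Strip an optional UCSC-style "chr" prefix so both dialects key identically.
.normChrom <- function(x) sub("^chr", "", as.character(x))

#' Canonical junction key
#'
#' Junctions are keyed by chromosome, first and last intronic base (1-based,
#' inclusive) and strand, the four fields that identify a unique splice
#' junction in a STAR `SJ.out.tab` file. Unknown strand is encoded `*`.
#'
#' @param chrom Chromosome name (without `chr` prefix).
#' @param start,end First/last base of the intron, 1-based inclusive.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return Character vector of keys, `"chrom:start-end:strand"`.
#' @export
junctionKey <- function(chrom, start, end, strand) {
  if (!length(chrom)) return(character(0))
  paste0(chrom, ":", start, "-", end, ":", strand)
}

#' @rdname junctionKey
#' @param gr A `GRanges` of junction intron intervals.
#' @export
junctionKeyFromRanges <- function(gr) {
  junctionKey(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr),
              as.character(GenomicRanges::strand(gr)))
}

# Parse "chrom:start-end:strand" keys back into a GRanges.
.keyToGRanges <- function(keys) {
  m <- regmatches(keys, regexec("^([^:]+):(\\d+)-(\\d+):([+*-])$", keys))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("malformed junction key(s): ", paste(keys[bad], collapse = ", "))
  }
  GenomicRanges::GRanges(
    seqnames = vapply(m, `[`, character(1), 2L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(m, `[`, character(1), 3L)),
      end = as.integer(vapply(m, `[`, character(1), 4L))),
    strand = vapply(m, `[`, character(1), 5L))
}

# Deterministic ordering of junctions: chromosome (karyotypic), start, end,
# strand. Used so catalogs are reproducible regardless of input file order.
.orderJunctions <- function(gr) {
  chr <- factor(as.character(GenomicRanges::seqnames(gr)),
                levels = .ALLOWED_CHROMS)
  order(chr, GenomicRanges::start(gr), GenomicRanges::end(gr),
        as.character(GenomicRanges::strand(gr)))
}

# Two strands are compatible when either is undefined or they agree.
.strandCompatible <- function(a, b) {
  a == "*" | b == "*" | a == b
}

.njxLog <- function(...) {
  message("[neojx] ", ...)
}

# Longest common prefix / suffix lengths of two character strings, compared
# element-wise; used for amino-acid delta bookkeeping.
.commonPrefixSuffix <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- min(length(av), length(bv))
  pre <- 0L
  while (pre < n && av[pre + 1L] == bv[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < n - pre &&
         av[length(av) - suf] == bv[length(bv) - suf]) suf <- suf + 1L
  c(prefix = pre, suffix = suf)
}
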