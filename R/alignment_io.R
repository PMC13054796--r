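## SAM/BAM ingestion: a minimal alignment-record table shared by the
## short-read and long-read quantification modules. Parsing is delegated to
## Rsamtools; the table keeps only what the filters and counters need.

#' Read alignment records from SAM or BAM
#'
#' `.sam` input is converted to BAM on the fly with [Rsamtools::asBam()].
#' The returned table has one row per alignment record with columns
#' `qname`, `flag`, `rname`, `pos` (1-based leftmost, `NA` if unmapped),
#' `mapq`, `cigar`, `strand`, `seq`, `nh` (NH tag, `NA` when absent), plus
#' flag-derived logicals `paired`, `proper`, `unmapped`, `read1`, `read2`,
#' `secondary`, `supplementary`, `duplicate`. Contig lengths from the header
#' are attached as the `seqinfo` attribute (named integer vector).
#'
#' @param path Path to a SAM or BAM file.
#' @return A data frame of class `mtdsrna_alignments`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand",
             "seq"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(flag))
  df <- data.frame(
    qname = res$qname,
    flag = flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    strand = as.character(res$strand),
    seq = as.character(res$seq),
    nh = nh,
    stringsAsFactors = FALSE)
  df$paired <- bitwAnd(flag, 0x1L) > 0L
  df$proper <- bitwAnd(flag, 0x2L) > 0L
  df$unmapped <- bitwAnd(flag, 0x4L) > 0L
  df$read1 <- bitwAnd(flag, 0x40L) > 0L
  df$read2 <- bitwAnd(flag, 0x80L) > 0L
  df$secondary <- bitwAnd(flag, 0x100L) > 0L
  df$duplicate <- bitwAnd(flag, 0x400L) > 0L
  df$supplementary <- bitwAnd(flag, 0x800L) > 0L
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  attr(df, "seqinfo") <- hdr
  class(df) <- c("mtdsrna_alignments", "data.frame")
  df
}

#' Filter configuration for short-read quantification
#'
#' "Uniquely mapped" is implemented aligner-agnostically: when the NH
#' (number of hits) tag is present the record must have `NH == 1`;
#' otherwise `mapq >= min_mapq` stands in for uniqueness.
#'
#' @param min_mapq Minimum mapping quality when no NH tag is present
#'   (default 1).
#' @param require_proper Require the proper-pair flag for paired records.
#' @param strict_paired Error on single-end records (paired-only designs).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mapq = 1L, require_proper = TRUE,
                          strict_paired = FALSE) {
  structure(list(min_mapq = as.integer(min_mapq),
                 require_proper = isTRUE(require_proper),
                 strict_paired = isTRUE(strict_paired)),
            class = "filter_config")
}

#' Record-level filter predicate
#'
#' A record passes when it is mapped, primary (neither secondary nor
#' supplementary), not a duplicate, properly paired when paired (and
#' `require_proper` is set), and uniquely mapped (NH tag equal to 1 when
#' present, else `mapq >= min_mapq`).
#'
#' @param aln An alignment table from [read_alignments()].
#' @param config A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
passes_filters <- function(aln, config = filter_config()) {
  unique_ok <- ifelse(is.na(aln$nh), aln$mapq >= config$min_mapq,
                      aln$nh == 1L)
  ok <- !aln$unmapped & !aln$secondary & !aln$supplementary &
    !aln$duplicate & unique_ok
  if (config$require_proper) ok <- ok & (!aln$paired | aln$proper)
  ok
}

## Reference-space aligned blocks for each record (M/=/X ops only, so
## deletions and introns contribute nothing to coverage or overlap).
## Returns an IRangesList parallel to the rows of `aln`.
.aligned_blocks <- function(aln) {
  out <- vector("list", nrow(aln))
  mapped <- !aln$unmapped & !is.na(aln$pos)
  if (any(mapped)) {
    rg <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar[mapped], pos = aln$pos[mapped], ops = c("M", "=", "X"))
    out[mapped] <- as.list(rg)
  }
  empty <- IRanges::IRanges()
  out[!mapped] <- list(empty)
  IRanges::IRangesList(out)
}
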