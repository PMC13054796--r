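## Strand-stratified quantification of stranded short-read RNA-seq against
## the mitochondrial contig: light/heavy fragment counts and fractions,
## mapping accounting, and per-base strand-specific normalized coverage.

#' Infer the transcript strand label (light/heavy) of alignment records
#'
#' For a stranded paired-end library the transcript strand follows from the
#' alignment strand, the mate rank and the library chemistry: under `RF`
#' (dUTP-style) read1 aligns antisense to the transcript, under `FR` read1
#' aligns sense. Read2 is always the orientation-complement of read1;
#' single-end reads follow the read1 rule. The resulting reference strand is
#' then labeled `light`/`heavy` via the [derive_strand_convention()] object.
#'
#' @param aln Alignment table ([read_alignments()]), mitochondrial records.
#' @param protocol `"RF"` or `"FR"`.
#' @param convention A `strand_convention`.
#' @param strict_paired Error on single-end records when `TRUE`.
#' @return Character vector `"light"`/`"heavy"` per record.
#' @export
infer_transcript_strand <- function(aln, protocol = c("RF", "FR"),
                                    convention, strict_paired = FALSE) {
  protocol <- match.arg(protocol)
  if (strict_paired && any(!aln$paired))
    stop("single-end record(s) present under a paired-only configuration")
  ## flip = this record's alignment strand is antisense to the transcript
  flip <- if (protocol == "RF") !aln$read2 else aln$read2
  ts <- ifelse(flip,
               ifelse(aln$strand == "+", "-", "+"),
               aln$strand)
  ifelse(ts == convention$heavy_reference_strand, "heavy", "light")
}

## fragment-unit row mask: one record per fragment (read1 for pairs)
.fragment_unit <- function(aln, count_mates_separately = FALSE) {
  if (count_mates_separately) rep(TRUE, nrow(aln)) else !aln$paired | aln$read1
}

#' Count light/heavy mitochondrial fragments
#'
#' The counting unit is the fragment: a proper pair is counted once (via
#' read1), a single-end read counts per read; `count_mates_separately = TRUE`
#' reproduces per-read counting. Records must pass [passes_filters()].
#' With zero mitochondrial fragments the fractions are `NA` with a warning.
#'
#' @param aln Alignment table covering all contigs of the sample.
#' @param protocol `"RF"` or `"FR"`.
#' @param convention A `strand_convention`.
#' @param config A [filter_config()].
#' @param contig Mitochondrial contig name (default `"chrMT"`).
#' @param sample_id Sample label for the output row.
#' @param count_mates_separately Count both mates of a pair.
#' @return An object of class `strand_counts`: `sample_id`, `n_light`,
#'   `n_heavy`, `n_mito`, `n_mapped_total`, `n_unmapped`, `f_light`,
#'   `f_heavy`.
#' @export
count_strands <- function(aln, protocol = c("RF", "FR"), convention,
                          config = filter_config(), contig = "chrMT",
                          sample_id = "sample",
                          count_mates_separately = FALSE) {
  protocol <- match.arg(protocol)
  unit <- .fragment_unit(aln, count_mates_separately)
  ok <- passes_filters(aln, config)
  n_mapped_total <- sum(unit & ok)
  n_unmapped <- sum(unit & aln$unmapped)
  mito <- unit & ok & aln$rname %in% contig
  n_mito <- sum(mito)
  if (n_mito == 0L) {
    warning("no mitochondrial fragments pass filters for sample '",
            sample_id, "'; fractions reported as NA")
    n_light <- n_heavy <- 0L
    f_light <- f_heavy <- NA_real_
  } else {
    lab <- infer_transcript_strand(aln[mito, , drop = FALSE], protocol,
                                   convention,
                                   strict_paired = config$strict_paired)
    n_light <- sum(lab == "light")
    n_heavy <- sum(lab == "heavy")
    f_light <- n_light / n_mito
    f_heavy <- n_heavy / n_mito
  }
  structure(list(sample_id = sample_id, n_light = n_light, n_heavy = n_heavy,
                 n_mito = n_mito, n_mapped_total = n_mapped_total,
                 n_unmapped = n_unmapped, f_light = f_light,
                 f_heavy = f_heavy, protocol = protocol),
            class = "strand_counts")
}

#' @export
print.strand_counts <- function(x, ...) {
  cat(sprintf(
    "<strand_counts> %s: n_mito=%d (light=%d, heavy=%d), f_light=%s\n",
    x$sample_id, x$n_mito, x$n_light, x$n_heavy,
    ifelse(is.na(x$f_light), "NA", sprintf("%.4f", x$f_light))))
  invisible(x)
}

#' @export
as.data.frame.strand_counts <- function(x, ...) {
  data.frame(sample_id = x$sample_id, n_light = x$n_light,
             n_heavy = x$n_heavy, n_mito = x$n_mito,
             n_mapped = x$n_mapped_total, n_unmapped = x$n_unmapped,
             f_light = x$f_light, f_heavy = x$f_heavy,
             stringsAsFactors = FALSE)
}

## per-strand base-resolution depth from aligned blocks; wraps nothing:
## records are trusted to lie within [1, length]
.strand_depth <- function(aln, labels, genome_length) {
  out <- list(light = numeric(genome_length), heavy = numeric(genome_length))
  for (s in c("light", "heavy")) {
    rows <- which(labels == s)
    if (length(rows) == 0L) next
    blk <- unlist(.aligned_blocks(aln[rows, , drop = FALSE]))
    blk <- IRanges::restrict(blk, start = 1L, end = genome_length)
    cov <- IRanges::coverage(blk, width = genome_length)
    out[[s]] <- as.numeric(cov)
  }
  out
}

#' Per-base strand-specific normalized coverage
#'
#' Depth accumulates per aligned block (deletions and introns contribute
#' nothing); both mates of a pair contribute. Normalization divides both
#' strands by the single sample-wide maximum over the two strands so that
#' relative strand asymmetry is preserved.
#'
#' @inheritParams count_strands
#' @param genome A [mito_genome()] (provides the vector length).
#' @return An object of class `strand_coverage`: numeric vectors `light`,
#'   `heavy`, `normalized_light`, `normalized_heavy` (length = genome
#'   length), and the scalar `max_depth`.
#' @export
per_base_coverage <- function(aln, genome, protocol = c("RF", "FR"),
                              convention, config = filter_config(),
                              contig = genome$contig_name,
                              sample_id = "sample") {
  protocol <- match.arg(protocol)
  keep <- passes_filters(aln, config) & aln$rname %in% contig
  sub <- aln[keep, , drop = FALSE]
  labels <- if (nrow(sub)) {
    infer_transcript_strand(sub, protocol, convention,
                            strict_paired = config$strict_paired)
  } else character(0)
  depth <- .strand_depth(sub, labels, genome$length)
  m <- max(depth$light, depth$heavy)
  if (m == 0) {
    warning("all-zero coverage for sample '", sample_id,
            "'; normalized vectors are all zero")
    nl <- depth$light
    nh <- depth$heavy
  } else {
    nl <- depth$light / m
    nh <- depth$heavy / m
  }
  structure(list(sample_id = sample_id, contig = contig,
                 light = depth$light, heavy = depth$heavy,
                 normalized_light = nl, normalized_heavy = nh,
                 max_depth = m),
            class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat(sprintf("<strand_coverage> %s on %s: %d bp, max depth %g\n",
              x$sample_id, x$contig, length(x$light), x$max_depth))
  invisible(x)
}

#' Mapped / unmapped / mitochondrial read accounting
#'
#' Totals are over primary records (secondary and supplementary alignments
#' are bookkeeping copies, not reads); `n_total = n_mapped + n_unmapped`.
#' `n_mito` counts fragments on the mitochondrial contig passing filters
#' (duplicates excluded by flag; a fragment whose mates overlap is still
#' one fragment).
#'
#' @inheritParams count_strands
#' @return A list with `n_total`, `n_mapped`, `n_unmapped`, `n_mito`.
#' @export
read_accounting <- function(aln, config = filter_config(),
                            contig = "chrMT") {
  primary <- !aln$secondary & !aln$supplementary
  n_total <- sum(primary)
  n_unmapped <- sum(primary & aln$unmapped)
  n_mapped <- n_total - n_unmapped
  unit <- .fragment_unit(aln)
  n_mito <- sum(unit & passes_filters(aln, config) & aln$rname %in% contig)
  list(n_total = n_total, n_mapped = n_mapped, n_unmapped = n_unmapped,
       n_mito = n_mito)
}

#' Write a strand-counts table to TSV
#' @param counts A `strand_counts` object or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strand_counts <- function(counts, path) {
  if (inherits(counts, "strand_counts")) counts <- list(counts)
  df <- do.call(rbind, lapply(counts, as.data.frame))
  .write_tsv(df, path)
}

#' Write per-base coverage as a bedGraph-style TSV
#'
#' Columns: contig, start (0-based), end (exclusive), strand (light/heavy),
#' depth, normalized_depth. Runs of equal depth are collapsed.
#'
#' @param coverage A `strand_coverage` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  rows <- lapply(c("light", "heavy"), function(s) {
    r <- rle(coverage[[s]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    m <- if (coverage$max_depth > 0) coverage$max_depth else 1
    data.frame(contig = coverage$contig, start = starts, end = ends,
               strand = s, depth = r$values,
               normalized_depth = r$values / m, stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

## shared TSV writer: tab-delimited, header row, '.' for missing values
.write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && anyNA(df[[j]])) df[[j]] <- as.character(df[[j]])
    if (is.character(df[[j]])) df[[j]][is.na(df[[j]])] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
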