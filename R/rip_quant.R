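## Long-read J2 RIP-seq quantification: per-feature counts with
## featureCounts-style overlap semantics (countMultiMappingReads = FALSE,
## allowMultiOverlap = TRUE, minOverlap = 6), chrMT mapping fractions, and
## per-strand normalized histograms.

## inclusion rule for long-read records: primary, mapped, on the target
## contig, and unique unless multimappers are requested
.longread_include <- function(aln, contig, count_multimappers) {
  ok <- !aln$unmapped & !aln$secondary & !aln$supplementary &
    aln$rname %in% contig
  if (!count_multimappers) ok <- ok & (is.na(aln$nh) | aln$nh == 1L)
  ok
}

#' Count long reads per mitochondrial feature
#'
#' An included read is assigned to every feature whose interval intersects
#' the read's aligned blocks by at least `min_overlap` bases (gaps in the
#' alignment contribute nothing). With `allow_multi_overlap = FALSE`, reads
#' meeting the threshold for more than one feature are left unassigned.
#' Secondary/supplementary records are excluded, as are multimappers
#' (NH tag > 1) unless `count_multimappers = TRUE`. Percentages are shares
#' of total assignments (a read assigned to k features contributes k
#' assignments), so they sum to 100 even with multi-overlap.
#'
#' @param aln Alignment table ([read_alignments()]).
#' @param features A `mito_features` data frame (with or without tRNAs,
#'   see [strip_trnas()]).
#' @param min_overlap Minimum overlap in bases (default 6).
#' @param allow_multi_overlap Assign reads to every overlapped feature.
#' @param count_multimappers Include records with NH tag > 1.
#' @param contig Mitochondrial contig name.
#' @param sample_id Sample label.
#' @return A data frame of class `feature_counts` with columns `name`,
#'   `ftype`, `strand`, `count`, `percent_of_assigned`; attributes
#'   `variant` (`"trna_included"`/`"trna_excluded"`), `sample_id`,
#'   `n_assignments`.
#' @export
count_features_longread <- function(aln, features, min_overlap = 6L,
                                    allow_multi_overlap = TRUE,
                                    count_multimappers = FALSE,
                                    contig = "chrMT",
                                    sample_id = "sample") {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (nrow(features) == 0L) stop("empty feature list")
  keep <- .longread_include(aln, contig, count_multimappers)
  sub <- aln[keep, , drop = FALSE]
  counts <- integer(nrow(features))
  if (nrow(sub) > 0L) {
    blocks <- .aligned_blocks(sub)          # IRangesList, one set per read
    feat_ir <- IRanges::IRanges(features$start + 1L, features$end)
    ub <- unlist(blocks)
    read_of_block <- rep(seq_len(nrow(sub)),
                         times = lengths(blocks))
    hits <- IRanges::findOverlaps(ub, feat_ir)
    if (length(hits) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(
        ub[S4Vectors::queryHits(hits)], feat_ir[S4Vectors::subjectHits(hits)]))
      key <- data.frame(read = read_of_block[S4Vectors::queryHits(hits)],
                        feat = S4Vectors::subjectHits(hits), ov = ov)
      agg <- aggregate(ov ~ read + feat, data = key, FUN = sum)
      agg <- agg[agg$ov >= min_overlap, , drop = FALSE]
      if (!allow_multi_overlap && nrow(agg) > 0L) {
        nfeat <- table(agg$read)
        ambiguous <- as.integer(names(nfeat)[nfeat > 1L])
        agg <- agg[!agg$read %in% ambiguous, , drop = FALSE]
      }
      if (nrow(agg) > 0L) {
        tb <- table(factor(agg$feat, levels = seq_len(nrow(features))))
        counts <- as.integer(tb)
      }
    }
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_,
                                                      length(counts))
  out <- data.frame(name = features$name, ftype = features$ftype,
                    strand = features$strand, count = counts,
                    percent_of_assigned = pct, stringsAsFactors = FALSE)
  attr(out, "variant") <- if (any(features$ftype == "tRNA"))
    "trna_included" else "trna_excluded"
  attr(out, "sample_id") <- sample_id
  attr(out, "n_assignments") <- total
  class(out) <- c("feature_counts", "data.frame")
  out
}

#' Fraction of reads mapped to the mitochondrial contig
#'
#' Primary mitochondrial alignments divided by total reads (mapped to any
#' contig plus unmapped). Secondary/supplementary records are ignored.
#'
#' @param aln Alignment table.
#' @param contig Mitochondrial contig name.
#' @return A single fraction in `[0, 1]`.
#' @export
mito_mapping_fraction <- function(aln, contig = "chrMT") {
  primary <- !aln$secondary & !aln$supplementary
  n_total <- sum(primary)
  if (n_total == 0L) stop("empty alignment stream")
  sum(primary & !aln$unmapped & aln$rname %in% contig) / n_total
}

#' Per-strand normalized coverage histogram for long reads
#'
#' Long reads carry their transcript strand directly from the alignment
#' orientation (single-stranded cDNA; no mate logic): a read aligned to the
#' heavy reference strand is a heavy transcript. Depth is accumulated per
#' aligned block, optionally binned, and both strands are divided by the
#' single sample-wide maximum.
#'
#' @param aln Alignment table.
#' @param genome A [mito_genome()].
#' @param convention A `strand_convention`.
#' @param bin_size Bin width in bp (depth averaged within bins; default 1).
#' @param count_multimappers Include NH > 1 records.
#' @param contig Mitochondrial contig name.
#' @param sample_id Sample label.
#' @return A `strand_coverage` object (binned when `bin_size > 1`, with a
#'   `bin_size` field).
#' @export
strand_histogram <- function(aln, genome, convention, bin_size = 1L,
                             count_multimappers = FALSE,
                             contig = genome$contig_name,
                             sample_id = "sample") {
  keep <- .longread_include(aln, contig, count_multimappers)
  sub <- aln[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    warning("no mitochondrial long reads for sample '", sample_id, "'")
  labels <- ifelse(sub$strand == convention$heavy_reference_strand,
                   "heavy", "light")
  depth <- .strand_depth(sub, labels, genome$length)
  if (bin_size > 1L) {
    bin <- function(v) {
      grp <- (seq_along(v) - 1L) %/% bin_size
      as.numeric(tapply(v, grp, mean))
    }
    depth <- lapply(depth, bin)
  }
  m <- max(depth$light, depth$heavy)
  nl <- if (m > 0) depth$light / m else depth$light
  nh <- if (m > 0) depth$heavy / m else depth$heavy
  structure(list(sample_id = sample_id, contig = contig,
                 light = depth$light, heavy = depth$heavy,
                 normalized_light = nl, normalized_heavy = nh,
                 max_depth = m, bin_size = as.integer(bin_size)),
            class = "strand_coverage")
}

#' Write a feature-count table to TSV
#' @param fc A `feature_counts` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_counts <- function(fc, path) {
  df <- as.data.frame(fc)
  df$sample_id <- attr(fc, "sample_id")
  df$variant <- attr(fc, "variant")
  .write_tsv(df, path)
}
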