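## A-to-I editing analysis: transcript-sense pileups from long-read RIP-seq,
## cataloging of partial-G candidate positions, cross-referencing against
## DNA replicate evidence (the DNA-A rule), and global A/G composition
## summaries at reference-A positions.
##
## ADAR converts adenosine to inosine in dsRNA; inosine is read as G by
## sequencers, so editing appears as an A>G mismatch in RNA that is absent
## from DNA. Genomic variants and heteroplasmy must be excluded before an
## RNA-level A/G mixture is attributed to editing.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", del = "del")

#' Build a transcript-sense pileup from long-read alignments
#'
#' Bases are counted in transcript-sense space: SAM stores bases in
#' forward-reference space, so when the sense strand is `"-"` every base is
#' complemented. In that space an A-to-G edit on the transcript appears as
#' G in the pileup column regardless of read orientation. Records are
#' filtered as in the long-read counter (primary, mapped, unique).
#' Deletions are counted in the `del` column; insertions are skipped.
#'
#' @param aln Alignment table ([read_alignments()]).
#' @param genome A [mito_genome()].
#' @param convention A `strand_convention`; the default sense strand is the
#'   heavy reference strand (the annotated sense of RNR1/RNR2).
#' @param region Optional 1-based inclusive `c(start, end)` window.
#' @param sense `"+"`/`"-"`; overrides the convention-derived sense.
#' @param contig Mitochondrial contig name.
#' @return A data frame of class `mtdsrna_pileup` with columns `position`
#'   (1-based), `A`, `C`, `G`, `T`, `del`, `depth`; attribute `sense`.
#' @export
build_pileup <- function(aln, genome, convention, region = NULL,
                         sense = NULL, contig = genome$contig_name) {
  if (is.null(sense)) sense <- convention$heavy_reference_strand
  sense <- match.arg(sense, c("+", "-"))
  if (is.null(region)) region <- c(1L, genome$length)
  if (region[1] < 1L || region[2] > genome$length || region[1] > region[2])
    stop("region out of bounds for genome of length ", genome$length)
  keep <- .longread_include(aln, contig, count_multimappers = FALSE) &
    !aln$duplicate
  sub <- aln[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = region[2] - region[1] + 1L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  if (nrow(sub) > 0L) {
    ## lay each read's bases onto reference space: deletions become "-",
    ## insertions and clips are dropped
    ref_seq <- GenomicAlignments::sequenceLayer(
      Biostrings::DNAStringSet(sub$seq), sub$cigar,
      from = "query", to = "reference")
    chars <- strsplit(as.character(ref_seq), "", fixed = TRUE)
    npos <- lengths(chars)
    posv <- unlist(Map(function(p, n) seq.int(p, length.out = n),
                       sub$pos, npos), use.names = FALSE)
    basev <- unlist(chars, use.names = FALSE)
    inside <- posv >= region[1] & posv <= region[2]
    posv <- posv[inside]
    basev <- basev[inside]
    basev[basev == "-"] <- "del"
    ok <- basev %in% colnames(counts)
    if (any(ok)) {
      tb <- table(factor(posv[ok], levels = region[1]:region[2]),
                  factor(basev[ok], levels = colnames(counts)))
      counts <- matrix(as.integer(tb), nrow = nrow(tb),
                       dimnames = list(NULL, colnames(counts)))
    }
  }
  if (sense == "-") {
    counts <- counts[, .COMPLEMENT[colnames(counts)], drop = FALSE]
    colnames(counts) <- c("A", "C", "G", "T", "del")
  }
  out <- data.frame(position = region[1]:region[2], counts)
  out$depth <- rowSums(counts)
  attr(out, "sense") <- sense
  attr(out, "contig") <- contig
  class(out) <- c("mtdsrna_pileup", "data.frame")
  out
}

#' Catalog candidate partial-G positions across RNA replicates
#'
#' A position is a candidate in a replicate when its G fraction among A/G
#' bases, `g_fraction = G / (A + G)`, lies strictly inside
#' `(min_frac, max_frac)` and the A+G depth is at least `min_depth`. All-G
#' positions are presumed genomic G; fractions at or below the floor are
#' treated as noise.
#'
#' @param pileups Named list of `mtdsrna_pileup` data frames, one per RNA
#'   replicate.
#' @param min_depth Minimum A+G depth (default 10).
#' @param min_frac,max_frac Open-interval bounds on `g_fraction`
#'   (defaults 0.05 and 0.95).
#' @return A data frame with columns `replicate`, `position`, `A`, `C`,
#'   `G`, `T`, `depth`, `ag_depth`, `g_fraction`.
#' @export
catalog_candidate_sites <- function(pileups, min_depth = 10L,
                                    min_frac = 0.05, max_frac = 0.95) {
  if (is.null(names(pileups)))
    names(pileups) <- paste0("rep", seq_along(pileups))
  rows <- lapply(names(pileups), function(id) {
    p <- pileups[[id]]
    ag <- p$A + p$G
    gf <- ifelse(ag > 0, p$G / ag, NA_real_)
    sel <- !is.na(gf) & ag >= min_depth & gf > min_frac & gf < max_frac
    if (!any(sel)) return(NULL)
    data.frame(replicate = id, position = p$position[sel],
               A = p$A[sel], C = p$C[sel], G = p$G[sel], T = p$T[sel],
               depth = p$depth[sel], ag_depth = ag[sel],
               g_fraction = gf[sel], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(replicate = character(0), position = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0),
                      ag_depth = integer(0), g_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call A-to-I editing sites by RNA/DNA cross-referencing
#'
#' Candidate positions (union over RNA replicates, per
#' [catalog_candidate_sites()]) are assigned a status:
#'
#' * `genomic_variant` — any DNA replicate's major allele is not A;
#' * `heteroplasmic` — DNA major allele is A everywhere but some replicate
#'   carries a minor-allele fraction at or above `het_threshold`;
#' * `low_coverage` — DNA evidence missing at the position, or the RNA
#'   replicate shortfall is due to insufficient A+G depth;
#' * `unreproducible` — the position is a candidate in fewer than
#'   `min_replicates` RNA replicates (depth was adequate);
#' * `edited` — all DNA replicates are clean-A and the candidate criteria
#'   hold in at least `min_replicates` RNA replicates.
#'
#' `mean_edited_fraction` averages `g_fraction` over qualifying replicates.
#' Positions are reported 1-based; gene context is taken from the feature
#' interval containing the site when an annotation is supplied.
#'
#' @param pileups Named list of `mtdsrna_pileup` objects (RNA replicates).
#' @param dna A `dna_evidence` object ([make_dna_evidence()],
#'   [load_dna_fasta()], [load_dna_table()]).
#' @param het_threshold Minor-allele fraction at/above which DNA evidence is
#'   heteroplasmic (default 0.05). Consensus-FASTA evidence carries allele
#'   fraction 1.0 for the consensus base, so heteroplasmy is undetectable
#'   from consensus sequences; supply allele tables to enable this check.
#' @param min_depth,min_frac,max_frac Candidate parameters, as in
#'   [catalog_candidate_sites()].
#' @param min_replicates RNA replicates required; default all supplied.
#' @param features Optional `mito_features` annotation for gene context.
#' @return A data frame of class `editing_calls`: `position` (1-based),
#'   `gene`, one `g_fraction.<replicate>` column per RNA replicate,
#'   `mean_edited_fraction`, `n_qualifying`, `dna_summary`, `status`.
#' @export
call_editing_sites <- function(pileups, dna, het_threshold = 0.05,
                               min_depth = 10L, min_frac = 0.05,
                               max_frac = 0.95, min_replicates = NULL,
                               features = NULL) {
  if (!inherits(dna, "dna_evidence"))
    stop("call-editing requires DNA evidence (make_dna_evidence(), ",
         "load_dna_fasta() or load_dna_table())")
  if (is.null(names(pileups)))
    names(pileups) <- paste0("rep", seq_along(pileups))
  n_reps <- length(pileups)
  if (is.null(min_replicates)) min_replicates <- n_reps
  cand <- catalog_candidate_sites(pileups, min_depth = min_depth,
                                  min_frac = min_frac, max_frac = max_frac)
  positions <- sort(unique(cand$position))
  rep_ids <- names(pileups)
  gfrac <- matrix(NA_real_, nrow = length(positions), ncol = n_reps,
                  dimnames = list(NULL, rep_ids))
  agdep <- matrix(0L, nrow = length(positions), ncol = n_reps,
                  dimnames = list(NULL, rep_ids))
  qualifies <- matrix(FALSE, nrow = length(positions), ncol = n_reps,
                      dimnames = list(NULL, rep_ids))
  for (id in rep_ids) {
    p <- pileups[[id]]
    idx <- match(positions, p$position)
    cov <- !is.na(idx)
    ag <- p$A[idx[cov]] + p$G[idx[cov]]
    agdep[cov, id] <- ag
    gfrac[cov, id] <- ifelse(ag > 0, p$G[idx[cov]] / ag, NA_real_)
    ci <- cand[cand$replicate == id, ]
    qualifies[, id] <- positions %in% ci$position
  }
  sense <- attr(pileups[[1]], "sense")
  if (is.null(sense)) sense <- "+"
  dna_eval <- dna_alleles_at(dna, positions, sense = sense)
  res <- lapply(seq_along(positions), function(i) {
    de <- dna_eval[dna_eval$position == positions[i], , drop = FALSE]
    dna_summary <- paste(sprintf("%s:%s(%.2f)", de$replicate_id, de$major,
                                 de$major_fraction), collapse = ";")
    nq <- sum(qualifies[i, ])
    if (anyNA(de$major)) {
      status <- "low_coverage"
      dna_summary <- paste0(dna_summary, ";missing_dna_coverage")
    } else if (any(de$major != "A")) {
      status <- "genomic_variant"
    } else if (any(1 - de$major_fraction >= het_threshold)) {
      status <- "heteroplasmic"
    } else if (nq < min_replicates) {
      status <- if (any(!qualifies[i, ] & agdep[i, ] < min_depth))
        "low_coverage" else "unreproducible"
    } else {
      status <- "edited"
    }
    mean_frac <- if (nq > 0) mean(gfrac[i, qualifies[i, ]]) else NA_real_
    data.frame(position = positions[i],
               gene = .gene_context(positions[i], features),
               t(setNames(gfrac[i, ], paste0("g_fraction.", rep_ids))),
               mean_edited_fraction = mean_frac, n_qualifying = nq,
               dna_summary = dna_summary, status = status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(position = integer(0), gene = character(0),
               mean_edited_fraction = numeric(0), n_qualifying = integer(0),
               dna_summary = character(0), status = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("editing_calls", "data.frame")
  out
}

#' Base composition of RNA reads at reference-A positions
#'
#' Percentages of A/C/G/T among RNA read bases (transcript-sense space) at
#' positions whose DNA or reference base is A. With DNA evidence supplied,
#' reference-A positions are those where every DNA replicate's major allele
#' is A; otherwise the genome sequence is used (complemented when the
#' pileup's sense strand is `"-"`). Deletions are excluded so the four
#' percentages sum to 100.
#'
#' @param pileup A `mtdsrna_pileup` data frame.
#' @param genome A [mito_genome()]; used when `dna` is `NULL`.
#' @param dna Optional `dna_evidence`.
#' @param sample_id Sample label.
#' @return A one-row data frame: `sample_id`, `n_positions`, `percent_A`,
#'   `percent_C`, `percent_G`, `percent_T`.
#' @export
composition_summary <- function(pileup, genome = NULL, dna = NULL,
                                sample_id = "sample") {
  sense <- attr(pileup, "sense")
  if (!is.null(dna)) {
    al <- dna_alleles_at(dna, pileup$position,
                         sense = if (is.null(sense)) "+" else sense)
    maj <- tapply(al$major, al$position,
                  function(m) if (anyNA(m)) NA_character_ else
                    if (all(m == "A")) "A" else "other")
    is_a <- !is.na(maj[as.character(pileup$position)]) &
      maj[as.character(pileup$position)] == "A"
  } else if (!is.null(genome)) {
    base <- substring(genome$sequence, pileup$position, pileup$position)
    if (identical(sense, "-")) base <- unname(.COMPLEMENT[base])
    is_a <- base == "A"
  } else {
    stop("composition_summary needs a genome or DNA evidence")
  }
  sel <- is_a & pileup$depth > 0
  if (!any(sel)) stop("no covered reference-A positions")
  tot <- sum(pileup$A[sel] + pileup$C[sel] + pileup$G[sel] + pileup$T[sel])
  data.frame(sample_id = sample_id, n_positions = sum(sel),
             percent_A = 100 * sum(pileup$A[sel]) / tot,
             percent_C = 100 * sum(pileup$C[sel]) / tot,
             percent_G = 100 * sum(pileup$G[sel]) / tot,
             percent_T = 100 * sum(pileup$T[sel]) / tot,
             stringsAsFactors = FALSE)
}

#' Write editing calls to TSV
#' @param calls An `editing_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editing_calls <- function(calls, path) {
  .write_tsv(as.data.frame(calls), path)
}

#' Write editing calls as a minimal VCF-like report
#'
#' One line per site: `CHROM POS ID REF ALT QUAL FILTER INFO`, `REF=A`,
#' `ALT=G`, INFO carrying the mean edited fraction, replicate count and
#' status. Sites with non-`edited` status carry their status as FILTER.
#'
#' @param calls An `editing_calls` data frame.
#' @param path Output path.
#' @param contig Contig name for CHROM.
#' @return `path`, invisibly.
#' @export
write_editing_vcf <- function(calls, path, contig = "chrMT") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mtdsrna",
           "##INFO=<ID=MEANF,Number=1,Type=Float,Description=\"Mean edited fraction over qualifying RNA replicates\">",
           "##INFO=<ID=NREP,Number=1,Type=Integer,Description=\"Qualifying RNA replicates\">",
           "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Call status\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\tA\tG\t.\t%s\tMEANF=%s;NREP=%d;STATUS=%s",
                  contig, calls$position,
                  ifelse(calls$status == "edited", "PASS", calls$status),
                  ifelse(is.na(calls$mean_edited_fraction), ".",
                         sprintf("%.4f", calls$mean_edited_fraction)),
                  calls$n_qualifying, calls$status)
  writeLines(c(hdr, body), path)
  invisible(path)
}
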