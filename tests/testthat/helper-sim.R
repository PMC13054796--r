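# Shared fixtures, built in code at test time.

# toy genome/annotation at full length, built once per test run
.toy_cache <- new.env(parent = emptyenv())
toy16k <- function() {
  if (is.null(.toy_cache$toy)) .toy_cache$toy <- make_toy_genome(1L)
  .toy_cache$toy
}

toy_convention <- function() derive_strand_convention(toy16k()$features)

# write a sim_reads object to SAM and read it back as an alignment table
sim_to_aln <- function(sim) {
  sam <- tempfile(fileext = ".sam")
  write_sam(sim, sam)
  read_alignments(sam)
}

# hand-crafted SAM from a record table; missing columns get defaults
craft_rec <- function(qname, flag, rname, pos, cigar, seq, mapq = 60L,
                      nh = 1L, rnext = "*", pnext = 0L, tlen = 0L) {
  if (length(qname) == 0L)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      nh = integer(0), stringsAsFactors = FALSE))
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, nh = nh, stringsAsFactors = FALSE)
}

craft_sam <- function(records, seqinfo = c(chrMT = 16569L, nuc1 = 50000L)) {
  sam <- tempfile(fileext = ".sam")
  write_sam(records, sam, seqinfo = seqinfo)
  sam
}

# n reference-A positions (1-based) inside a named feature, spread out and
# away from the feature edges (reads are placed within the feature, so
# coverage tapers over the outermost read-length; margin keeps full depth)
a_positions_in <- function(toy, feature, n, min_gap = 20L, margin = 310L) {
  f <- toy$features[toy$features$name == feature, ]
  lo <- f$start + margin
  hi <- f$end - margin
  stopifnot(hi > lo)
  ch <- strsplit(substring(toy$genome$sequence, lo + 1L, hi), "")[[1]]
  pos <- lo + which(ch == "A")  # 1-based
  picked <- integer(0)
  for (p in pos) {
    if (length(picked) == 0L || p - picked[length(picked)] >= min_gap)
      picked <- c(picked, p)
    if (length(picked) == n) break
  }
  stopifnot(length(picked) == n)
  picked
}

# brute-force oracle: loop over every read x feature pair, intersecting the
# read's (single-block) interval with the feature interval
brute_feature_counts <- function(aln, features, min_overlap = 6L,
                                 allow_multi_overlap = TRUE) {
  keep <- !aln$unmapped & !aln$secondary & !aln$supplementary &
    aln$rname == "chrMT" & (is.na(aln$nh) | aln$nh == 1L)
  sub <- aln[keep, , drop = FALSE]
  len <- as.integer(sub("M$", "", sub$cigar))
  counts <- integer(nrow(features))
  for (i in seq_len(nrow(sub))) {
    rs <- sub$pos[i] - 1L            # 0-based
    re <- rs + len[i]
    hits <- integer(0)
    for (j in seq_len(nrow(features))) {
      ov <- min(re, features$end[j]) - max(rs, features$start[j])
      if (ov >= min_overlap) hits <- c(hits, j)
    }
    if (!allow_multi_overlap && length(hits) > 1L) next
    counts[hits] <- counts[hits] + 1L
  }
  counts
}

# three RIP-seq replicate pileups over RNR2 with per-replicate edit sites
rip_replicates <- function(seeds, sites_list, n_long_reads = 2000L,
                           f_light = 0.3) {
  toy <- toy16k()
  conv <- toy_convention()
  w <- list(light = c(RNR2 = 1), heavy = c(RNR2 = 1))
  out <- list(pileups = list(), truths = list())
  for (i in seq_along(seeds)) {
    cfg <- sim_config(seed = seeds[i], n_long_reads = n_long_reads,
                      f_light = f_light, region_weights = w)
    rip <- simulate_rip_longreads(cfg, toy$genome, toy$features)
    if (!is.null(sites_list[[i]]) && nrow(sites_list[[i]]) > 0)
      rip <- inject_editing(rip, sites_list[[i]], toy$genome,
                            seed = seeds[i])
    out$pileups[[paste0("rna", i)]] <-
      build_pileup(sim_to_aln(rip), toy$genome, conv)
    out$truths[[paste0("rna", i)]] <- rip$truth
  }
  out
}
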