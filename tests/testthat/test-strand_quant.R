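make_filter_fixture <- function() {
  seqs <- strrep("A", 50)
  recs <- rbind(
    craft_rec("ok",    99L,  "chrMT", 100L, "50M", seqs, nh = 1L,
              rnext = "=", pnext = 300L, tlen = 250L),
    craft_rec("ok",    147L, "chrMT", 300L, "50M", seqs, nh = 1L,
              rnext = "=", pnext = 100L, tlen = -250L),
    craft_rec("sec",   355L, "chrMT", 500L, "50M", seqs, nh = 1L),
    craft_rec("multi", 99L,  "chrMT", 700L, "50M", seqs, nh = 3L,
              rnext = "=", pnext = 900L, tlen = 250L),
    craft_rec("dup",   1123L, "chrMT", 1100L, "50M", seqs, nh = 1L,
              rnext = "=", pnext = 1300L, tlen = 250L),
    craft_rec("improper", 65L, "chrMT", 1500L, "50M", seqs, nh = 1L,
              rnext = "=", pnext = 1700L, tlen = 0L),
    craft_rec("mapq0", 0L, "chrMT", 1900L, "50M", seqs, mapq = 0L,
              nh = NA_integer_),
    craft_rec("mapq0nh1", 16L, "chrMT", 2100L, "50M", seqs, mapq = 0L,
              nh = 1L),
    craft_rec("unmapped", 4L, "*", NA_integer_, "*", seqs,
              mapq = 0L, nh = NA_integer_))
  read_alignments(craft_sam(recs))
}

test_that("passes_filters enforces primary/unique/proper/duplicate rules", {
  aln <- make_filter_fixture()
  ok <- passes_filters(aln)
  got <- setNames(ok, aln$qname)
  expect_true(all(got[names(got) == "ok"]))
  expect_false(got[["sec"]])        # secondary
  expect_false(got[["multi"]])      # NH = 3
  expect_false(got[["dup"]])        # duplicate flag
  expect_false(got[["improper"]])   # paired but not proper
  expect_false(got[["mapq0"]])      # no NH tag, mapq < min_mapq
  expect_true(got[["mapq0nh1"]])    # NH tag overrides mapq
  expect_false(got[["unmapped"]])
  # relaxing proper-pair requirement admits the improper pair
  ok2 <- passes_filters(aln, filter_config(require_proper = FALSE))
  expect_true(setNames(ok2, aln$qname)[["improper"]])
})

test_that("transcript strand inference follows protocol and mate rank", {
  conv <- toy_convention()  # heavy = "+"
  one <- function(strand, read2, paired = TRUE) {
    data.frame(strand = strand, read2 = read2, paired = paired)
  }
  # RF: read1 aligns antisense -> read1 on plus = transcript minus = light
  expect_equal(infer_transcript_strand(one("+", FALSE), "RF", conv), "light")
  # FR flips the protocol
  expect_equal(infer_transcript_strand(one("+", FALSE), "FR", conv), "heavy")
  # read2 is the orientation complement of read1
  expect_equal(infer_transcript_strand(one("+", TRUE), "RF", conv), "heavy")
  expect_equal(infer_transcript_strand(one("-", TRUE), "RF", conv), "light")
  # strict mode rejects single-end records
  expect_error(
    infer_transcript_strand(one("+", FALSE, paired = FALSE), "RF", conv,
                            strict_paired = TRUE),
    "single-end")
})

test_that("mates of one fragment always agree on the transcript strand", {
  toy <- toy16k()
  conv <- toy_convention()
  cfg <- sim_config(seed = 5, n_fragments = 500, f_light = 0.4)
  sim <- simulate_stranded_reads(cfg, toy$genome, toy$features)
  aln <- sim_to_aln(sim)
  for (proto in c("RF", "FR")) {
    lab <- infer_transcript_strand(aln, proto, conv)
    per_frag <- tapply(lab, aln$qname, function(x) length(unique(x)))
    expect_true(all(per_frag == 1L))
  }
  # and the inferred labels equal the simulator's truth under RF
  lab <- infer_transcript_strand(aln, "RF", conv)
  truth <- sim$truth$per_fragment
  got <- as.character(tapply(lab, aln$qname, unique)[truth$qname])
  expect_equal(got, truth$strand_label)
})

test_that("count_strands matches simulator truth and is order-independent", {
  toy <- toy16k()
  conv <- toy_convention()
  cfg <- sim_config(seed = 9, n_fragments = 2000, f_light = 0.25,
                    decoy_fraction = 0.2, n_unmapped = 30L)
  sim <- simulate_stranded_reads(cfg, toy$genome, toy$features)
  aln <- sim_to_aln(sim)
  cs <- count_strands(aln, "RF", conv)
  expect_equal(cs$f_light, sim$truth$realized_f_light)
  expect_equal(cs$n_mito, sim$truth$n_mito)
  expect_equal(cs$n_light + cs$n_heavy, cs$n_mito)
  expect_equal(cs$n_unmapped, 30L)
  expect_lte(cs$n_mito, cs$n_mapped_total)
  # order independence
  shuffled <- aln[sample.int(nrow(aln)), , drop = FALSE]
  class(shuffled) <- class(aln)
  cs2 <- count_strands(shuffled, "RF", conv)
  expect_equal(as.data.frame(cs2), as.data.frame(cs))
  # counting both mates doubles every fragment count
  cs3 <- count_strands(aln, "RF", conv, count_mates_separately = TRUE)
  expect_equal(cs3$n_light, 2L * cs$n_light)
  expect_equal(cs3$f_light, cs$f_light)
})

test_that("degenerate inputs: all-heavy mixture and empty stream", {
  toy <- toy16k()
  conv <- toy_convention()
  cfg <- sim_config(seed = 2, n_fragments = 10, f_light = 0)
  sim <- simulate_stranded_reads(cfg, toy$genome, toy$features)
  cs <- count_strands(sim_to_aln(sim), "RF", conv)
  expect_equal(cs$f_light, 0)
  expect_equal(cs$n_heavy, 10L)

  empty_sam <- craft_sam(craft_rec(character(0), integer(0), character(0),
                                   integer(0), character(0), character(0)))
  aln0 <- read_alignments(empty_sam)
  expect_warning(cs0 <- count_strands(aln0, "RF", conv), "no mitochondrial")
  expect_true(is.na(cs0$f_light))
  acc <- read_accounting(aln0)
  expect_equal(unlist(acc), c(n_total = 0L, n_mapped = 0L, n_unmapped = 0L,
                              n_mito = 0L))
})

test_that("read accounting partitions mapped and unmapped records", {
  seqs <- strrep("C", 30)
  recs <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      craft_rec(paste0("m", i), 0L, "chrMT", i * 100L, "30M", seqs))),
    do.call(rbind, lapply(1:3, function(i)
      craft_rec(paste0("u", i), 4L, "*", NA_integer_, "*", seqs,
                mapq = 0L, nh = NA_integer_))))
  aln <- read_alignments(craft_sam(recs))
  acc <- read_accounting(aln)
  expect_equal(acc$n_total, 8L)
  expect_equal(acc$n_mapped, 5L)
  expect_equal(acc$n_unmapped, 3L)
  expect_equal(acc$n_mito, 5L)
})

test_that("mito share of mapped fragments recovers the decoy split", {
  toy <- toy16k()
  cfg <- sim_config(seed = 21, n_fragments = 4000, decoy_fraction = 0.8)
  sim <- simulate_stranded_reads(cfg, toy$genome, toy$features)
  aln <- sim_to_aln(sim)
  acc <- read_accounting(aln)
  frac <- acc$n_mito / (acc$n_mapped / 2)   # records -> fragments
  sigma <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(abs(frac - 0.2), 3 * sigma)
})

test_that("per-base coverage matches hand-computed pileups", {
  toy <- toy16k()
  conv <- toy_convention()
  seq100 <- substring(toy$genome$sequence, 1001, 1100)
  # single-end plus-strand read under RF = light transcript
  one <- read_alignments(craft_sam(
    craft_rec("r1", 0L, "chrMT", 1001L, "100M", seq100)))
  cov <- per_base_coverage(one, toy$genome, "RF", conv)
  expect_equal(sum(cov$light), 100)
  expect_equal(sum(cov$heavy), 0)
  expect_equal(max(cov$normalized_light), 1)
  expect_equal(unique(cov$light[1001:1100]), 1)

  # two light reads overlapping by 50 nt: plateau 2 -> 1.0, flanks 0.5
  two <- read_alignments(craft_sam(rbind(
    craft_rec("a", 0L, "chrMT", 1001L, "100M", seq100),
    craft_rec("b", 0L, "chrMT", 1051L,
              "100M", substring(toy$genome$sequence, 1051, 1150)))))
  cov2 <- per_base_coverage(two, toy$genome, "RF", conv)
  expect_equal(unique(cov2$normalized_light[1051:1100]), 1)
  expect_equal(unique(cov2$normalized_light[1001:1050]), 0.5)
  expect_equal(unique(cov2$normalized_light[1101:1150]), 0.5)
  # conservation: aligned bases on the light strand
  expect_equal(sum(cov2$light), 200)

  # all-zero coverage warns
  empty <- read_alignments(craft_sam(craft_rec(character(0), integer(0),
                                               character(0), integer(0),
                                               character(0), character(0))))
  expect_warning(cov0 <- per_base_coverage(empty, toy$genome, "RF", conv),
                 "all-zero")
  expect_equal(max(cov0$normalized_light, cov0$normalized_heavy), 0)
})

test_that("light coverage peaks inside the rRNA intervals when simulated so", {
  toy <- toy16k()
  conv <- toy_convention()
  w <- list(light = c(RNR1 = 1, RNR2 = 2))  # light antisense to the rRNAs
  cfg <- sim_config(seed = 13, n_fragments = 3000, f_light = 0.3,
                    region_weights = w)
  sim <- simulate_stranded_reads(cfg, toy$genome, toy$features)
  cov <- per_base_coverage(sim_to_aln(sim), toy$genome, "RF", conv)
  rr <- toy$features[toy$features$ftype == "rRNA", ]
  inside <- unlist(Map(function(s, e) (s + 1):e, rr$start, rr$end))
  expect_true(which.max(cov$normalized_light) %in% inside)
  expect_equal(max(cov$normalized_light[inside]),
               max(cov$normalized_light))
})

test_that("protocol and convention symmetries swap counts exactly", {
  toy <- toy16k()
  conv <- toy_convention()
  cfg <- sim_config(seed = 31, n_fragments = 1500, f_light = 0.35)
  aln <- sim_to_aln(simulate_stranded_reads(cfg, toy$genome, toy$features))
  rf <- count_strands(aln, "RF", conv)
  fr <- count_strands(aln, "FR", conv)
  expect_equal(fr$n_light, rf$n_heavy)
  expect_equal(fr$n_heavy, rf$n_light)
  flipped <- derive_strand_convention(within(toy$features, {
    strand <- ifelse(strand == "+", "-", "+")
  }))
  flip <- count_strands(aln, "RF", flipped)
  expect_equal(flip$n_light, rf$n_heavy)
  expect_equal(flip$n_heavy, rf$n_light)
})
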