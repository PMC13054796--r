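test_that("pileup counts hand-crafted columns in transcript-sense space", {
  toy <- toy16k()
  conv <- toy_convention()
  p <- attr(toy$genome, "editing_ref_position")  # reference A, 2617
  seqat <- function(q, n) substring(toy$genome$sequence, q, q + n - 1L)
  # 10 sense (plus) reads showing the reference A
  sense <- do.call(rbind, lapply(1:10, function(i)
    craft_rec(paste0("s", i), 0L, "chrMT", p - 20L, "41M",
              seqat(p - 20L, 41))))
  pu <- build_pileup(read_alignments(craft_sam(sense)), toy$genome, conv)
  col <- pu[pu$position == p, ]
  expect_equal(col$A, 10L)
  expect_equal(col$depth, 10L)
  # 10 antisense (minus-aligned) reads of the same molecules: identical
  # columns, because bases are complemented back to transcript sense
  anti <- sense
  anti$flag <- 16L
  pu2 <- build_pileup(read_alignments(craft_sam(anti)), toy$genome, conv)
  expect_equal(pu2[pu2$position == p, c("A", "C", "G", "T")],
               col[, c("A", "C", "G", "T")], ignore_attr = TRUE)
  expect_error(build_pileup(read_alignments(craft_sam(sense)), toy$genome,
                            conv, region = c(0, 10)), "out of bounds")
})

test_that("pileup agrees with the Rsamtools pileup oracle", {
  toy <- toy16k()
  conv <- toy_convention()
  w <- list(light = c(RNR2 = 1), heavy = c(RNR2 = 1))
  sites <- data.frame(position = a_positions_in(toy16k(), "RNR2", 3),
                      rate = c(0.1, 0.3, 0.8))
  cfg <- sim_config(seed = 17, n_long_reads = 400, f_light = 0.3,
                    region_weights = w, editing_sites = sites)
  rip <- inject_editing(
    simulate_rip_longreads(cfg, toy$genome, toy$features),
    sites, toy$genome, seed = 17)
  sam <- tempfile(fileext = ".sam")
  write_sam(rip, sam)
  pu <- build_pileup(read_alignments(sam), toy$genome, conv)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  oracle <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(min_base_quality = 0L,
                                         min_mapq = 0L,
                                         distinguish_strands = FALSE,
                                         max_depth = 100000L))
  for (b in c("A", "C", "G", "T")) {
    ob <- oracle[oracle$nucleotide == b, ]
    want <- setNames(rep(0L, nrow(pu)), pu$position)
    want[as.character(ob$pos)] <- ob$count
    expect_equal(pu[[b]], unname(want))
  }
  # and the injected sites show their realized edited fractions exactly
  tr <- rip$truth$editing
  got <- pu[match(tr$position, pu$position), ]
  expect_equal(got$G / (got$A + got$G), tr$realized_fraction)
})

test_that("candidate cataloging applies the open-interval and depth rules", {
  mk_pileup <- function(A, G, pos = seq_along(A)) {
    out <- data.frame(position = pos, A = A, C = 0L, G = G, T = 0L,
                      del = 0L, depth = A + G)
    attr(out, "sense") <- "+"
    class(out) <- c("mtdsrna_pileup", "data.frame")
    out
  }
  pu <- mk_pileup(A = c(0L, 98L, 85L, 5L, 90L),
                  G = c(50L, 2L, 15L, 95L, 30L),
                  pos = c(10L, 20L, 30L, 40L, 50L))
  # pos 10: g = 1.0 (all G, presumed genomic) -> excluded
  # pos 20: g = 0.02 < 0.05 -> excluded; pos 30: g = 0.15 -> candidate
  # pos 40: g = 0.95 boundary, open interval -> excluded
  # pos 50: g = 0.25 -> candidate
  cand <- catalog_candidate_sites(list(r1 = pu))
  expect_equal(cand$position, c(30L, 50L))
  shallow <- mk_pileup(A = 8L, G = 1L, pos = 99L)  # depth 9 < 10
  expect_equal(nrow(catalog_candidate_sites(list(r1 = shallow))), 0L)
})

test_that("editing caller recovers injected sites and excludes confounders", {
  toy <- toy16k()
  pos <- a_positions_in(toy, "RNR2", 5)
  p_edit <- pos[1]; p_var <- pos[2]; p_het <- pos[3]; p_once <- pos[4]
  shared <- data.frame(position = c(p_edit, p_var, p_het),
                       rate = c(0.15, 0.2, 0.3))
  only_rep1 <- rbind(shared, data.frame(position = p_once, rate = 0.2))
  reps <- rip_replicates(seeds = c(401, 402, 403),
                         sites_list = list(only_rep1, shared, shared))
  dna <- make_dna_evidence(
    toy$genome,
    variants = data.frame(position = p_var, allele = "G", replicate = 2L),
    heteroplasmy = data.frame(position = p_het, minor_allele = "G",
                              fraction = 0.3, replicate = NA_integer_))
  calls <- call_editing_sites(reps$pileups, dna, features = toy$features)
  st <- setNames(calls$status, calls$position)
  expect_equal(st[[as.character(p_edit)]], "edited")
  expect_equal(st[[as.character(p_var)]], "genomic_variant")
  expect_equal(st[[as.character(p_het)]], "heteroplasmic")
  expect_equal(st[[as.character(p_once)]], "unreproducible")
  # no confounder leaks into the edited set; no false positives elsewhere
  expect_equal(calls$position[calls$status == "edited"], p_edit)
  expect_equal(calls$gene[calls$position == p_edit], "RNR2")
  # mean edited fraction matches the mean of realized per-replicate truths
  realized <- vapply(reps$truths, function(tr)
    tr$editing$realized_fraction[tr$editing$position == p_edit], numeric(1))
  expect_equal(calls$mean_edited_fraction[calls$position == p_edit],
               mean(realized))
  # relaxing min_replicates rescues the single-replicate site
  calls_any <- call_editing_sites(reps$pileups, dna, min_replicates = 1L,
                                  features = toy$features)
  expect_equal(calls_any$status[calls_any$position == p_once], "edited")
  expect_error(call_editing_sites(reps$pileups, dna = NULL),
               "DNA evidence")
})

test_that("exact recovery: called set equals injected set on clean data", {
  toy <- toy16k()
  pos <- a_positions_in(toy, "RNR2", 3)
  sites <- data.frame(position = pos, rate = c(0.2, 0.4, 0.6))
  reps <- rip_replicates(seeds = c(411, 412, 413),
                         sites_list = list(sites, sites, sites))
  calls <- call_editing_sites(reps$pileups, make_dna_evidence(toy$genome),
                              features = toy$features)
  expect_setequal(calls$position[calls$status == "edited"], pos)
  expect_equal(nrow(calls[!calls$position %in% pos, ]), 0L)
})

test_that("DNA evidence round-trips and consensus hides heteroplasmy", {
  toy <- toy16k()
  p <- a_positions_in(toy, "ND5", 2)
  dna <- make_dna_evidence(
    toy$genome,
    variants = data.frame(position = p[1], allele = "G",
                          replicate = NA_integer_),
    heteroplasmy = data.frame(position = p[2], minor_allele = "G",
                              fraction = 0.3, replicate = 2L))
  al <- dna_alleles_at(dna, p)
  expect_true(all(al$major[al$position == p[1]] == "G"))
  r2 <- al[al$position == p[2] & al$replicate_id == "dna2", ]
  expect_equal(r2$A, 0.7)
  expect_equal(r2$G, 0.3)
  expect_equal(al$A[al$position == p[2] & al$replicate_id == "dna1"], 1)

  dir <- tempfile(); files <- write_dna_evidence(dna, dir)
  tab <- load_dna_table(files$tables, toy$genome)
  expect_equal(dna_alleles_at(tab, p), al)
  cons <- load_dna_fasta(files$fasta)
  alc <- dna_alleles_at(cons, p)
  # consensus collapses the 70/30 site to fraction 1.0 for the major allele
  expect_equal(alc$major_fraction[alc$position == p[2] &
                                    alc$replicate_id == "dna2"], 1)
  expect_error(make_dna_evidence(toy$genome, heteroplasmy = data.frame(
    position = p[2], minor_allele = "G", fraction = 1.4,
    replicate = NA_integer_)), "fraction")
})

test_that("composition summary tracks editing burden and its direction", {
  toy <- toy16k()
  conv <- toy_convention()
  w <- list(light = c(RNR2 = 1), heavy = c(RNR2 = 1))
  run_at_rate <- function(seed, rate) {
    pos <- a_positions_in(toy, "RNR2", 40, min_gap = 5L)
    cfg <- sim_config(seed = seed, n_long_reads = 1500, f_light = 0.3,
                      region_weights = w)
    rip <- simulate_rip_longreads(cfg, toy$genome, toy$features)
    if (rate > 0)
      rip <- inject_editing(rip, data.frame(position = pos, rate = rate),
                            toy$genome, seed = seed)
    pu <- build_pileup(sim_to_aln(rip), toy$genome, conv,
                       region = c(1671L, 3229L))
    composition_summary(pu, genome = toy$genome)
  }
  clean <- run_at_rate(501, 0)
  expect_equal(clean$percent_G, 0)
  expect_equal(clean$percent_A, 100)
  # editing across the covered A positions: percent_G rises toward the
  # diluted rate, A falls; r vs r/2 keeps the ordering
  hi <- run_at_rate(502, 0.10)
  lo <- run_at_rate(502, 0.05)
  expect_gt(hi$percent_G, lo$percent_G)
  expect_gt(lo$percent_A, hi$percent_A)
  expect_equal(hi$percent_A + hi$percent_C + hi$percent_G + hi$percent_T,
               100)
})

test_that("editing artifacts are written as TSV and VCF-like reports", {
  toy <- toy16k()
  pos <- a_positions_in(toy, "RNR2", 1)
  sites <- data.frame(position = pos, rate = 0.3)
  reps <- rip_replicates(seeds = c(421, 422, 423),
                         sites_list = list(sites, sites, sites),
                         n_long_reads = 800)
  calls <- call_editing_sites(reps$pileups, make_dna_evidence(toy$genome),
                              features = toy$features)
  tsv <- tempfile(fileext = ".tsv")
  vcf <- tempfile(fileext = ".vcf")
  write_editing_calls(calls, tsv)
  write_editing_vcf(calls, vcf)
  tb <- read.delim(tsv)
  expect_true("status" %in% names(tb))
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(calls))
  expect_match(body[1], "^chrMT\\t\\d+\\t\\.\\tA\\tG\\t")
  expect_match(body[calls$position == pos], "STATUS=edited")
})
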