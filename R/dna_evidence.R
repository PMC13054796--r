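## DNA replicate evidence for the editing caller: either consensus
## sequences (one FASTA per replicate; allele fraction 1.0 for the
## consensus base, so heteroplasmy is undetectable) or per-position allele
## tables (observed fractions, heteroplasmy detectable).

#' Construct DNA replicate evidence from a reference genome
#'
#' Default evidence is three replicates identical to the reference. A
#' `variants` table changes the major allele at a position; a
#' `heteroplasmy` table mixes a minor allele at a given fraction.
#' Positions are 1-based; `replicate = NA` applies to all replicates.
#'
#' @param genome A [mito_genome()].
#' @param n_replicates Number of DNA replicates (default 3).
#' @param variants Optional data frame `position`, `allele`, `replicate`.
#' @param heteroplasmy Optional data frame `position`, `minor_allele`,
#'   `fraction`, `replicate`.
#' @return An object of class `dna_evidence`.
#' @export
make_dna_evidence <- function(genome, n_replicates = 3L, variants = NULL,
                              heteroplasmy = NULL) {
  reps <- lapply(seq_len(n_replicates), function(i) {
    list(replicate_id = paste0("dna", i),
         alleles = data.frame(position = integer(0), A = numeric(0),
                              C = numeric(0), G = numeric(0),
                              T = numeric(0)))
  })
  names(reps) <- vapply(reps, `[[`, "", "replicate_id")
  set_alleles <- function(rep_idx, position, fracs) {
    for (i in rep_idx) {
      al <- reps[[i]]$alleles
      al <- al[al$position != position, , drop = FALSE]
      al <- rbind(al, data.frame(position = position, A = fracs["A"],
                                 C = fracs["C"], G = fracs["G"],
                                 T = fracs["T"]))
      reps[[i]]$alleles <<- al[order(al$position), , drop = FALSE]
    }
  }
  all_reps <- seq_len(n_replicates)
  if (!is.null(variants)) {
    for (k in seq_len(nrow(variants))) {
      pos <- variants$position[k]
      if (pos < 1 || pos > genome$length) stop("variant position ", pos,
                                               " outside genome")
      fr <- setNames(numeric(4), c("A", "C", "G", "T"))
      fr[variants$allele[k]] <- 1
      idx <- if (is.na(variants$replicate[k])) all_reps else
        variants$replicate[k]
      set_alleles(idx, pos, fr)
    }
  }
  if (!is.null(heteroplasmy)) {
    for (k in seq_len(nrow(heteroplasmy))) {
      pos <- heteroplasmy$position[k]
      if (pos < 1 || pos > genome$length) stop("heteroplasmy position ", pos,
                                               " outside genome")
      f <- heteroplasmy$fraction[k]
      if (f < 0 || f > 1) stop("heteroplasmy fraction outside [0, 1]")
      refb <- substring(genome$sequence, pos, pos)
      fr <- setNames(numeric(4), c("A", "C", "G", "T"))
      fr[refb] <- 1 - f
      fr[heteroplasmy$minor_allele[k]] <- fr[heteroplasmy$minor_allele[k]] + f
      if (abs(sum(fr) - 1) > 1e-9) stop("allele fractions do not sum to 1")
      idx <- if (is.na(heteroplasmy$replicate[k])) all_reps else
        heteroplasmy$replicate[k]
      set_alleles(idx, pos, fr)
    }
  }
  structure(list(kind = "table", reference = genome$sequence,
                 length = genome$length, replicates = reps),
            class = "dna_evidence")
}

#' @export
print.dna_evidence <- function(x, ...) {
  cat(sprintf("<dna_evidence> %d replicate(s), kind '%s', %d bp reference\n",
              length(x$replicates), x$kind, x$length))
  invisible(x)
}

#' Load DNA evidence from consensus FASTA files (one per replicate)
#'
#' Consensus sequences imply allele fraction 1.0 for the consensus base at
#' every position, so heteroplasmy cannot be detected from this input;
#' supply allele tables ([load_dna_table()]) to enable the heteroplasmy
#' check.
#'
#' @param paths Character vector of FASTA paths, one replicate each.
#' @param contig Optional record name to select within each file.
#' @return A `dna_evidence` object of kind `"consensus"`.
#' @export
load_dna_fasta <- function(paths, contig = NULL) {
  reps <- lapply(seq_along(paths), function(i) {
    g <- load_genome(paths[i], contig = contig)
    list(replicate_id = paste0("dna", i), sequence = g$sequence)
  })
  names(reps) <- vapply(reps, `[[`, "", "replicate_id")
  structure(list(kind = "consensus", reference = reps[[1]]$sequence,
                 length = nchar(reps[[1]]$sequence), replicates = reps),
            class = "dna_evidence")
}

#' Load DNA evidence from allele-table TSVs (one per replicate)
#'
#' Each table has columns `position` (1-based), `A_frac`, `C_frac`,
#' `G_frac`, `T_frac`; positions absent from the table take the reference
#' base at fraction 1.0.
#'
#' @param paths Character vector of TSV paths, one replicate each.
#' @param genome A [mito_genome()] providing the reference for positions
#'   absent from the tables.
#' @return A `dna_evidence` object of kind `"table"`.
#' @export
load_dna_table <- function(paths, genome) {
  reps <- lapply(seq_along(paths), function(i) {
    tb <- read.delim(paths[i], stringsAsFactors = FALSE)
    need <- c("position", "A_frac", "C_frac", "G_frac", "T_frac")
    if (!all(need %in% names(tb)))
      stop("allele table ", paths[i], " must have columns: ",
           paste(need, collapse = ", "))
    tot <- tb$A_frac + tb$C_frac + tb$G_frac + tb$T_frac
    if (any(abs(tot - 1) > 1e-9))
      stop("allele fractions do not sum to 1 in ", paths[i])
    list(replicate_id = paste0("dna", i),
         alleles = data.frame(position = tb$position, A = tb$A_frac,
                              C = tb$C_frac, G = tb$G_frac, T = tb$T_frac))
  })
  names(reps) <- vapply(reps, `[[`, "", "replicate_id")
  structure(list(kind = "table", reference = genome$sequence,
                 length = genome$length, replicates = reps),
            class = "dna_evidence")
}

#' Per-replicate allele evidence at given positions
#'
#' @param dna A `dna_evidence` object.
#' @param positions 1-based positions.
#' @param sense `"+"` or `"-"`: strand space in which alleles are reported.
#'   DNA evidence is stored in forward-reference space; with `sense = "-"`
#'   the A/T and C/G fractions are swapped so the result is comparable to a
#'   minus-sense RNA pileup.
#' @return Data frame: `position`, `replicate_id`, `A`, `C`, `G`, `T`
#'   (fractions), `major`, `major_fraction`. `major` is `NA` where the
#'   evidence does not cover the position.
#' @export
dna_alleles_at <- function(dna, positions, sense = "+") {
  if (length(positions) == 0L)
    return(data.frame(position = integer(0), replicate_id = character(0),
                      A = numeric(0), C = numeric(0), G = numeric(0),
                      T = numeric(0), major = character(0),
                      major_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(dna$replicates, function(rep) {
    fr <- matrix(NA_real_, nrow = length(positions), ncol = 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
    covered <- positions >= 1 & positions <= dna$length
    if (any(covered)) {
      src <- if (dna$kind == "consensus") rep$sequence else dna$reference
      base <- substring(src, positions[covered], positions[covered])
      for (b in c("A", "C", "G", "T")) fr[covered, b] <- as.numeric(base == b)
      if (dna$kind != "consensus") {
        idx <- match(positions, rep$alleles$position)
        hit <- !is.na(idx)
        for (b in c("A", "C", "G", "T"))
          fr[hit, b] <- rep$alleles[[b]][idx[hit]]
      }
    }
    if (sense == "-")
      fr <- fr[, c("T", "G", "C", "A"), drop = FALSE]
    colnames(fr) <- c("A", "C", "G", "T")
    major_i <- apply(fr, 1L, function(v) if (anyNA(v)) NA_integer_ else
      which.max(v))
    data.frame(position = positions, replicate_id = rep$replicate_id,
               fr,
               major = c("A", "C", "G", "T")[major_i],
               major_fraction = vapply(seq_along(major_i), function(i)
                 if (is.na(major_i[i])) NA_real_ else fr[i, major_i[i]],
                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write DNA evidence to files
#'
#' Writes one consensus FASTA per replicate (variant major alleles
#' substituted into the reference; heteroplasmic positions collapse to the
#' major allele) and, for table evidence, one allele-table TSV per
#' replicate carrying the full fractions.
#'
#' @param dna A `dna_evidence` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_dna_evidence <- function(dna, dir, prefix = "dna") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- character(0)
  tables <- character(0)
  for (rep in dna$replicates) {
    if (dna$kind == "consensus") {
      seq <- rep$sequence
    } else {
      seq <- dna$reference
      al <- rep$alleles
      if (nrow(al) > 0) {
        major <- c("A", "C", "G", "T")[
          apply(as.matrix(al[, c("A", "C", "G", "T")]), 1L, which.max)]
        for (k in seq_len(nrow(al)))
          substring(seq, al$position[k], al$position[k]) <- major[k]
      }
    }
    fp <- file.path(dir, paste0(prefix, "_", rep$replicate_id, ".fasta"))
    write_genome_fasta(mito_genome("chrMT", seq), fp)
    fasta <- c(fasta, fp)
    if (dna$kind == "table") {
      tp <- file.path(dir, paste0(prefix, "_", rep$replicate_id,
                                  "_alleles.tsv"))
      al <- rep$alleles
      .write_tsv(data.frame(position = al$position, A_frac = al$A,
                            C_frac = al$C, G_frac = al$G, T_frac = al$T),
                 tp)
      tables <- c(tables, tp)
    }
  }
  invisible(list(fasta = fasta, tables = tables))
}
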