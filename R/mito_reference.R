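## Mitochondrial reference model: circular genome, feature annotation and the
## light/heavy strand convention used by every downstream module.

#' Construct a mitochondrial genome object
#'
#' @param contig_name Contig name as it appears in alignment files
#'   (default `"chrMT"`).
#' @param sequence Nucleotide string over `{A,C,G,T}`; `U` is converted to
#'   `T`, lower case is uppercased, anything else is an error.
#' @param circular Logical; mitochondrial genomes are circular.
#'
#' @return An object of class `mito_genome` with fields `contig_name`,
#'   `length`, `sequence`, `circular`.
#' @export
mito_genome <- function(contig_name = "chrMT", sequence, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", sequence)
  seq <- toupper(chartr("U", "T", seq))
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1L) {
    stop("non-nucleotide symbol(s) '",
         paste(unique(substring(seq, bad, bad)), collapse = "','"),
         "' at position(s) ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  if (nchar(seq) == 0L) stop("zero-length genome sequence")
  structure(
    list(contig_name = contig_name, length = nchar(seq),
         sequence = seq, circular = isTRUE(circular)),
    class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s\n", x$contig_name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Load a mitochondrial genome from FASTA
#'
#' Exactly one record is selected: by `contig` when given, otherwise the
#' first record in the file. The record name stored on the returned object
#' is the first whitespace-delimited word of the FASTA header.
#'
#' @param path Path to a FASTA file.
#' @param contig Optional record name to select.
#' @param circular Logical, default `TRUE`.
#' @return A [mito_genome()] object.
#' @export
load_genome <- function(path, contig = NULL, circular = TRUE) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ## read as raw strings: RNA-style U (converted to T in mito_genome) would
  ## be mangled by the DNA alphabet
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (is.null(contig)) {
    i <- 1L
  } else {
    i <- match(contig, nm)
    if (is.na(i)) stop("contig '", contig, "' not found in ", path,
                       " (records: ", paste(nm, collapse = ", "), ")")
  }
  mito_genome(contig_name = nm[i], sequence = as.character(ss[[i]]),
              circular = circular)
}

## documented mapping from annotation type/biotype strings (and, for BED,
## feature names) to the internal feature-type enum
.ftype_from_type <- function(type) {
  key <- tolower(type)
  out <- rep(NA_character_, length(key))
  out[key %in% c("rrna")] <- "rRNA"
  out[key %in% c("trna")] <- "tRNA"
  out[key %in% c("mrna", "gene", "cds", "exon", "protein_coding")] <- "mRNA"
  out[key %in% c("d_loop", "d-loop", "dloop")] <- "D_loop"
  out
}

.ftype_from_name <- function(name) {
  up <- toupper(sub("^MT-", "", toupper(name)))
  out <- rep(NA_character_, length(up))
  out[grepl("^RNR", up)] <- "rRNA"
  out[grepl("^T[A-Z][0-9]?$", up) | grepl("^TRN", up)] <- "tRNA"
  out[grepl("^D[-_]?LOOP", up)] <- "D_loop"
  ## the 13 protein-coding mitochondrial genes
  out[grepl("^(ND[1-6]L?|CO[X]?[1-3]|ATP[68]|CYT?B)$", up)] <- "mRNA"
  out
}

.validate_features <- function(df, genome = NULL) {
  stopifnot(all(c("feature_id", "name", "ftype", "start", "end", "strand")
                %in% names(df)))
  if (any(df$end <= df$start))
    stop("feature(s) with end <= start: ",
         paste(df$name[df$end <= df$start], collapse = ", "))
  if (any(!df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ","))
  if (any(df$start < 0))
    stop("negative feature start")
  if (!is.null(genome) && any(df$end > genome$length))
    stop("feature(s) exceeding genome bounds (length ", genome$length, "): ",
         paste(df$name[df$end > genome$length], collapse = ", "))
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mito_features", "data.frame")
  df
}

#' Load a feature annotation (GFF3 or BED)
#'
#' Both dialects are converted to the internal 0-based half-open convention:
#' GFF3 coordinates are 1-based inclusive, BED coordinates are already
#' 0-based half-open. Feature types are inferred from the GFF3 type column
#' (`rRNA`, `tRNA`, `mRNA`/`gene`/`CDS`, `D_loop`); for BED, which carries no
#' type column, from the feature name (`RNR*` = rRNA, `TRN*`/`MT-T*` = tRNA,
#' `D_LOOP` = D-loop, the 13 protein-coding gene symbols = mRNA).
#' Unrecognized types map to `mRNA` with a warning (never
#' silently to tRNA, since tRNA status changes counting results).
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param genome Optional [mito_genome()] used for bounds checking.
#' @param format `"gff3"` or `"bed"`; inferred from the extension by default.
#' @return A `mito_features` data frame with columns `feature_id`, `name`,
#'   `ftype`, `start` (0-based), `end` (exclusive), `strand` (`"+"`/`"-"`),
#'   sorted by `start`.
#' @export
load_annotation <- function(path, genome = NULL, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                     stop("cannot infer annotation format from extension '",
                          ext, "'; pass format = 'gff3' or 'bed'"))
  }
  format <- match.arg(format, c("gff3", "bed"))
  if (format == "gff3") {
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 9) stop("malformed GFF3: expected 9 columns")
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
      out <- rep(NA_character_, length(attrs))
      out[lengths(regmatches(attrs,
        gregexpr(paste0("(^|;)", key, "=[^;]*"), attrs))) > 0] <-
        sub(paste0("^.*", key, "="), "", m)
      out
    }
    nm <- attr_field(raw[[9]], "Name")
    id <- attr_field(raw[[9]], "ID")
    nm[is.na(nm)] <- id[is.na(nm)]
    nm[is.na(nm)] <- paste0("feature_", seq_len(nrow(raw)))[is.na(nm)]
    id[is.na(id)] <- nm[is.na(id)]
    ftype <- .ftype_from_type(raw[[3]])
    miss <- is.na(ftype)
    ftype[miss] <- .ftype_from_name(nm[miss])
    df <- data.frame(feature_id = id, name = nm, ftype = ftype,
                     start = as.integer(raw[[4]]) - 1L,
                     end = as.integer(raw[[5]]),
                     strand = as.character(raw[[7]]),
                     stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 6) stop("BED input needs >= 6 columns (strand required)")
    nm <- as.character(raw[[4]])
    df <- data.frame(feature_id = nm, name = nm,
                     ftype = .ftype_from_name(nm),
                     start = as.integer(raw[[2]]),
                     end = as.integer(raw[[3]]),
                     strand = as.character(raw[[6]]),
                     stringsAsFactors = FALSE)
  }
  if (anyNA(df$ftype)) {
    warning("unrecognized feature type(s) for ",
            paste(unique(df$name[is.na(df$ftype)]), collapse = ", "),
            "; mapped to mRNA")
    df$ftype[is.na(df$ftype)] <- "mRNA"
  }
  .validate_features(df, genome)
}

#' Remove tRNA features
#'
#' Reproduces the modified-annotation variant in which all tRNA genes are
#' dropped before counting; all other features and their order are kept.
#'
#' @param features A `mito_features` data frame.
#' @return The same data frame without `ftype == "tRNA"` rows.
#' @export
strip_trnas <- function(features) {
  out <- features[features$ftype != "tRNA", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(features)
  out
}

#' Derive the heavy/light strand convention from the annotation
#'
#' The heavy strand is defined operationally as the reference strand that is
#' sense to the annotated rRNA genes (RNR1/RNR2); light is its opposite.
#' This keeps light/heavy labels correct regardless of how the reference
#' FASTA is oriented.
#'
#' @param features A `mito_features` data frame containing at least one rRNA.
#' @return An object of class `strand_convention` with fields
#'   `heavy_reference_strand` and `light_reference_strand` (`"+"`/`"-"`).
#' @export
derive_strand_convention <- function(features) {
  rr <- features[features$ftype == "rRNA", , drop = FALSE]
  if (nrow(rr) == 0L) stop("annotation contains no rRNA feature; ",
                           "cannot derive the heavy-strand convention")
  s <- unique(rr$strand)
  if (length(s) != 1L)
    stop("rRNA features disagree on strand (",
         paste(paste(rr$name, rr$strand), collapse = "; "),
         "); cannot derive a strand convention")
  structure(
    list(heavy_reference_strand = s,
         light_reference_strand = if (s == "+") "-" else "+"),
    class = "strand_convention")
}

#' @export
print.strand_convention <- function(x, ...) {
  cat(sprintf("<strand_convention> heavy = '%s' strand, light = '%s' strand\n",
              x$heavy_reference_strand, x$light_reference_strand))
  invisible(x)
}

.flip_convention <- function(convention) {
  structure(list(heavy_reference_strand = convention$light_reference_strand,
                 light_reference_strand = convention$heavy_reference_strand),
            class = "strand_convention")
}

## ---- writers (used by the simulator and the CLI) ----

#' Write a genome (plus optional extra contigs) to FASTA
#' @param genome A [mito_genome()].
#' @param path Output path.
#' @param extra Optional named character vector of additional contig
#'   sequences (e.g. the nuclear decoy).
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, extra = NULL, width = 70L) {
  seqs <- c(setNames(genome$sequence, genome$contig_name), extra)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a feature annotation to GFF3
#' @param features `mito_features` data frame (0-based half-open).
#' @param path Output path.
#' @param contig Contig name for column 1.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(features, path, contig = "chrMT") {
  lines <- c("##gff-version 3",
             sprintf("%s\tmtdsrna\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     contig, features$ftype, features$start + 1L,
                     features$end, features$strand,
                     features$feature_id, features$name))
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature annotation to BED6
#' @inheritParams write_annotation_gff3
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(features, path, contig = "chrMT") {
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t%s", contig, features$start,
                     features$end, features$name, features$strand),
             path)
  invisible(path)
}

## first feature (preferring non-tRNA) containing each 1-based position
.gene_context <- function(positions_1b, features) {
  if (is.null(features)) return(rep(NA_character_, length(positions_1b)))
  vapply(positions_1b, function(p) {
    hit <- features[features$start < p & features$end >= p, , drop = FALSE]
    if (nrow(hit) == 0L) return(NA_character_)
    non_t <- hit[hit$ftype != "tRNA", , drop = FALSE]
    if (nrow(non_t) > 0L) non_t$name[1] else hit$name[1]
  }, character(1))
}
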