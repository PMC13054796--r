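## Figure-shaped outputs. Each plot function draws from a written TSV (or
## the data frame it round-trips through), never from values computed only
## inside plotting code.

#' Stacked light/heavy strand-fraction bars per sample
#' @param x A strand-counts TSV path or the data frame it contains.
#' @param file Optional output file (PDF/PNG by extension); `NULL` draws to
#'   the current device.
#' @return Invisibly, the plotted data frame.
#' @export
plot_strand_fractions <- function(x, file = NULL) {
  df <- if (is.character(x)) read.delim(x, na.strings = ".") else x
  .open_dev(file)
  on.exit(.close_dev(file))
  m <- rbind(light = df$f_light, heavy = df$f_heavy)
  graphics::barplot(m, names.arg = df$sample_id, col = c("red", "blue"),
                    ylab = "fraction of chrMT reads", las = 2,
                    legend.text = c("light", "heavy"))
  invisible(df)
}

#' Per-base strand coverage profile (heavy up, light down)
#' @param x A coverage TSV path ([write_coverage()]) or its data frame.
#' @param file Optional output file.
#' @return Invisibly, the plotted data frame.
#' @export
plot_coverage <- function(x, file = NULL) {
  df <- if (is.character(x)) read.delim(x, na.strings = ".") else x
  .open_dev(file)
  on.exit(.close_dev(file))
  graphics::plot(NA, xlim = range(c(df$start, df$end)), ylim = c(-1, 1),
                 xlab = "chrMT position", ylab = "normalized depth",
                 main = unique(df$contig)[1])
  for (s in c("heavy", "light")) {
    sub <- df[df$strand == s, ]
    sgn <- if (s == "heavy") 1 else -1
    graphics::segments(sub$start, sgn * sub$normalized_depth, sub$end,
                       sgn * sub$normalized_depth,
                       col = if (s == "heavy") "blue" else "red")
  }
  graphics::abline(h = 0, col = "grey")
  invisible(df)
}

#' Per-feature long-read count bars
#' @param x A feature-counts TSV path ([write_feature_counts()]) or its
#'   data frame.
#' @param file Optional output file.
#' @return Invisibly, the plotted data frame.
#' @export
plot_feature_counts <- function(x, file = NULL) {
  df <- if (is.character(x)) read.delim(x, na.strings = ".") else x
  .open_dev(file)
  on.exit(.close_dev(file))
  graphics::barplot(df$percent_of_assigned, names.arg = df$name, las = 2,
                    ylab = "% of assignments",
                    col = ifelse(df$ftype == "tRNA", "grey", "steelblue"))
  invisible(df)
}

#' Edited vs unedited pie for one editing site
#' @param x An editing-calls TSV path ([write_editing_calls()]) or its data
#'   frame.
#' @param position 1-based site to plot (default: the first `edited` row).
#' @param file Optional output file.
#' @return Invisibly, the mean edited fraction plotted.
#' @export
plot_editing_pie <- function(x, position = NULL, file = NULL) {
  df <- if (is.character(x)) read.delim(x, na.strings = ".") else x
  if (is.null(position)) {
    hit <- df[df$status == "edited", , drop = FALSE]
    if (nrow(hit) == 0L) stop("no edited site to plot")
    row <- hit[1, ]
  } else {
    row <- df[df$position == position, , drop = FALSE]
    if (nrow(row) == 0L) stop("position ", position, " not in table")
  }
  f <- row$mean_edited_fraction
  .open_dev(file)
  on.exit(.close_dev(file))
  graphics::pie(c(edited = f, unedited = 1 - f),
                labels = sprintf(c("edited %.1f%%", "unedited %.1f%%"),
                                 c(100 * f, 100 * (1 - f))),
                col = c("red", "black"),
                main = sprintf("position %d", row$position))
  invisible(f)
}

.open_dev <- function(file) {
  if (is.null(file)) return(invisible())
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         pdf = grDevices::pdf(file),
         png = grDevices::png(file, width = 900, height = 600),
         stop("unsupported plot format: ", ext))
}

.close_dev <- function(file) {
  if (!is.null(file)) grDevices::dev.off()
}
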