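## Quartile-based stratification of samples by light-strand fraction:
## top quartile = high mtdsRNA, bottom quartile = low, rest intermediate.

#' Stratify samples into high / intermediate / low mtdsRNA tiers
#'
#' Quartiles of the light-strand fraction are computed by linear
#' interpolation over sorted order statistics ([stats::quantile()] type 7).
#' Boundary samples are inclusive: a sample exactly at the first quartile is
#' `low`, exactly at the third quartile is `high`. Samples with `NA`
#' fractions (no mitochondrial reads) are excluded from quantile computation
#' and reported as tier `missing`. If the two quartiles coincide (no
#' spread), all non-missing samples are `intermediate` and a warning is
#' issued.
#'
#' @param fractions Named numeric vector of light-strand fractions in
#'   `[0, 1]`, one per sample; at least 4 non-missing values.
#' @return An object of class `stratification`: `q1`, `q3`, `tiers`
#'   (named character vector: `high`/`intermediate`/`low`/`missing`),
#'   `method`.
#' @export
stratify_samples <- function(fractions) {
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("fractions must be a named vector (sample ids)")
  defined <- !is.na(fractions)
  vals <- fractions[defined]
  if (length(vals) < 4L)
    stop("need at least 4 samples with defined fractions, got ",
         length(vals))
  if (any(vals < 0 | vals > 1))
    stop("fraction(s) outside [0, 1]: ",
         paste(names(vals)[vals < 0 | vals > 1], collapse = ", "))
  qs <- quantile(vals, probs = c(0.25, 0.75), type = 7, names = FALSE)
  q1 <- qs[1]
  q3 <- qs[2]
  tiers <- setNames(rep("missing", length(fractions)), names(fractions))
  if (q1 == q3) {
    warning("no spread in fractions (q1 == q3); all samples intermediate")
    tiers[defined] <- "intermediate"
  } else {
    tiers[defined] <- ifelse(vals <= q1, "low",
                             ifelse(vals >= q3, "high", "intermediate"))
  }
  structure(list(q1 = q1, q3 = q3, tiers = tiers,
                 method = "linear interpolation (quantile type 7)"),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  tb <- table(factor(x$tiers,
                     levels = c("high", "intermediate", "low", "missing")))
  cat(sprintf("<stratification> q1=%.4f q3=%.4f | high=%d int=%d low=%d%s\n",
              x$q1, x$q3, tb[["high"]], tb[["intermediate"]], tb[["low"]],
              if (tb[["missing"]] > 0)
                sprintf(" missing=%d", tb[["missing"]]) else ""))
  invisible(x)
}

#' Write a stratification result (TSV + JSON sidecar)
#'
#' @param strat A `stratification` object.
#' @param fractions The named fraction vector it was computed from.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_stratification <- function(strat, fractions, tsv_path = NULL,
                                 json_path = NULL) {
  if (!is.null(tsv_path)) {
    .write_tsv(data.frame(sample_id = names(strat$tiers),
                          f_light = fractions[names(strat$tiers)],
                          tier = unname(strat$tiers),
                          stringsAsFactors = FALSE),
               tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(q1 = strat$q1, q3 = strat$q3,
                              method = strat$method),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
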