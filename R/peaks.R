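#' Construct a peak set
#'
#' A peak set is the atom of every computation in cobindkit: a labeled,
#' sorted collection of genomic intervals, one per called peak. Coordinates
#' follow the BED convention throughout the package: 0-based inclusive
#' start, exclusive end. Duplicated records are retained (each BED record is
#' one peak).
#'
#' @param chrom Character vector of chromosome names (nonempty strings).
#' @param start,end Numeric vectors of 0-based half-open coordinates;
#'   `0 <= start < end` is enforced per record.
#' @param strand Strand per record: `"+"`, `"-"` or `"*"` (unknown). Any
#'   other value is coerced to `"*"`.
#' @param name Optional per-record name (BED column 4).
#' @param label Short label identifying the dataset (defaults used in error
#'   messages, plots and matrix headers).
#' @param source Path the peaks were read from, if any.
#' @return A `peak_set`: a data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand`, sorted by (chrom, start, end), with attributes
#'   `label` and `source`.
#' @examples
#' peak_set(c("chr1", "chr1"), c(100, 500), c(200, 900), label = "tf_chip")
#' @export
peak_set <- function(chrom, start, end, strand = "*", name = NA_character_,
                     label = "peaks", source = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  df$strand[!(df$strand %in% c("+", "-"))] <- "*"
  validate_intervals(df$chrom, df$start, df$end, context = label)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    class = c("peak_set", "data.frame"),
    label = label, source = source
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf(
    "peak_set '%s': %d peaks on %d chromosome(s)\n",
    peak_label(x), nrow(x), length(unique(x$chrom))
  ))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Label of a peak set
#' @param x A `peak_set`.
#' @return The dataset label (character scalar).
#' @export
peak_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "peaks" else lab
}

# Shared interval invariant check: nonempty chrom, 0 <= start < end.
validate_intervals <- function(chrom, start, end, context = "interval set") {
  if (!length(chrom)) {
    return(invisible(TRUE))
  }
  bad <- which(is.na(chrom) | !nzchar(chrom))
  if (length(bad)) {
    stop(context, ": empty chromosome name at record ", bad[1])
  }
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(
      context, ": invalid coordinates at record ", bad[1],
      " (need 0 <= start < end, got start=", start[bad[1]],
      ", end=", end[bad[1]], ")"
    )
  }
  invisible(TRUE)
}

# Warn (once per call site) when two interval sets share no chromosome
# names: almost always a naming-convention mismatch ("chr1" vs "1"), which
# we refuse to paper over by prefix munging.
warn_if_no_shared_chroms <- function(chrom_a, chrom_b, label_a, label_b) {
  if (length(chrom_a) && length(chrom_b) &&
    !length(intersect(unique(chrom_a), unique(chrom_b)))) {
    warning(
      "'", label_a, "' and '", label_b, "' share no chromosome names; ",
      "check naming conventions (e.g. 'chr1' vs '1')",
      call. = FALSE
    )
  }
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# GRanges from 0-based half-open columns, with shared seqlevels so that
# findOverlaps never sees mismatched levels.
as_granges0 <- function(chrom, start, end, levels = sort(unique(chrom))) {
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = levels),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
}

fmt_coord <- function(x) sprintf("%.0f", x)
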