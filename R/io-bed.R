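#' Read a peak-called BED file
#'
#' Parses BED3-BED6 (tab-separated). Track, browser and `#` comment lines
#' are skipped. Columns beyond 6 are ignored: the analyses in this package
#' consume only peak locations (and strand, in the optional strand-aware
#' mode), never scores.
#'
#' Coordinates are kept in BED's native 0-based half-open convention.
#' Strand is taken from column 6 when present (`+`/`-`); anything else,
#' including absent, is "unknown" (`*`).
#'
#' Malformed records — fewer than 3 fields, non-integer coordinates, or
#' `start >= end` — raise an error naming the file and line number. A file
#' with no data records returns an empty `peak_set`; pipeline entry points
#' reject empty inputs explicitly rather than succeeding silently.
#'
#' @param path Path to a BED file.
#' @param label Dataset label; defaults to the file name without extension.
#' @return A [peak_set()].
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(label)) {
    label <- sub("\\.(bed|narrowPeak|broadPeak|txt)$", "",
      basename(path),
      ignore.case = TRUE
    )
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^(#|track([ \t]|$)|browser([ \t]|$))", lines) &
    nzchar(trimws(lines))
  data_idx <- which(is_data)
  if (!length(data_idx)) {
    return(peak_set(character(), numeric(), numeric(),
      label = label, source = path
    ))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: expected at least 3 tab-separated fields, found %d",
      path, data_idx[bad[1]], nf[bad[1]]
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  bad <- which(!grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr))
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: non-integer coordinates '%s'..'%s'",
      path, data_idx[bad[1]], start_chr[bad[1]], end_chr[bad[1]]
    ))
  }
  start <- as.numeric(start_chr)
  end <- as.numeric(end_chr)
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: start (%s) must be less than end (%s)",
      path, data_idx[bad[1]], start_chr[bad[1]], end_chr[bad[1]]
    ))
  }
  bad <- which(!nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("%s: line %d: empty chromosome name", path, data_idx[bad[1]]))
  }
  name <- vapply(fields, function(f) {
    if (length(f) >= 4L) f[[4L]] else NA_character_
  }, character(1))
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L) f[[6L]] else "*"
  }, character(1))
  peak_set(chrom, start, end,
    strand = strand, name = name,
    label = label, source = path
  )
}

#' Write intervals as a BED file
#'
#' Writes BED3 when no record carries a name or strand, BED6 otherwise
#' (score column fixed at 0; unknown strand written as `.`). Coordinates
#' round-trip exactly through [read_bed()]. An empty collection yields an
#' empty, header-free file.
#'
#' @param x A `peak_set` or data.frame with columns `chrom`, `start`, `end`
#'   and optionally `name`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (!nrow(x)) {
    ok <- file.create(path)
    if (!ok) stop("cannot write BED file: ", path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else rep(NA_character_, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep("*", nrow(x))
  has_meta <- any(!is.na(name) & nzchar(name)) || any(strand %in% c("+", "-"))
  lines <- if (has_meta) {
    paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
      ifelse(is.na(name) | !nzchar(name), ".", name),
      "0",
      ifelse(strand %in% c("+", "-"), strand, "."),
      sep = "\t"
    )
  } else {
    paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end), sep = "\t")
  }
  tryCatch(writeLines(lines, path),
    error = function(e) stop("cannot write BED file ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}
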