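#' Map peaks into genomic bins
#'
#' Splits the genome into fixed-width bins (bin index `i` covers
#' `[i * bin_size, (i + 1) * bin_size)`) and records which bins each
#' dataset occupies. A peak occupies every bin it overlaps by at least one
#' base pair, so a long peak spanning k bins occupies all k; occupancy is a
#' set, so multiple peaks in one bin count once. No chromosome-length file
#' is needed: indices derive from coordinates alone.
#'
#' @param peaks A [peak_set()] (or data.frame with `chrom`, `start`, `end`).
#' @param bin_size Bin width in bp (the "scope" of the exploration stage);
#'   default 1000.
#' @return A `bin_occupancy`: list with `bin_size` and `occupied`, a
#'   mapping chromosome -> sorted vector of occupied bin indices.
#' @export
bin_peaks <- function(peaks, bin_size = 1000) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || is.na(bin_size) ||
    bin_size <= 0) {
    stop("bin_size must be a single positive number of base pairs")
  }
  occupied <- list()
  if (nrow(peaks)) {
    first <- as.integer(peaks$start %/% bin_size)
    last <- as.integer((peaks$end - 1) %/% bin_size)
    n_bins <- last - first + 1L
    bins <- sequence(n_bins, from = first)
    chrom <- rep(peaks$chrom, n_bins)
    occupied <- lapply(split(bins, chrom), function(b) sort(unique(b)))
  }
  structure(list(bin_size = bin_size, occupied = occupied),
    class = "bin_occupancy"
  )
}

#' @export
print.bin_occupancy <- function(x, ...) {
  cat(sprintf(
    "bin_occupancy: %d occupied bins of %s bp on %d chromosome(s)\n",
    sum(lengths(x$occupied)), fmt_coord(x$bin_size), length(x$occupied)
  ))
  invisible(x)
}

#' Correlation matrix score between two binned datasets
#'
#' The co-binding score of an (reference, experimental) pair is the number
#' of bins occupied by both datasets divided by the number of bins occupied
#' by the reference — a reference-normalized overlap fraction in \[0, 1\].
#' The score is asymmetric: swapping the roles changes the denominator.
#'
#' @param reference,experimental `bin_occupancy` objects built with the
#'   same `bin_size` (see [bin_peaks()]).
#' @return A number in \[0, 1\]; 0 when no bin is shared.
#' @export
cms <- function(reference, experimental) {
  if (!inherits(reference, "bin_occupancy") ||
    !inherits(experimental, "bin_occupancy")) {
    stop("cms() expects two bin_occupancy objects from bin_peaks()")
  }
  if (reference$bin_size != experimental$bin_size) {
    stop(
      "bin occupancies were built with different bin sizes (",
      fmt_coord(reference$bin_size), " vs ",
      fmt_coord(experimental$bin_size), ")"
    )
  }
  n_ref <- sum(lengths(reference$occupied))
  if (n_ref == 0L) {
    stop("reference dataset occupies no bins; co-binding score is undefined")
  }
  shared <- 0L
  for (chrom in intersect(
    names(reference$occupied),
    names(experimental$occupied)
  )) {
    shared <- shared + length(intersect(
      reference$occupied[[chrom]],
      experimental$occupied[[chrom]]
    ))
  }
  shared / n_ref
}

#' Pairwise co-binding correlation matrix over N peak sets
#'
#' Computes the full N x N matrix of reference-normalized co-binding
#' scores: entry `[r, e]` treats dataset r as the reference and dataset e
#' as the experimental overlay (rows = reference). The diagonal is computed
#' like any other entry and equals 1 for any dataset with occupied bins.
#'
#' @param peak_sets List of at least two nonempty [peak_set()] objects;
#'   list names (or peak-set labels) become the matrix dimnames.
#' @param bin_size Bin width in bp; default 1000.
#' @return Numeric N x N matrix with entries in \[0, 1\] and attribute
#'   `bin_size`.
#' @export
correlation_matrix <- function(peak_sets, bin_size = 1000) {
  if (length(peak_sets) < 2L) {
    stop("at least two peak sets are required for a correlation matrix")
  }
  labels <- names(peak_sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(peak_sets, peak_label, character(1))
  }
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }
  n_peaks <- vapply(peak_sets, nrow, integer(1))
  if (any(n_peaks == 0L)) {
    stop(
      "peak set '", labels[which(n_peaks == 0L)[1]],
      "' is empty: every dataset must contain at least one peak"
    )
  }
  for (i in seq_along(peak_sets)[-1]) {
    warn_if_no_shared_chroms(
      peak_sets[[1]]$chrom, peak_sets[[i]]$chrom,
      labels[1], labels[i]
    )
  }
  occ <- lapply(peak_sets, bin_peaks, bin_size = bin_size)
  n <- length(occ)
  values <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (r in seq_len(n)) {
    for (e in seq_len(n)) {
      values[r, e] <- cms(occ[[r]], occ[[e]])
    }
  }
  attr(values, "bin_size") <- bin_size
  values
}

#' Export a correlation matrix as CSV and heatmap
#'
#' Writes `<out_prefix>.cms.csv` (full precision, labels as header row and
#' column, with a comment line stating the row = reference orientation) and
#' `<out_prefix>.heatmap.png` rendered on a fixed \[0, 1\] scale with a
#' yellow-to-red colormap by default. The CSV is the authoritative
#' artifact; the heatmap is a rendering of it.
#'
#' @param values Matrix from [correlation_matrix()].
#' @param out_prefix Output path prefix.
#' @param colormap Character vector of colors to ramp between (low to
#'   high), or a comma-separated string such as `"yellow,red"`.
#' @return Named character vector of written paths, invisibly.
#' @export
export_matrix <- function(values, out_prefix, colormap = c("yellow", "red")) {
  colormap <- parse_colormap(colormap)
  csv_path <- paste0(out_prefix, ".cms.csv")
  png_path <- paste0(out_prefix, ".heatmap.png")
  tryCatch(
    {
      con <- file(csv_path, open = "wt")
      on.exit(close(con))
      writeLines(
        "# co-binding correlation matrix: rows = reference, columns = experimental",
        con
      )
      utils::write.table(values, con,
        sep = ",", quote = FALSE,
        col.names = NA, row.names = TRUE
      )
    },
    error = function(e) {
      stop("cannot write matrix CSV ", csv_path, ": ", conditionMessage(e))
    }
  )
  pal <- grDevices::colorRampPalette(colormap)(100)
  pheatmap::pheatmap(values,
    color = pal, breaks = seq(0, 1, length.out = 101),
    cluster_rows = FALSE, cluster_cols = FALSE,
    display_numbers = nrow(values) <= 12,
    main = "Co-binding correlation (rows = reference)",
    filename = png_path, silent = TRUE
  )
  invisible(c(csv = csv_path, heatmap = png_path))
}

# Accepts c("yellow", "red") or "yellow,red"; validates color names.
parse_colormap <- function(colormap) {
  if (length(colormap) == 1L && grepl(",", colormap)) {
    colormap <- trimws(strsplit(colormap, ",", fixed = TRUE)[[1]])
  }
  if (length(colormap) < 2L) {
    stop("colormap needs at least two colors (low, high)")
  }
  ok <- vapply(colormap, function(col) {
    tryCatch(
      {
        grDevices::col2rgb(col)
        TRUE
      },
      error = function(e) FALSE
    )
  }, logical(1))
  if (!all(ok)) stop("unknown color in colormap: ", colormap[!ok][1])
  colormap
}

#' Run the multifactor co-binding screen end to end
#'
#' Reads N BED files, computes the binned co-binding correlation matrix,
#' and writes `<out_prefix>.cms.csv`, `<out_prefix>.heatmap.png`, a plain
#' run log `<out_prefix>.log`, and `<out_prefix>.manifest.json` listing
#' every emitted file with the fully resolved parameters.
#'
#' @param bed_paths Character vector of at least two BED file paths.
#' @param out_prefix Output path prefix.
#' @param bin_size Bin width in bp; default 1000.
#' @param colormap Heatmap colors, low to high; default yellow to red.
#' @param labels Optional dataset labels (default: file names).
#' @return The correlation matrix, invisibly.
#' @export
run_bindexplore <- function(bed_paths, out_prefix, bin_size = 1000,
                            colormap = c("yellow", "red"), labels = NULL) {
  if (length(bed_paths) < 2L) {
    stop("bindexplore requires at least two BED files")
  }
  colormap <- parse_colormap(colormap)
  peak_sets <- lapply(bed_paths, read_bed)
  if (!is.null(labels)) {
    if (length(labels) != length(peak_sets)) {
      stop("labels must match the number of BED files")
    }
    names(peak_sets) <- labels
  } else {
    names(peak_sets) <- vapply(peak_sets, peak_label, character(1))
  }
  empty <- vapply(peak_sets, nrow, integer(1)) == 0L
  if (any(empty)) {
    stop("empty input: no peak records in ", bed_paths[empty][1])
  }
  out_dir <- dirname(out_prefix)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  values <- correlation_matrix(peak_sets, bin_size = bin_size)
  paths <- export_matrix(values, out_prefix, colormap = colormap)
  log_path <- paste0(out_prefix, ".log")
  writeLines(c(
    "cobindkit explore",
    paste0("bin_size: ", fmt_coord(bin_size)),
    paste0("colormap: ", paste(colormap, collapse = ",")),
    paste0("datasets: ", paste(names(peak_sets), collapse = ", ")),
    vapply(seq_along(peak_sets), function(i) {
      sprintf(
        "  %s: %d peaks (%s)", names(peak_sets)[i],
        nrow(peak_sets[[i]]), bed_paths[i]
      )
    }, character(1))
  ), log_path)
  manifest_path <- paste0(out_prefix, ".manifest.json")
  write_manifest(manifest_path,
    tool = "bindexplore",
    parameters = list(
      bin_size = bin_size,
      colormap = paste(colormap, collapse = ",")
    ),
    inputs = list(beds = as.character(bed_paths)),
    outputs = basename(c(paths, log = log_path, manifest = manifest_path))
  )
  invisible(values)
}

write_manifest <- function(path, tool, parameters, inputs, outputs,
                           extra = list()) {
  manifest <- c(
    list(
      tool = tool,
      package = "cobindkit",
      version = as.character(utils::packageVersion("cobindkit")),
      parameters = parameters,
      inputs = inputs,
      outputs = as.character(outputs)
    ),
    extra,
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null"
  )
  invisible(path)
}
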