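#' Run a full pairwise binding comparison
#'
#' End-to-end bindcompare stage: reads the reference and experimental BED
#' files, finds and classifies all scoped overlap events, builds the
#' global and per-chromosome binding profiles, merges event footprints
#' into loci, and (when annotation is supplied) attaches gene ids and
#' extracts footprint sequences. All results are written as plain files so
#' every plot can be regenerated from data:
#'
#' * `events.bed` — one record per event footprint, category in the name
#'   column
#' * `events.csv` — full event table (reference/experimental coordinates,
#'   category, footprint, gene ids)
#' * `summary.csv` — event count per category
#' * `profile.csv` and `profiles_by_chrom/<chrom>.csv` — offset, CRO, ORF,
#'   ORE, PXP and Reference columns
#' * `genes.txt` (with `--gtf`), `events.fa` (with a genome FASTA)
#' * `profile.png`, `categories.png` (unless `plots = FALSE`)
#' * `manifest.json` — resolved parameters, inputs and every emitted file
#'
#' Reruns on identical inputs produce byte-identical CSV/BED outputs.
#'
#' @param ref_bed,exp_bed Paths to the reference and experimental BED
#'   files.
#' @param out_dir Output directory (created if needed).
#' @param scope Window extension in bp; `NULL` selects the mode default
#'   (1000 for DNA, 250 for RNA).
#' @param mode `"DNA"` or `"RNA"`; only sets the default scope.
#' @param gtf Optional GTF path for gene annotation.
#' @param fasta Optional genome FASTA path for sequence extraction.
#' @param stranded Swap 5'/3' labels for minus-strand reference peaks.
#' @param plots Render PNG figures from the emitted tables.
#' @return A `compare_result` list (events, category_counts, profile,
#'   per_chrom_profiles, merged_loci, gene_ids, output_dir), invisibly.
#' @export
run_bindcompare <- function(ref_bed, exp_bed, out_dir, scope = NULL,
                            mode = c("DNA", "RNA"), gtf = NULL, fasta = NULL,
                            stranded = FALSE, plots = TRUE) {
  mode <- match.arg(mode)
  if (is.null(scope)) scope <- default_scope(mode)
  ref_set <- read_bed(ref_bed)
  exp_set <- read_bed(exp_bed)
  if (!nrow(ref_set)) stop("empty input: no peak records in ", ref_bed)
  if (!nrow(exp_set)) stop("empty input: no peak records in ", exp_bed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  events <- find_overlaps(ref_set, exp_set, scope = scope, stranded = stranded)
  counts <- category_counts(events)
  profile <- build_profile(events, ref_set, scope)
  chrom_profiles <- per_chromosome_profiles(events, ref_set, scope)
  loci <- merge_loci(events)

  genes <- if (!is.null(gtf)) read_gtf_genes(gtf) else NULL
  event_genes <- if (!is.null(genes)) {
    annotate_genes(events, genes)
  } else {
    rep(list(character()), nrow(events))
  }
  gene_ids <- sort(unique(unlist(event_genes)))

  outputs <- character()

  events_bed <- data.frame(
    chrom = events$chrom, start = events$fp_start, end = events$fp_end,
    name = events$category, strand = rep("*", nrow(events)),
    stringsAsFactors = FALSE
  )
  write_bed(events_bed, file.path(out_dir, "events.bed"))
  outputs <- c(outputs, "events.bed")

  events_csv <- as.data.frame(events)
  events_csv$genes <- vapply(event_genes, paste, character(1), collapse = ";")
  utils::write.csv(events_csv, file.path(out_dir, "events.csv"),
    row.names = FALSE
  )
  outputs <- c(outputs, "events.csv")

  utils::write.csv(
    data.frame(category = names(counts), count = as.integer(counts)),
    file.path(out_dir, "summary.csv"),
    row.names = FALSE
  )
  outputs <- c(outputs, "summary.csv")

  utils::write.csv(as.data.frame(profile), file.path(out_dir, "profile.csv"),
    row.names = FALSE
  )
  outputs <- c(outputs, "profile.csv")

  chrom_dir <- file.path(out_dir, "profiles_by_chrom")
  if (!dir.exists(chrom_dir)) dir.create(chrom_dir)
  for (chrom in names(chrom_profiles)) {
    utils::write.csv(
      as.data.frame(chrom_profiles[[chrom]]),
      file.path(chrom_dir, paste0(chrom, ".csv")),
      row.names = FALSE
    )
    outputs <- c(outputs, file.path("profiles_by_chrom", paste0(chrom, ".csv")))
  }

  if (!is.null(genes)) {
    writeLines(gene_ids, file.path(out_dir, "genes.txt"))
    outputs <- c(outputs, "genes.txt")
  }
  if (!is.null(fasta)) {
    genome <- read_genome(fasta)
    seqs <- extract_event_sequences(events, genome)
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "events.fa"))
    outputs <- c(outputs, "events.fa")
  }
  if (plots) {
    plot_profile_png(profile, file.path(out_dir, "profile.png"))
    plot_categories_png(counts, file.path(out_dir, "categories.png"))
    outputs <- c(outputs, "profile.png", "categories.png")
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path,
    tool = "bindcompare",
    parameters = list(
      scope = scope, mode = mode, stranded = stranded
    ),
    inputs = list(
      reference_bed = ref_bed, experimental_bed = exp_bed,
      gtf = if (is.null(gtf)) NULL else gtf,
      fasta = if (is.null(fasta)) NULL else fasta
    ),
    outputs = c(outputs, "manifest.json"),
    extra = list(
      n_reference_peaks = nrow(ref_set),
      n_experimental_peaks = nrow(exp_set),
      n_events = nrow(events),
      category_counts = as.list(counts),
      n_merged_loci = nrow(loci),
      n_genes = length(gene_ids)
    )
  )

  result <- structure(
    list(
      events = events,
      category_counts = counts,
      profile = profile,
      per_chrom_profiles = chrom_profiles,
      merged_loci = loci,
      gene_ids = gene_ids,
      output_dir = out_dir
    ),
    class = "compare_result"
  )
  invisible(result)
}

#' Default scope for a comparison mode
#' @param mode `"DNA"` (1000 bp) or `"RNA"` (250 nt).
#' @return Integer scope in bp.
#' @export
default_scope <- function(mode = c("DNA", "RNA")) {
  mode <- match.arg(mode)
  if (mode == "RNA") 250L else 1000L
}

#' @export
print.compare_result <- function(x, ...) {
  cat(sprintf(
    "bindcompare result: %d events over %d merged loci (scope %s)\n",
    nrow(x$events), nrow(x$merged_loci), fmt_coord(attr(x$events, "scope"))
  ))
  counts <- x$category_counts
  cat("  ", paste(names(counts), counts, sep = "=", collapse = "  "), "\n")
  if (length(x$gene_ids)) {
    cat(sprintf("  %d associated gene(s)\n", length(x$gene_ids)))
  }
  cat("  outputs in:", x$output_dir, "\n")
  invisible(x)
}

category_palette <- function() {
  c(
    CRO = "#1b9e77", ORF = "#d95f02", ORE = "#7570b3", PXP = "#e7298a",
    Reference = "grey60"
  )
}

plot_profile_png <- function(profile, path) {
  pal <- category_palette()
  df <- as.data.frame(profile)
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  ymax <- max(df[, -1], 1)
  graphics::plot(NA,
    xlim = range(df$offset), ylim = c(0, ymax),
    xlab = "offset from reference peak midpoint (bp)",
    ylab = "events covering position",
    main = "Overlap profile over the average reference peak"
  )
  graphics::polygon(
    c(df$offset, rev(df$offset)),
    c(df$Reference, rep(0, nrow(df))),
    col = grDevices::adjustcolor(pal[["Reference"]], alpha.f = 0.4),
    border = NA
  )
  for (k in c("CRO", "ORF", "ORE", "PXP")) {
    graphics::lines(df$offset, df[[k]], col = pal[[k]], lwd = 2)
  }
  graphics::legend("topright",
    legend = names(pal), col = pal,
    lwd = c(2, 2, 2, 2, 8), bty = "n"
  )
  invisible(path)
}

plot_categories_png <- function(counts, path) {
  pal <- category_palette()
  grDevices::png(path, width = 600, height = 500)
  on.exit(grDevices::dev.off())
  graphics::barplot(counts,
    col = pal[names(counts)],
    ylab = "overlap events", main = "Overlap events by category"
  )
  invisible(path)
}
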