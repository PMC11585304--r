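#' Load a completed bindcompare run for cross-condition comparison
#'
#' Reads the `events.bed` and `manifest.json` emitted by
#' [run_bindcompare()] and union-merges the event footprints into
#' non-intersecting loci (so no two loci within one experiment overlap).
#' Per-locus gene sets are reconstructed from `events.csv` when present.
#'
#' @param dir Output directory of a bindcompare run.
#' @param label Condition label; defaults to the directory name.
#' @return An `experiment_summary`: list with `label`, `loci` (data.frame
#'   `chrom`, `start`, `end`), `locus_genes` (list parallel to `loci`),
#'   `gene_ids`, `manifest` and `dir`.
#' @export
load_experiment <- function(dir, label = NULL) {
  if (!dir.exists(dir)) stop("experiment directory not found: ", dir)
  if (is.null(label)) label <- basename(normalizePath(dir, mustWork = FALSE))
  events_path <- file.path(dir, "events.bed")
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(events_path)) {
    stop("not a bindcompare output directory (missing events.bed): ", dir)
  }
  if (!file.exists(manifest_path)) {
    stop("not a bindcompare output directory (missing manifest.json): ", dir)
  }
  footprints <- read_bed(events_path, label = label)
  manifest <- jsonlite::read_json(manifest_path)
  loci <- merge_loci(data.frame(
    chrom = footprints$chrom,
    fp_start = footprints$start,
    fp_end = footprints$end,
    stringsAsFactors = FALSE
  ))
  locus_genes <- rep(list(character()), nrow(loci))
  gene_ids <- character()
  events_csv <- file.path(dir, "events.csv")
  if (file.exists(events_csv) && nrow(loci)) {
    ev <- utils::read.csv(events_csv, stringsAsFactors = FALSE)
    if (nrow(ev) && "genes" %in% names(ev)) {
      per_event <- strsplit(ifelse(is.na(ev$genes), "", ev$genes), ";",
        fixed = TRUE
      )
      levels <- sort(unique(c(ev$chrom, loci$chrom)))
      hits <- GenomicRanges::findOverlaps(
        as_granges0(ev$chrom, ev$fp_start, ev$fp_end, levels),
        as_granges0(loci$chrom, loci$start, loci$end, levels),
        minoverlap = 1L
      )
      by_locus <- split(
        S4Vectors::queryHits(hits),
        S4Vectors::subjectHits(hits)
      )
      locus_genes[as.integer(names(by_locus))] <- lapply(
        by_locus,
        function(ev_idx) {
          g <- unlist(per_event[ev_idx], use.names = FALSE)
          sort(unique(g[nzchar(g)]))
        }
      )
      gene_ids <- sort(unique(unlist(locus_genes)))
    }
  }
  genes_txt <- file.path(dir, "genes.txt")
  if (!length(gene_ids) && file.exists(genes_txt)) {
    gene_ids <- sort(unique(readLines(genes_txt, warn = FALSE)))
    gene_ids <- gene_ids[nzchar(gene_ids)]
  }
  structure(
    list(
      label = label, loci = loci, locus_genes = locus_genes,
      gene_ids = gene_ids, manifest = manifest, dir = dir
    ),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf(
    "experiment '%s': %d merged overlap loci, %d gene(s)\n",
    x$label, nrow(x$loci), length(x$gene_ids)
  ))
  invisible(x)
}

#' Compare overlap loci between two experimental conditions
#'
#' Classifies merged overlap loci from two bindcompare runs: a locus pair
#' (one from each condition) is *common* when the intervals intersect by
#' at least one base pair; loci with no cross-condition intersection are
#' *unique* to their condition. No scope re-expansion is applied here —
#' proximity was already folded in upstream when the loci were built.
#' Gene lists per class are unions over member loci, so a gene hit by
#' distinct loci may legitimately appear in more than one class.
#'
#' @param a,b `experiment_summary` objects from [load_experiment()].
#' @return A `comparexp_result`: list with `common` (data.frame of
#'   intersecting locus pairs), `unique_a`, `unique_b` (loci data.frames),
#'   `counts` (common_pairs, common_a, common_b, unique_a, unique_b) and
#'   `genes` (character vectors `common`, `unique_a`, `unique_b`).
#' @export
compare_experiments <- function(a, b) {
  stopifnot(inherits(a, "experiment_summary"), inherits(b, "experiment_summary"))
  la <- a$loci
  lb <- b$loci
  levels <- sort(unique(c(la$chrom, lb$chrom)))
  q <- integer()
  s <- integer()
  if (nrow(la) && nrow(lb)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(la$chrom, la$start, la$end, levels),
      as_granges0(lb$chrom, lb$start, lb$end, levels),
      minoverlap = 1L
    )
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
  }
  common <- data.frame(
    chrom = if (length(q)) la$chrom[q] else character(),
    a_start = la$start[q], a_end = la$end[q],
    b_start = lb$start[s], b_end = lb$end[s],
    stringsAsFactors = FALSE
  )
  unique_a <- la[setdiff(seq_len(nrow(la)), q), , drop = FALSE]
  unique_b <- lb[setdiff(seq_len(nrow(lb)), s), , drop = FALSE]
  rownames(unique_a) <- rownames(unique_b) <- NULL
  gene_union <- function(genes_list, idx) {
    as.character(sort(unique(unlist(genes_list[idx], use.names = FALSE))))
  }
  genes <- list(
    common = sort(unique(c(
      gene_union(a$locus_genes, unique(q)),
      gene_union(b$locus_genes, unique(s))
    ))),
    unique_a = gene_union(a$locus_genes, setdiff(seq_len(nrow(la)), q)),
    unique_b = gene_union(b$locus_genes, setdiff(seq_len(nrow(lb)), s))
  )
  structure(
    list(
      a_label = a$label, b_label = b$label,
      common = common, unique_a = unique_a, unique_b = unique_b,
      counts = c(
        common_pairs = nrow(common),
        common_a = length(unique(q)), common_b = length(unique(s)),
        unique_a = nrow(unique_a), unique_b = nrow(unique_b)
      ),
      genes = genes
    ),
    class = "comparexp_result"
  )
}

#' @export
print.comparexp_result <- function(x, ...) {
  cat(sprintf("comparexp: '%s' vs '%s'\n", x$a_label, x$b_label))
  cat(
    "  ",
    paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n"
  )
  invisible(x)
}

#' Run a cross-condition comparison end to end
#'
#' Loads two bindcompare output directories, compares their merged
#' overlap loci and writes `common.bed` (union span of each intersecting
#' pair, pair coordinates in the name column), `unique_exp1.bed`,
#' `unique_exp2.bed`, `venn_counts.csv`, per-class gene lists
#' (`genes_common.txt`, `genes_unique1.txt`, `genes_unique2.txt`) and a
#' `manifest.json`.
#'
#' @param dir_a,dir_b bindcompare output directories for the two
#'   conditions.
#' @param out_dir Output directory (created if needed).
#' @return The `comparexp_result`, invisibly.
#' @export
run_comparexp <- function(dir_a, dir_b, out_dir) {
  a <- load_experiment(dir_a)
  b <- load_experiment(dir_b)
  result <- compare_experiments(a, b)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  common_bed <- data.frame(
    chrom = result$common$chrom,
    start = pmin(result$common$a_start, result$common$b_start),
    end = pmax(result$common$a_end, result$common$b_end),
    name = sprintf(
      "%s:%s-%s|%s:%s-%s",
      a$label, fmt_coord(result$common$a_start),
      fmt_coord(result$common$a_end),
      b$label, fmt_coord(result$common$b_start),
      fmt_coord(result$common$b_end)
    ),
    strand = rep("*", nrow(result$common)),
    stringsAsFactors = FALSE
  )
  write_bed(common_bed, file.path(out_dir, "common.bed"))
  write_bed(result$unique_a, file.path(out_dir, "unique_exp1.bed"))
  write_bed(result$unique_b, file.path(out_dir, "unique_exp2.bed"))
  utils::write.csv(
    data.frame(
      class = names(result$counts),
      count = as.integer(result$counts)
    ),
    file.path(out_dir, "venn_counts.csv"),
    row.names = FALSE
  )
  writeLines(result$genes$common, file.path(out_dir, "genes_common.txt"))
  writeLines(result$genes$unique_a, file.path(out_dir, "genes_unique1.txt"))
  writeLines(result$genes$unique_b, file.path(out_dir, "genes_unique2.txt"))
  outputs <- c(
    "common.bed", "unique_exp1.bed", "unique_exp2.bed",
    "venn_counts.csv", "genes_common.txt", "genes_unique1.txt",
    "genes_unique2.txt", "manifest.json"
  )
  write_manifest(file.path(out_dir, "manifest.json"),
    tool = "comparexp",
    parameters = list(),
    inputs = list(experiment_one = dir_a, experiment_two = dir_b),
    outputs = outputs,
    extra = list(counts = as.list(result$counts))
  )
  invisible(result)
}
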