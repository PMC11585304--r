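# Programmatic fixtures shared across test files.

rand_peak_set <- function(n, chroms = c("chr1", "chr2", "chr3"),
                          chrom_len = 5e4, width_range = c(50, 500),
                          label = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  width <- floor(runif(n, width_range[1], width_range[2] + 1))
  start <- floor(runif(n, 0, chrom_len - width))
  peak_set(chrom, start, start + width, label = label)
}

write_tmp_lines <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny two-peak comparison run on disk; returns the output directory.
minimal_compare_run <- function(dir = tempfile("cmp"),
                                ref_line = "chr1\t1000\t2000",
                                exp_line = "chr1\t1500\t2500",
                                ...) {
  ref <- write_tmp_lines(ref_line)
  exp <- write_tmp_lines(exp_line)
  run_bindcompare(ref, exp, dir, plots = FALSE, ...)
  dir
}

# experiment_summary built in memory from bare loci (no gene annotation);
# loci are union-merged to satisfy the non-overlapping invariant.
make_experiment <- function(chrom, start, end, label = "cond") {
  loci <- merge_loci(data.frame(
    chrom = chrom, fp_start = start, fp_end = end,
    stringsAsFactors = FALSE
  ))
  structure(
    list(
      label = label, loci = loci,
      locus_genes = rep(list(character()), nrow(loci)),
      gene_ids = character(), manifest = list(), dir = NA_character_
    ),
    class = "experiment_summary"
  )
}
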