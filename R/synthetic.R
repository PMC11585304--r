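#' Specification for a synthetic co-binding study
#'
#' Defines the conditions of a simulated pair of binding experiments: a
#' reference peak set and an experimental peak set in which a controlled
#' fraction of reference peaks carries a planted experimental partner at a
#' controlled relative offset, plus unrelated background experimental
#' peaks. Defaults emulate a modest metazoan ChIP-like study: two 10-Mb
#' chromosomes, 1000 reference peaks of 150-350 bp, half of them
#' co-bound, partners displaced up to 250 bp, and 500 background peaks.
#'
#' @param chrom_lengths Named numeric vector, chromosome -> length in bp.
#' @param n_ref Number of reference peaks (placed without self-overlap).
#' @param n_exp_background Number of background experimental peaks.
#' @param co_fraction Fraction of reference peaks given a planted partner,
#'   in \[0, 1\].
#' @param offset_model Distribution of the partner start relative to the
#'   reference start: `list(kind = "fixed", offset = 0)` or
#'   `list(kind = "uniform", max_abs = d)` (integer offsets in ±d).
#' @param peak_length_model Peak width distribution:
#'   `list(kind = "fixed", length = L)` or
#'   `list(kind = "uniform", min = a, max = b)`.
#' @param scope Scope (bp) whose windows background peaks must avoid.
#' @param contaminated If `TRUE`, background peaks are placed uniformly,
#'   with no exclusion from scoped windows (realistic noise); default
#'   `FALSE` so planted-signal recovery is exact.
#' @param seed Integer seed; the generated files are a pure function of
#'   the spec including the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                           n_ref = 1000, n_exp_background = 500,
                           co_fraction = 0.5,
                           offset_model = list(kind = "uniform", max_abs = 250),
                           peak_length_model = list(
                             kind = "uniform",
                             min = 150, max = 350
                           ),
                           scope = 1000, contaminated = FALSE, seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector of chromosome lengths")
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  if (n_ref < 0 || n_exp_background < 0) stop("peak counts must be >= 0")
  if (is.na(co_fraction) || co_fraction < 0 || co_fraction > 1) {
    stop("co_fraction must lie in [0, 1]")
  }
  if (scope < 0) stop("scope must be >= 0")
  structure(
    list(
      chrom_lengths = chrom_lengths, n_ref = n_ref,
      n_exp_background = n_exp_background, co_fraction = co_fraction,
      offset_model = offset_model, peak_length_model = peak_length_model,
      scope = scope, contaminated = isTRUE(contaminated),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

draw_lengths <- function(model, n) {
  if (n == 0L) {
    return(numeric())
  }
  switch(model$kind,
    fixed = rep(model$length, n),
    uniform = floor(stats::runif(n, model$min, model$max + 1)),
    stop("unknown peak_length_model kind: ", model$kind)
  )
}

draw_offsets <- function(model, n) {
  if (n == 0L) {
    return(numeric())
  }
  switch(model$kind,
    fixed = rep(model$offset, n),
    uniform = floor(stats::runif(n, -model$max_abs, model$max_abs + 1)),
    stop("unknown offset_model kind: ", model$kind)
  )
}

# Planted category from geometry alone (independent of classify_overlap):
# derived from gap/containment arithmetic on the planted offset and widths.
planted_category <- function(ref_start, ref_end, exp_start, exp_end, scope) {
  gap_right <- exp_start - ref_end # >= 0 when exp is fully 3' of ref
  gap_left <- ref_start - exp_end # >= 0 when exp is fully 5' of ref
  disjoint <- gap_right >= 0 | gap_left >= 0
  within_scope <- pmax(gap_right, gap_left) < scope
  nested <- (exp_start >= ref_start & exp_end <= ref_end) |
    (exp_start <= ref_start & exp_end >= ref_end)
  out <- rep(NA_character_, length(ref_start))
  out[disjoint & within_scope] <- "PXP"
  out[!disjoint & nested] <- "CRO"
  front <- !disjoint & !nested & exp_start < ref_start
  out[front] <- "ORF"
  out[!disjoint & !nested & !front] <- "ORE"
  out
}

# Uniformly sample peak placements across chromosomes (probability
# proportional to chromosome length), keeping each peak within bounds.
sample_placements <- function(n, chrom_lengths, widths) {
  chroms <- names(chrom_lengths)
  chrom_idx <- sample.int(length(chroms), n,
    replace = TRUE,
    prob = chrom_lengths / sum(chrom_lengths)
  )
  max_start <- chrom_lengths[chrom_idx] - widths
  if (any(max_start < 0)) {
    stop("generation error: a peak is wider than its chromosome")
  }
  start <- floor(stats::runif(n) * (max_start + 1))
  data.frame(
    chrom = chroms[chrom_idx], start = start, end = start + widths,
    stringsAsFactors = FALSE
  )
}

# Drop placements that overlap an earlier-sorted placement on the same
# chromosome (single sweep with a running maximum end).
drop_self_overlaps <- function(df) {
  if (nrow(df) < 2L) {
    return(df)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  keep <- logical(nrow(df))
  prev_chrom <- ""
  prev_end <- -Inf
  for (k in seq_len(nrow(df))) {
    if (df$chrom[k] != prev_chrom || df$start[k] >= prev_end) {
      keep[k] <- TRUE
      prev_chrom <- df$chrom[k]
      prev_end <- df$end[k]
    }
  }
  df[keep, , drop = FALSE]
}

#' Generate co-bound reference and experimental peak sets
#'
#' Places `n_ref` non-self-overlapping reference peaks; gives each a
#' planted experimental partner with probability `co_fraction`, drawn
#' from the offset and width models; and adds `n_exp_background`
#' experimental peaks placed uniformly and (unless `contaminated`)
#' rejection-sampled away from every scoped reference window, so any
#' overlap event traces back to a planted partner. The returned truth
#' table records each reference peak, its partner (if any) and the
#' partner's intended overlap category, computed from the planted
#' geometry.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir If non-`NULL`, writes `ref.bed`, `exp.bed`, `truth.csv`
#'   (and a `manifest.json`) there; identical spec + seed produce
#'   byte-identical files.
#' @return List with `ref` and `exp` ([peak_set()]s), `truth`
#'   (data.frame), `spec`, and `files` when written.
#' @export
generate_cobound_peaks <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    refs <- place_reference_peaks(spec)
    partner_of <- stats::runif(spec$n_ref) < spec$co_fraction
    partners <- plant_partners(spec, refs, which(partner_of))
    background <- place_background(spec, refs)

    truth <- data.frame(
      ref_name = refs$name,
      chrom = refs$chrom,
      ref_start = refs$start, ref_end = refs$end,
      partner = partner_of,
      exp_start = NA_real_, exp_end = NA_real_,
      category = NA_character_,
      stringsAsFactors = FALSE
    )
    if (nrow(partners)) {
      idx <- match(partners$ref_name, truth$ref_name)
      truth$exp_start[idx] <- partners$start
      truth$exp_end[idx] <- partners$end
      truth$category[idx] <- planted_category(
        truth$ref_start[idx], truth$ref_end[idx],
        partners$start, partners$end, spec$scope
      )
    }

    ref_ps <- peak_set(refs$chrom, refs$start, refs$end,
      name = refs$name, label = "synthetic_ref"
    )
    exp_all <- rbind(
      partners[, c("chrom", "start", "end", "name")],
      background[, c("chrom", "start", "end", "name")]
    )
    exp_ps <- peak_set(exp_all$chrom, exp_all$start, exp_all$end,
      name = exp_all$name, label = "synthetic_exp"
    )

    files <- NULL
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      files <- c(
        ref = file.path(out_dir, "ref.bed"),
        exp = file.path(out_dir, "exp.bed"),
        truth = file.path(out_dir, "truth.csv")
      )
      write_bed(ref_ps, files[["ref"]])
      write_bed(exp_ps, files[["exp"]])
      utils::write.csv(truth, files[["truth"]], row.names = FALSE)
    }
    list(ref = ref_ps, exp = exp_ps, truth = truth, spec = spec, files = files)
  })
}

place_reference_peaks <- function(spec, max_rounds = 60L) {
  placed <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    stringsAsFactors = FALSE
  )
  for (round in seq_len(max_rounds)) {
    missing <- spec$n_ref - nrow(placed)
    if (missing == 0L) break
    widths <- draw_lengths(spec$peak_length_model, missing)
    fresh <- sample_placements(missing, spec$chrom_lengths, widths)
    placed <- drop_self_overlaps(rbind(placed, fresh))
  }
  if (nrow(placed) < spec$n_ref) {
    stop(
      "generation error: could not place ", spec$n_ref,
      " non-overlapping reference peaks after ", max_rounds,
      " rounds; enlarge the genome or reduce n_ref"
    )
  }
  placed <- placed[order(placed$chrom, placed$start, placed$end), ,
    drop = FALSE
  ]
  placed$name <- sprintf("ref_%05d", seq_len(nrow(placed)))
  placed
}

plant_partners <- function(spec, refs, idx, max_tries = 60L) {
  n <- length(idx)
  if (!n) {
    return(data.frame(
      ref_name = character(), chrom = character(),
      start = numeric(), end = numeric(), name = character(),
      stringsAsFactors = FALSE
    ))
  }
  chrom_len <- spec$chrom_lengths[refs$chrom[idx]]
  widths <- draw_lengths(spec$peak_length_model, n)
  start <- refs$start[idx] + draw_offsets(spec$offset_model, n)
  for (try in seq_len(max_tries)) {
    bad <- which(start < 0 | start + widths > chrom_len)
    if (!length(bad)) break
    start[bad] <- refs$start[idx][bad] +
      draw_offsets(spec$offset_model, length(bad))
  }
  bad <- start < 0 | start + widths > chrom_len
  if (any(bad)) {
    stop(
      "generation error: planted partner for ", refs$name[idx][bad][1],
      " cannot fit its chromosome; check offset and length models"
    )
  }
  data.frame(
    ref_name = refs$name[idx], chrom = refs$chrom[idx],
    start = start, end = start + widths,
    name = sprintf("partner_%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

place_background <- function(spec, refs, max_rounds = 60L) {
  empty <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), stringsAsFactors = FALSE
  )
  if (spec$n_exp_background == 0L) {
    return(empty)
  }
  levels <- names(spec$chrom_lengths)
  windows <- as_granges0(
    refs$chrom, pmax(refs$start - spec$scope, 0),
    refs$end + spec$scope, levels
  )
  kept <- empty[, c("chrom", "start", "end")]
  for (round in seq_len(max_rounds)) {
    missing <- spec$n_exp_background - nrow(kept)
    if (missing == 0L) break
    widths <- draw_lengths(spec$peak_length_model, missing)
    fresh <- sample_placements(missing, spec$chrom_lengths, widths)
    if (!spec$contaminated && nrow(refs)) {
      gr <- as_granges0(fresh$chrom, fresh$start, fresh$end, levels)
      clash <- GenomicRanges::countOverlaps(gr, windows, minoverlap = 1L) > 0L
      fresh <- fresh[!clash, , drop = FALSE]
    }
    kept <- rbind(kept, fresh)
  }
  if (nrow(kept) < spec$n_exp_background) {
    stop(
      "generation error: could not place ", spec$n_exp_background,
      " background peaks outside scoped reference windows after ",
      max_rounds, " rounds; reduce n_exp_background or the scope"
    )
  }
  kept$name <- sprintf("bg_%05d", seq_len(nrow(kept)))
  kept
}

#' Generate a synthetic genome FASTA and gene annotation
#'
#' Emits a random-base genome matching `spec$chrom_lengths` and a GTF of
#' non-overlapping genes tiled at known coordinates (alternating
#' gene/gap), returned as a ground-truth table. Both files are a pure
#' function of the spec's seed.
#'
#' @param spec A [synthetic_spec()] (chromosome lengths and seed are
#'   used).
#' @param out_dir If non-`NULL`, writes `genome.fa` and `genes.gtf` there.
#' @param gene_length,gene_gap Tiling geometry in bp.
#' @return List with `genome` (`DNAStringSet`), `genes` (data.frame
#'   ground truth, 0-based half-open), and `files` when written.
#' @export
generate_genome <- function(spec, out_dir = NULL, gene_length = 500,
                            gene_gap = 500) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genome <- Biostrings::DNAStringSet(vapply(
      spec$chrom_lengths,
      function(len) {
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""
        )
      },
      character(1)
    ))
    names(genome) <- names(spec$chrom_lengths)
    genes <- do.call(rbind, lapply(names(spec$chrom_lengths), function(chrom) {
      len <- spec$chrom_lengths[[chrom]]
      starts <- seq(gene_gap, len - gene_length, by = gene_length + gene_gap)
      if (!length(starts)) {
        return(NULL)
      }
      data.frame(
        gene_id = sprintf("%s_g%04d", chrom, seq_along(starts)),
        chrom = chrom, start = starts, end = starts + gene_length,
        strand = rep_len(c("+", "-"), length(starts)),
        stringsAsFactors = FALSE
      )
    }))
    if (is.null(genes)) {
      genes <- data.frame(
        gene_id = character(), chrom = character(), start = numeric(),
        end = numeric(), strand = character(), stringsAsFactors = FALSE
      )
    }
    files <- NULL
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      files <- c(
        genome = file.path(out_dir, "genome.fa"),
        gtf = file.path(out_dir, "genes.gtf")
      )
      Biostrings::writeXStringSet(genome, files[["genome"]])
      gtf_lines <- sprintf(
        "%s\tcobindkit\tgene\t%s\t%s\t.\t%s\t.\tgene_id \"%s\";",
        genes$chrom, fmt_coord(genes$start + 1), fmt_coord(genes$end),
        genes$strand, genes$gene_id
      )
      writeLines(gtf_lines, files[["gtf"]])
    }
    list(genome = genome, genes = genes, files = files)
  })
}

#' Run the simulator and write a fixture directory
#'
#' Convenience wrapper used by the command line: generates peaks (and
#' optionally a genome + GTF) under `out_dir` with a manifest.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory.
#' @param with_genome Also emit `genome.fa` and `genes.gtf`.
#' @return The [generate_cobound_peaks()] result, invisibly.
#' @export
run_simulate <- function(spec, out_dir, with_genome = FALSE) {
  sim <- generate_cobound_peaks(spec, out_dir = out_dir)
  outputs <- basename(unname(sim$files))
  if (with_genome) {
    gen <- generate_genome(spec, out_dir = out_dir)
    outputs <- c(outputs, basename(unname(gen$files)))
  }
  spec_json <- spec
  spec_json$chrom_lengths <- as.list(spec$chrom_lengths)
  write_manifest(file.path(out_dir, "manifest.json"),
    tool = "simulate",
    parameters = unclass(spec_json),
    inputs = list(),
    outputs = c(outputs, "manifest.json"),
    extra = list(
      n_ref_placed = nrow(sim$ref),
      n_exp_placed = nrow(sim$exp),
      n_partners = sum(sim$truth$partner)
    )
  )
  invisible(sim)
}
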