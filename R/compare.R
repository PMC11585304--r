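#' Classify the relation between a reference and an experimental peak
#'
#' Every experimental peak falling inside the scoped window
#' `[ref_start - scope, ref_end + scope)` of a reference peak is assigned
#' exactly one of four categories:
#'
#' * `CRO` (complete reference overlap): one peak fully contains the other
#'   (either direction; equal endpoints count as containment).
#' * `ORF` (overlap reference front): partial overlap extending past the
#'   reference 5' edge (`exp_start < ref_start`).
#' * `ORE` (overlap reference end): partial overlap extending past the
#'   reference 3' edge.
#' * `PXP` (proximal peak): no base-pair intersection with the reference
#'   peak, but intersection with the scoped window (edge-to-edge distance
#'   within `scope`).
#'
#' Peaks outside the scoped window get `NA` (no event). 5'/3' follow
#' genomic orientation here; strand-aware relabeling for minus-strand
#' references is applied by [find_overlaps()] when requested.
#'
#' All arguments are vectorized and recycled.
#'
#' @param ref_start,ref_end,exp_start,exp_end 0-based half-open coordinates
#'   of peaks on the same chromosome.
#' @param scope Non-negative window extension in bp on each side of the
#'   reference peak.
#' @return Character vector of `"CRO"`, `"ORF"`, `"ORE"`, `"PXP"` or `NA`.
#' @export
classify_overlap <- function(ref_start, ref_end, exp_start, exp_end, scope) {
  if (!is.numeric(scope) || length(scope) != 1L || is.na(scope) || scope < 0) {
    stop("scope must be a single non-negative number of base pairs")
  }
  n <- max(length(ref_start), length(ref_end), length(exp_start), length(exp_end))
  ref_start <- rep_len(ref_start, n)
  ref_end <- rep_len(ref_end, n)
  exp_start <- rep_len(exp_start, n)
  exp_end <- rep_len(exp_end, n)
  in_window <- exp_start < ref_end + scope & exp_end > ref_start - scope
  intersects <- exp_start < ref_end & exp_end > ref_start
  contained <- (exp_start <= ref_start & exp_end >= ref_end) |
    (exp_start >= ref_start & exp_end <= ref_end)
  out <- rep(NA_character_, n)
  out[in_window] <- "PXP"
  hit <- which(intersects) # intersecting implies in-window for scope >= 0
  out[hit] <- ifelse(contained[hit], "CRO",
    ifelse(exp_start[hit] < ref_start[hit], "ORF", "ORE")
  )
  out
}

#' Find and classify all scoped overlap events between two peak sets
#'
#' For every (reference peak, experimental peak) pair on the same
#' chromosome where the experimental peak intersects the reference peak's
#' scoped window, emits one event carrying the pair's coordinates, its
#' category (see [classify_overlap()]) and the merged footprint
#' `[min(starts), max(ends))`. The search uses interval trees
#' (GenomicRanges) over scope-extended reference windows; a reference peak
#' may yield many events and an experimental peak may participate in many.
#'
#' @param ref_set,exp_set Nonempty [peak_set()] objects.
#' @param scope Window extension in bp (default 1000; use 250 for RNA
#'   peaks).
#' @param stranded If `TRUE`, ORF/ORE labels are swapped for minus-strand
#'   reference peaks so that 5'/3' follow the reference transcript
#'   orientation. Default `FALSE` (genomic orientation).
#' @return An `overlap_events` data.frame sorted by (chrom, ref_start,
#'   exp_start), with columns `chrom`, `ref_id`, `ref_start`, `ref_end`,
#'   `ref_strand`, `exp_id`, `exp_start`, `exp_end`, `exp_strand`,
#'   `category`, `fp_start`, `fp_end`; `ref_id`/`exp_id` are row indices
#'   into the sorted input sets.
#' @export
find_overlaps <- function(ref_set, exp_set, scope = 1000, stranded = FALSE) {
  if (!is.numeric(scope) || length(scope) != 1L || is.na(scope) || scope < 0) {
    stop("scope must be a single non-negative number of base pairs")
  }
  if (!nrow(ref_set)) {
    stop("reference peak set ('", peak_label(ref_set), "') is empty")
  }
  if (!nrow(exp_set)) {
    stop("experimental peak set ('", peak_label(exp_set), "') is empty")
  }
  warn_if_no_shared_chroms(
    ref_set$chrom, exp_set$chrom,
    peak_label(ref_set), peak_label(exp_set)
  )
  levels <- sort(unique(c(ref_set$chrom, exp_set$chrom)))
  windows <- as_granges0(
    ref_set$chrom, pmax(ref_set$start - scope, 0),
    ref_set$end + scope, levels
  )
  exp_gr <- as_granges0(exp_set$chrom, exp_set$start, exp_set$end, levels)
  hits <- GenomicRanges::findOverlaps(windows, exp_gr, minoverlap = 1L)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  category <- classify_overlap(
    ref_set$start[i], ref_set$end[i],
    exp_set$start[j], exp_set$end[j], scope
  )
  if (stranded) {
    minus <- ref_set$strand[i] == "-"
    flip <- minus & category %in% c("ORF", "ORE")
    category[flip] <- ifelse(category[flip] == "ORF", "ORE", "ORF")
  }
  events <- data.frame(
    chrom = ref_set$chrom[i],
    ref_id = i,
    ref_start = ref_set$start[i],
    ref_end = ref_set$end[i],
    ref_strand = ref_set$strand[i],
    exp_id = j,
    exp_start = exp_set$start[j],
    exp_end = exp_set$end[j],
    exp_strand = exp_set$strand[j],
    category = category,
    fp_start = pmin(ref_set$start[i], exp_set$start[j]),
    fp_end = pmax(ref_set$end[i], exp_set$end[j]),
    stringsAsFactors = FALSE
  )
  ord <- order(
    events$chrom, events$ref_start, events$exp_start,
    events$ref_end, events$exp_end, events$ref_id, events$exp_id
  )
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
    class = c("overlap_events", "data.frame"),
    scope = scope,
    ref_label = peak_label(ref_set),
    exp_label = peak_label(exp_set)
  )
}

#' Category counts of an event list
#' @param events Events from [find_overlaps()].
#' @return Named integer vector over CRO, ORF, ORE, PXP.
#' @export
category_counts <- function(events) {
  cats <- c("CRO", "ORF", "ORE", "PXP")
  counts <- table(factor(events$category, levels = cats))
  stats::setNames(as.integer(counts), cats)
}

#' Build the positional overlap profile around reference-peak midpoints
#'
#' Aggregates, for each overlap category, how often experimental-peak
#' coverage occurs at each position relative to the midpoint of the
#' involved reference peak. The window half-width is
#' `scope + ceiling(Lmax / 2)` with `Lmax` the longest reference peak in
#' the run, so every scoped event fits. For each event, every base of the
#' experimental peak inside the window increments that category's track at
#' its offset from the reference midpoint (`floor((start + end) / 2)`).
#' The `Reference` track accumulates the coverage of each reference peak
#' participating in at least one event (counted once per peak), giving the
#' average-reference-peak backdrop the category tracks are read against.
#'
#' @param events Events from [find_overlaps()] produced with `ref_set` and
#'   `scope`.
#' @param ref_set The reference [peak_set()] of the run (used for `Lmax`).
#' @param scope The scope the events were called with.
#' @return An `overlap_profile`: list with `scope`, `half_width`,
#'   `offsets` (-half_width ... half_width - 1) and `counts`, an integer
#'   matrix with columns CRO, ORF, ORE, PXP, Reference.
#' @export
build_profile <- function(events, ref_set, scope) {
  if (!nrow(ref_set)) stop("reference peak set is empty")
  l_max <- max(ref_set$end - ref_set$start)
  half_width <- as.integer(scope + ceiling(l_max / 2))
  width <- 2L * half_width
  offsets <- seq.int(-half_width, half_width - 1L)
  cats <- c("CRO", "ORF", "ORE", "PXP")
  counts <- matrix(0L,
    nrow = width, ncol = 5L,
    dimnames = list(NULL, c(cats, "Reference"))
  )
  if (nrow(events)) {
    mid <- (events$ref_start + events$ref_end) %/% 2
    lo <- pmax(events$exp_start, mid - half_width)
    hi <- pmin(events$exp_end, mid + half_width)
    run <- as.integer(pmax(hi - lo, 0))
    pos <- sequence(run, from = as.integer(lo - mid + half_width + 1))
    cat_per_base <- rep(events$category, run)
    for (k in cats) {
      counts[, k] <- tabulate(pos[cat_per_base == k], nbins = width)
    }
    refs <- events[!duplicated(events$ref_id),
      c("ref_start", "ref_end"),
      drop = FALSE
    ]
    ref_mid <- (refs$ref_start + refs$ref_end) %/% 2
    ref_pos <- sequence(
      as.integer(refs$ref_end - refs$ref_start),
      from = as.integer(refs$ref_start - ref_mid + half_width + 1)
    )
    counts[, "Reference"] <- tabulate(ref_pos, nbins = width)
  }
  structure(
    list(
      scope = scope, half_width = half_width,
      offsets = offsets, counts = counts
    ),
    class = "overlap_profile"
  )
}

#' @export
#' @method as.data.frame overlap_profile
as.data.frame.overlap_profile <- function(x, ...) {
  data.frame(offset = x$offsets, x$counts, check.names = FALSE)
}

#' @export
print.overlap_profile <- function(x, ...) {
  totals <- colSums(x$counts)
  cat(sprintf(
    "overlap_profile: offsets %d..%d (scope %s)\n",
    -x$half_width, x$half_width - 1L, fmt_coord(x$scope)
  ))
  cat(
    "covered bp per track:",
    paste(names(totals), totals, sep = "=", collapse = " "), "\n"
  )
  invisible(x)
}

#' Per-chromosome overlap profiles
#'
#' Partitions events by chromosome and builds one profile per chromosome
#' with the same half-width as the global profile (Lmax taken from the
#' whole reference set), so per-chromosome tracks sum position-wise to the
#' global tracks. Chromosomes with no events are omitted.
#'
#' @inheritParams build_profile
#' @return Named list of `overlap_profile` objects, keyed by chromosome.
#' @export
per_chromosome_profiles <- function(events, ref_set, scope) {
  parts <- split(as.data.frame(events), events$chrom, drop = TRUE)
  lapply(parts, build_profile, ref_set = ref_set, scope = scope)
}

#' Annotate events with overlapping genes
#'
#' An event is annotated with every gene whose span intersects the event's
#' merged footprint (the bounding interval of the reference and
#' experimental peaks) by at least one base pair; half-open adjacency does
#' not count. Events hitting no gene get an empty set.
#'
#' @param events Events from [find_overlaps()].
#' @param genes Gene models from [read_gtf_genes()].
#' @return List (one element per event, in order) of sorted gene-id
#'   character vectors.
#' @export
annotate_genes <- function(events, genes) {
  hits_per_event <- rep(list(character()), nrow(events))
  if (nrow(events) && nrow(genes)) {
    levels <- sort(unique(c(events$chrom, genes$chrom)))
    fp <- as_granges0(events$chrom, events$fp_start, events$fp_end, levels)
    gg <- as_granges0(genes$chrom, genes$start, genes$end, levels)
    hits <- GenomicRanges::findOverlaps(fp, gg, minoverlap = 1L)
    by_event <- split(
      genes$gene_id[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits)
    )
    hits_per_event[as.integer(names(by_event))] <-
      lapply(by_event, function(g) sort(unique(g)))
  }
  hits_per_event
}

#' Extract the sequence under each event footprint
#'
#' One FASTA record per event, covering the merged footprint, with a
#' header of the form `chrom:start-end|CATEGORY` (0-based half-open
#' coordinates). Footprints extending past a chromosome end are clipped to
#' the chromosome with a warning. Duplicate footprints yield duplicate
#' records.
#'
#' @param events Events from [find_overlaps()].
#' @param genome Genome from [read_genome()].
#' @return A named [Biostrings::DNAStringSet] (possibly empty).
#' @export
extract_event_sequences <- function(events, genome) {
  if (!nrow(events)) {
    return(Biostrings::DNAStringSet())
  }
  idx <- match(events$chrom, names(genome))
  if (anyNA(idx)) {
    stop(
      "chromosome '", events$chrom[is.na(idx)][1],
      "' not present in genome FASTA"
    )
  }
  chrom_len <- Biostrings::width(genome)[idx]
  lo <- pmax(events$fp_start, 0)
  hi <- pmin(events$fp_end, chrom_len)
  n_clipped <- sum(lo != events$fp_start | hi != events$fp_end)
  if (n_clipped > 0L) {
    warning(
      n_clipped, " event footprint(s) clipped to chromosome bounds",
      call. = FALSE
    )
  }
  seqs <- vapply(seq_len(nrow(events)), function(k) {
    extract_sequence(genome, events$chrom[k], lo[k], hi[k])
  }, character(1))
  names(seqs) <- sprintf(
    "%s:%s-%s|%s", events$chrom,
    fmt_coord(lo), fmt_coord(hi), events$category
  )
  Biostrings::DNAStringSet(seqs)
}

#' Event counts across a ladder of scopes
#'
#' Recounts overlap events at each scope in an ascending ladder; because
#' scoped windows nest, counts are non-decreasing, and the count at scope
#' 0 equals the number of strictly intersecting pairs. Plotting count
#' against scope exposes the inflection point where few new overlaps
#' appear, which is how the default scopes were calibrated.
#'
#' @param ref_set,exp_set Nonempty [peak_set()] objects.
#' @param scopes Ascending vector of scopes in bp.
#' @return data.frame with columns `scope` and `n_events`.
#' @export
scope_sweep <- function(ref_set, exp_set,
                        scopes = c(0, 50, 100, 250, 500, 1000, 2000)) {
  if (is.unsorted(scopes)) stop("scopes must be sorted ascending")
  n_events <- vapply(
    scopes,
    function(s) nrow(find_overlaps(ref_set, exp_set, scope = s)),
    numeric(1)
  )
  data.frame(scope = scopes, n_events = n_events)
}

#' Merge event footprints into non-overlapping loci
#'
#' Union-merges the footprints of all events into maximal non-intersecting
#' loci, the unit at which two conditions are compared by
#' [compare_experiments()].
#'
#' @param events Events from [find_overlaps()], or any data.frame with
#'   `chrom`, `fp_start`, `fp_end`.
#' @return data.frame with columns `chrom`, `start`, `end`, sorted.
#' @export
merge_loci <- function(events) {
  if (!nrow(events)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  gr <- GenomicRanges::reduce(
    as_granges0(events$chrom, events$fp_start, events$fp_end)
  )
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}
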