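# Independent oracles: deliberately naive reimplementations used only to
# check the package's optimized paths. They share no code with R/.

# Category of one (ref, exp) pair via explicit intersection arithmetic.
oracle_category <- function(rs, re, es, ee, scope) {
  inter <- min(re, ee) - max(rs, es) # bp of peak-peak intersection
  win_inter <- min(re + scope, ee) - max(rs - scope, es)
  if (win_inter <= 0) {
    return(NA_character_)
  }
  if (inter <= 0) {
    return("PXP")
  }
  exp_inside <- es >= rs && ee <= re
  ref_inside <- rs >= es && re <= ee
  if (exp_inside || ref_inside) {
    return("CRO")
  }
  if (es < rs) "ORF" else "ORE"
}

# All-pairs scan over two peak sets; returns the same columns as
# find_overlaps(), in the same deterministic order.
oracle_overlaps <- function(ref_set, exp_set, scope) {
  rows <- list()
  for (chrom in intersect(unique(ref_set$chrom), unique(exp_set$chrom))) {
    ri <- which(ref_set$chrom == chrom)
    ej <- which(exp_set$chrom == chrom)
    for (i in ri) {
      for (j in ej) {
        category <- oracle_category(
          ref_set$start[i], ref_set$end[i],
          exp_set$start[j], exp_set$end[j], scope
        )
        if (!is.na(category)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, ref_id = i,
            ref_start = ref_set$start[i], ref_end = ref_set$end[i],
            exp_id = j,
            exp_start = exp_set$start[j], exp_end = exp_set$end[j],
            category = category, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      chrom = character(), ref_id = integer(),
      ref_start = numeric(), ref_end = numeric(), exp_id = integer(),
      exp_start = numeric(), exp_end = numeric(), category = character(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(
    out$chrom, out$ref_start, out$exp_start,
    out$ref_end, out$exp_end, out$ref_id, out$exp_id
  ), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized variant for larger fuzz instances: classifies the full cross
# product per chromosome with plain arithmetic (no interval trees).
oracle_overlaps_fast <- function(ref_set, exp_set, scope) {
  pieces <- list()
  for (chrom in intersect(unique(ref_set$chrom), unique(exp_set$chrom))) {
    ri <- which(ref_set$chrom == chrom)
    ej <- which(exp_set$chrom == chrom)
    i <- rep(ri, times = length(ej))
    j <- rep(ej, each = length(ri))
    rs <- ref_set$start[i]
    re <- ref_set$end[i]
    es <- exp_set$start[j]
    ee <- exp_set$end[j]
    inter <- pmin(re, ee) - pmax(rs, es)
    win_inter <- pmin(re + scope, ee) - pmax(rs - scope, es)
    category <- rep(NA_character_, length(i))
    category[win_inter > 0] <- "PXP"
    nested <- (es >= rs & ee <= re) | (rs >= es & re <= ee)
    hit <- inter > 0
    category[hit & nested] <- "CRO"
    category[hit & !nested & es < rs] <- "ORF"
    category[hit & !nested & es >= rs] <- "ORE"
    keep <- !is.na(category)
    pieces[[chrom]] <- data.frame(
      chrom = chrom, ref_id = i[keep], ref_start = rs[keep],
      ref_end = re[keep], exp_id = j[keep], exp_start = es[keep],
      exp_end = ee[keep], category = category[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(pieces)) {
    do.call(rbind, pieces)
  } else {
    oracle_overlaps(ref_set[0, ], exp_set[0, ], scope)
  }
  out <- out[order(
    out$chrom, out$ref_start, out$exp_start,
    out$ref_end, out$exp_end, out$ref_id, out$exp_id
  ), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-base bin enumeration: a peak's occupied bins computed by walking
# every base it covers.
oracle_bin_occupancy <- function(peaks, bin_size) {
  occupied <- list()
  for (k in seq_len(nrow(peaks))) {
    bases <- seq(peaks$start[k], peaks$end[k] - 1)
    chrom <- peaks$chrom[k]
    occupied[[chrom]] <- union(occupied[[chrom]], unique(bases %/% bin_size))
  }
  lapply(occupied, sort)
}

oracle_cms <- function(ref_peaks, exp_peaks, bin_size) {
  ref_occ <- oracle_bin_occupancy(ref_peaks, bin_size)
  exp_occ <- oracle_bin_occupancy(exp_peaks, bin_size)
  n_ref <- sum(lengths(ref_occ))
  shared <- 0
  for (chrom in intersect(names(ref_occ), names(exp_occ))) {
    shared <- shared + length(intersect(ref_occ[[chrom]], exp_occ[[chrom]]))
  }
  shared / n_ref
}

# Count of strictly intersecting (>= 1 bp) pairs via GenomicRanges alone.
oracle_strict_count <- function(ref_set, exp_set) {
  levels <- sort(unique(c(ref_set$chrom, exp_set$chrom)))
  gr <- function(x) {
    GenomicRanges::GRanges(
      factor(x$chrom, levels),
      IRanges::IRanges(x$start + 1, x$end)
    )
  }
  length(GenomicRanges::findOverlaps(gr(ref_set), gr(exp_set), minoverlap = 1L))
}
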