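#' Read gene models from a GTF annotation
#'
#' Imports a GTF (1-based closed coordinates, attribute column carrying
#' `gene_id`) and returns one gene model per record whose feature type is
#' `gene`, converted to the package's 0-based half-open convention
#' (`start - 1`, `end`). When the file contains no `gene` features (some
#' annotations ship only exons/transcripts), the union span over all
#' features of each distinct `gene_id` is used instead, so the returned
#' span covers every annotated part of the gene.
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by (chrom, start, end).
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!length(gr)) stop("GTF file contains no records: ", path)
  meta <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(meta)) {
    as.character(meta$gene_id)
  } else {
    rep(NA_character_, length(gr))
  }
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad)) {
    stop(sprintf(
      "%s: record %d lacks a gene_id attribute", path, bad[1]
    ))
  }
  type <- as.character(meta$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start1 <- GenomicRanges::start(gr)
  end1 <- GenomicRanges::end(gr)
  if (any(type == "gene")) {
    keep <- type == "gene"
    out <- data.frame(
      gene_id = ids[keep], chrom = chrom[keep],
      start = start1[keep] - 1, end = as.numeric(end1[keep]),
      strand = strand[keep], stringsAsFactors = FALSE
    )
  } else {
    # union span per distinct gene_id (per chromosome, defensively)
    key <- paste(ids, chrom, sep = "\r")
    first <- !duplicated(key)
    out <- data.frame(
      gene_id = ids[first], chrom = chrom[first],
      start = as.numeric(tapply(start1, key, min)[key[first]]) - 1,
      end = as.numeric(tapply(end1, key, max)[key[first]]),
      strand = vapply(
        split(strand, key)[key[first]],
        function(s) if (length(unique(s)) == 1L) s[1] else "*",
        character(1)
      ),
      stringsAsFactors = FALSE
    )
  }
  validate_intervals(out$chrom, out$start, out$end, context = path)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a genome FASTA
#'
#' Reads a (multi-record) FASTA into a `DNAStringSet`, trimming record
#' descriptions so names are bare chromosome identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract the sequence of a genomic interval
#'
#' Returns the forward-strand sequence of the 0-based half-open interval
#' (`end - start` bases), upper-cased. The reverse complement is available
#' behind an explicit flag and is off by default, since emitted overlap
#' sequences are reported on the forward strand.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name (exact match against FASTA record names).
#' @param start,end 0-based half-open coordinates within the chromosome.
#' @param reverse_complement Return the reverse complement instead.
#' @return A character scalar of length `end - start`.
#' @export
extract_sequence <- function(genome, chrom, start, end,
                             reverse_complement = FALSE) {
  idx <- match(chrom, names(genome))
  if (is.na(idx)) {
    stop(
      "chromosome '", chrom, "' not present in genome FASTA (interval ",
      chrom, ":", fmt_coord(start), "-", fmt_coord(end), ")"
    )
  }
  chrom_len <- Biostrings::width(genome)[idx]
  if (start < 0 || end > chrom_len || start >= end) {
    stop(sprintf(
      "interval %s:%s-%s outside chromosome bounds (length %d)",
      chrom, fmt_coord(start), fmt_coord(end), chrom_len
    ))
  }
  s <- Biostrings::subseq(genome[[idx]], start = start + 1, end = end)
  if (reverse_complement) s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}
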