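test_that("classify_overlap implements the four-category decision rule", {
  # spanning experimental peak: containment either direction is CRO
  expect_equal(classify_overlap(1000, 2000, 900, 2100, 1000), "CRO")
  expect_equal(classify_overlap(1000, 2000, 1200, 1400, 1000), "CRO")
  expect_equal(classify_overlap(1000, 2000, 1000, 2000, 1000), "CRO")
  # partial overlaps at the 5' front / 3' end
  expect_equal(classify_overlap(1000, 2000, 500, 1500, 1000), "ORF")
  expect_equal(classify_overlap(1000, 2000, 1500, 2500, 1000), "ORE")
  # proximal peak only while the scoped window is reached
  expect_equal(classify_overlap(1000, 2000, 2200, 2400, 1000), "PXP")
  expect_true(is.na(classify_overlap(1000, 2000, 2200, 2400, 100)))
  expect_error(classify_overlap(1000, 2000, 900, 2100, -1), "non-negative")
})

test_that("find_overlaps emits one classified event per in-scope pair", {
  ref <- peak_set("chr1", 1000, 2000, label = "ref")
  exp <- peak_set(c("chr1", "chr1"), c(1500, 5000), c(2500, 5100),
    label = "exp"
  )
  events <- find_overlaps(ref, exp, scope = 1000)
  expect_equal(nrow(events), 1L)
  expect_equal(events$category, "ORE")
  expect_equal(events$fp_start, 1000)
  expect_equal(events$fp_end, 2500)

  # identical single-peak sets: one complete overlap
  solo <- peak_set("chr1", 100, 300)
  self_events <- find_overlaps(solo, solo, scope = 1000)
  expect_equal(self_events$category, "CRO")

  # disjoint chromosomes: no events (and a naming-mismatch warning)
  other <- peak_set("chrX", 1000, 2000)
  expect_warning(
    none <- find_overlaps(ref, other, scope = 1000),
    "share no chromosome names"
  )
  expect_equal(nrow(none), 0L)

  empty <- peak_set(character(), numeric(), numeric(), label = "void")
  expect_error(find_overlaps(empty, exp), "reference.*'void'.*empty")
  expect_error(find_overlaps(ref, empty), "experimental.*'void'.*empty")
})

test_that("find_overlaps matches the all-pairs oracle on random instances", {
  set.seed(301)
  for (rep in 1:25) {
    scope <- sample(c(0, 50, 250, 1000), 1)
    ref <- rand_peak_set(sample(1:40, 1), chrom_len = 2e4)
    exp <- rand_peak_set(sample(1:40, 1), chrom_len = 2e4)
    got <- find_overlaps(ref, exp, scope = scope)
    want <- oracle_overlaps(ref, exp, scope)
    expect_equal(as.data.frame(got)[, names(want)], want)
  }
})

test_that("results are strand-neutral by default, strand-aware on request", {
  set.seed(77)
  ref <- rand_peak_set(60)
  exp <- rand_peak_set(60)
  stranded_ref <- ref
  stranded_ref$strand <- sample(c("+", "-"), nrow(ref), replace = TRUE)
  base <- find_overlaps(ref, exp, scope = 250)
  with_strand <- find_overlaps(stranded_ref, exp, scope = 250)
  expect_equal(as.data.frame(base)[, c("chrom", "ref_start", "exp_start", "category")],
    as.data.frame(with_strand)[, c("chrom", "ref_start", "exp_start", "category")])

  # stranded mode swaps 5'/3' labels on minus-strand reference peaks only
  aware <- find_overlaps(stranded_ref, exp, scope = 250, stranded = TRUE)
  minus <- aware$ref_strand == "-"
  swap <- c(ORF = "ORE", ORE = "ORF", CRO = "CRO", PXP = "PXP")
  expect_equal(aware$category[minus], unname(swap[with_strand$category[minus]]))
  expect_equal(aware$category[!minus], with_strand$category[!minus])
})

test_that("event counts are monotone in scope and nest as event sets", {
  set.seed(404)
  ref <- rand_peak_set(80)
  exp <- rand_peak_set(80)
  scopes <- c(0, 50, 250, 1000, 2000)
  sweep <- scope_sweep(ref, exp, scopes)
  expect_true(all(diff(sweep$n_events) >= 0))
  expect_equal(sweep$scope, scopes)
  expect_error(scope_sweep(ref, exp, c(100, 0)), "ascending")

  # events at a smaller scope are a subset with unchanged categories
  small <- as.data.frame(find_overlaps(ref, exp, scope = 50))
  large <- as.data.frame(find_overlaps(ref, exp, scope = 1000))
  key <- function(events) {
    paste(events$chrom, events$ref_id, events$exp_id, events$category)
  }
  expect_true(all(key(small) %in% key(large)))

  # scope 0 equals strict intersection: proximal peaks are impossible
  strict <- as.data.frame(find_overlaps(ref, exp, scope = 0))
  expect_equal(nrow(strict), oracle_strict_count(ref, exp))
  expect_false(any(strict$category == "PXP"))
})

test_that("events stay silent until the scope reaches an engineered gap", {
  # experimental peaks planted exactly 5 kb downstream of each reference
  ref <- peak_set(rep("chr1", 3), c(10000, 30000, 60000), c(10500, 30500, 60500))
  exp <- peak_set(rep("chr1", 3), c(15500, 35500, 65500), c(16000, 36000, 66000))
  sweep <- scope_sweep(ref, exp, scopes = c(0, 1000, 2500, 4999, 5000, 6000))
  expect_equal(sweep$n_events, c(0, 0, 0, 0, 0, 3))
  expect_equal(
    find_overlaps(ref, exp, scope = 5001)$category,
    rep("PXP", 3)
  )
})

test_that("build_profile reproduces the hand-computed single-event tracks", {
  ref <- peak_set("chr1", 1000, 2000)
  exp <- peak_set("chr1", 1500, 2500)
  scope <- 1000
  events <- find_overlaps(ref, exp, scope = scope)
  profile <- build_profile(events, ref, scope)
  # Lmax = 1000, half-width = scope + 500 = 1500, midpoint = 1500
  expect_equal(profile$half_width, 1500L)
  expect_equal(profile$offsets, seq(-1500L, 1499L))
  df <- as.data.frame(profile)
  expect_equal(df$ORE, as.integer(df$offset >= 0 & df$offset < 1000))
  expect_equal(df$Reference, as.integer(df$offset >= -500 & df$offset < 500))
  expect_true(all(df$CRO == 0L) && all(df$ORF == 0L) && all(df$PXP == 0L))

  # zero events: all-zero tracks of the same geometry
  empty_profile <- build_profile(events[0, ], ref, scope)
  expect_true(all(empty_profile$counts == 0L))
  expect_equal(dim(empty_profile$counts), c(3000L, 5L))
})

test_that("profile tracks are additive in events and reference peaks", {
  ref <- peak_set("chr1", 1000, 2000)
  exp1 <- peak_set("chr1", 1500, 2500)
  # duplicated experimental peak: category track doubles, reference
  # track (counted once per participating peak) does not
  exp2 <- peak_set(c("chr1", "chr1"), c(1500, 1500), c(2500, 2500))
  p1 <- build_profile(find_overlaps(ref, exp1, 1000), ref, 1000)
  p2 <- build_profile(find_overlaps(ref, exp2, 1000), ref, 1000)
  expect_equal(p2$counts[, "ORE"], 2L * p1$counts[, "ORE"])
  expect_equal(p2$counts[, "Reference"], p1$counts[, "Reference"])
  # duplicated reference peak: both participate, reference track doubles
  ref2 <- peak_set(c("chr1", "chr1"), c(1000, 1000), c(2000, 2000))
  p3 <- build_profile(find_overlaps(ref2, exp1, 1000), ref2, 1000)
  expect_equal(p3$counts[, "Reference"], 2L * p1$counts[, "Reference"])
  expect_equal(p3$counts[, "ORE"], 2L * p1$counts[, "ORE"])
})

test_that("per-chromosome profiles partition the global profile", {
  set.seed(88)
  ref <- rand_peak_set(60, chroms = c("chr2L", "chrX"))
  exp <- rand_peak_set(60, chroms = c("chr2L", "chrX"))
  events <- find_overlaps(ref, exp, scope = 500)
  global <- build_profile(events, ref, 500)
  per_chrom <- per_chromosome_profiles(events, ref, 500)
  expect_setequal(names(per_chrom), unique(events$chrom))
  summed <- Reduce(`+`, lapply(per_chrom, `[[`, "counts"))
  expect_equal(summed, global$counts)
  # single-chromosome case: the per-chromosome profile IS the global one
  chr_events <- events[events$chrom == "chrX", ]
  only <- per_chromosome_profiles(chr_events, ref, 500)
  expect_equal(names(only), "chrX")
  expect_equal(only$chrX$counts, build_profile(chr_events, ref, 500)$counts)
})

test_that("annotate_genes intersects merged footprints with gene spans", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(250, 300, 20000), end = c(900, 900, 21000),
    strand = "+", stringsAsFactors = FALSE
  )
  events <- find_overlaps(
    peak_set("chr1", 100, 200), peak_set("chr1", 150, 300),
    scope = 1000
  )
  expect_equal(events$fp_start, 100)
  expect_equal(events$fp_end, 300)
  # 50 bp intersection with g1; g2 touches at 300 (half-open: no overlap)
  expect_equal(annotate_genes(events, genes), list("g1"))
  # footprint spanning two genes reports both
  wide <- find_overlaps(
    peak_set("chr1", 100, 200), peak_set("chr1", 150, 950),
    scope = 1000
  )
  expect_equal(annotate_genes(wide, genes), list(c("g1", "g2")))
  # no gene in range: empty set, not a missing entry
  far <- find_overlaps(
    peak_set("chr2", 100, 200), peak_set("chr2", 150, 300),
    scope = 1000
  )
  expect_equal(annotate_genes(far, genes), list(character()))
})

test_that("extract_event_sequences emits one footprint record per event", {
  fasta <- write_tmp_lines(c(">chrT", "ACGTACGT"), ext = ".fa")
  genome <- read_genome(fasta)
  events <- find_overlaps(
    peak_set("chrT", 2, 4), peak_set("chrT", 3, 5),
    scope = 2
  )
  seqs <- extract_event_sequences(events, genome)
  expect_equal(names(seqs), "chrT:2-5|ORE")
  expect_equal(as.character(seqs[[1]]), "GTA")
  # duplicate footprints are preserved, not deduplicated
  dup_exp <- peak_set(c("chrT", "chrT"), c(3, 3), c(5, 5))
  dup_seqs <- extract_event_sequences(
    find_overlaps(peak_set("chrT", 2, 4), dup_exp, scope = 2), genome
  )
  expect_equal(length(dup_seqs), 2L)
  # footprints past the chromosome end are clipped with a warning
  over <- find_overlaps(
    peak_set("chrT", 2, 4), peak_set("chrT", 3, 12),
    scope = 10
  )
  expect_warning(
    clipped <- extract_event_sequences(over, genome),
    "clipped"
  )
  expect_equal(as.character(clipped[[1]]), "GTACGT")
  expect_equal(length(extract_event_sequences(events[0, ], genome)), 0L)
})

test_that("run_bindcompare writes a complete, deterministic output set", {
  out1 <- tempfile("run")
  dir <- minimal_compare_run(out1)
  expect_true(all(file.exists(file.path(dir, c(
    "events.bed", "events.csv", "summary.csv", "profile.csv",
    "manifest.json"
  )))))
  events_lines <- readLines(file.path(dir, "events.bed"))
  expect_equal(length(events_lines), 1L)
  expect_match(events_lines, "^chr1\t1000\t2500\tORE")
  summary <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(summary$count[summary$category == "ORE"], 1L)
  expect_equal(sum(summary$count), 1L)
  # optional annotation absent: no gene or sequence outputs, no error
  expect_false(file.exists(file.path(dir, "genes.txt")))
  expect_false(file.exists(file.path(dir, "events.fa")))
  # reruns are byte-identical for every table
  out2 <- minimal_compare_run(tempfile("run"))
  for (file in c("events.bed", "events.csv", "summary.csv", "profile.csv")) {
    expect_identical(
      readLines(file.path(out1, file)),
      readLines(file.path(out2, file)),
      label = file
    )
  }
})

test_that("run_bindcompare attaches genes and sequences when annotated", {
  gtf <- write_tmp_lines(
    "chr1\tsrc\tgene\t1201\t3000\t.\t+\t.\tgene_id \"target1\";",
    ext = ".gtf"
  )
  fasta <- write_tmp_lines(
    c(">chr1", paste(rep("ACGT", 1000), collapse = "")),
    ext = ".fa"
  )
  dir <- minimal_compare_run(tempfile("annot"), gtf = gtf, fasta = fasta)
  expect_equal(readLines(file.path(dir, "genes.txt")), "target1")
  fa <- Biostrings::readDNAStringSet(file.path(dir, "events.fa"))
  expect_equal(length(fa), 1L)
  expect_equal(Biostrings::width(fa), 1500L)
  expect_match(names(fa), "chr1:1000-2500\\|ORE")
  events <- utils::read.csv(file.path(dir, "events.csv"))
  expect_equal(events$genes, "target1")
})
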