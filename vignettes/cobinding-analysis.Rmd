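---
title: "Co-binding analysis of protein–nucleic-acid peak sets"
author: "cobindkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-binding analysis of protein–nucleic-acid peak sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobindkit)
```

## The problem and the model

Peak callers reduce a binding assay (ChIP-seq, CUT&RUN, eCLIP) to a BED
file of genomic intervals. Given several such files, the questions this
package addresses are combinatorial: which factors bind the same loci,
where exactly an experimental factor sits relative to a reference
factor's peaks, and which shared loci appear or disappear between two
experimental conditions. No signal-level data (bigWig, BAM) is used
anywhere: the peak intervals are the data.

Coordinates are 0-based half-open (BED-native) at every user-facing
surface. GTF input (1-based closed) is converted on read; using one
convention everywhere removes a whole class of off-by-one errors.
Touching intervals (`end == start`) do **not** overlap.

### Stage 1: binned co-binding screening

The genome is partitioned into bins of width $b$ (bin $i$ covers
$[ib, (i+1)b)$); no chromosome-length file is needed because bin
indices derive from coordinates alone. Each dataset becomes the *set*
of bins its peaks touch: a peak occupies every bin it overlaps by at
least 1 bp (a midpoint-assignment rule was rejected because it
undercounts peaks longer than a bin), and multiple peaks in a bin count
once. For an ordered pair with reference $r$ and experimental $e$,

$$\mathrm{CMS}(r, e) = \frac{|B_r \cap B_e|}{|B_r|} \in [0, 1],$$

where $B_x$ is the occupied-bin set. The normalization by the
*reference* makes the matrix asymmetric — CMS$(r,e)$ reads "the
fraction of $r$'s binding territory that $e$ also occupies" — so the
orientation is fixed and documented: matrix rows are the reference.
Diagonal entries are computed like any other entry (they equal 1 for
any nonempty dataset), which doubles as a self-test. A reference with
zero occupied bins is an error, never a silent 0. No significance test
is attached to CMS: the score is a screening statistic, and a proper
null would need a genome-composition model the method does not define.

### Stage 2: scoped overlap classification

Given a reference set and an experimental set, each reference peak
$[s, e)$ defines a scoped window $[s - \sigma, e + \sigma)$. Every
experimental peak intersecting the window yields one event, classified
exhaustively and exclusively:

* **CRO** — containment in either direction (experimental peak inside
  the reference or spanning it; equal endpoints count). A nested
  experimental peak is neither a 5′ nor a 3′ partial overlap, so
  containment is treated as one category; the rule lives in a single
  function (`classify_overlap()`) so it is trivial to revise.
* **ORF** — partial intersection with `exp_start < ref_start`
  (extends past the reference 5′ front).
* **ORE** — partial intersection extending past the 3′ end.
* **PXP** — no intersection with the peak but intersection with the
  window. The proximity criterion is edge-to-edge distance, not
  midpoint distance, so it does not depend on peak lengths.

5′/3′ follow genomic orientation by default; an opt-in stranded mode
swaps ORF/ORE for minus-strand reference peaks. Events are one per
(reference, experimental) pair: an experimental peak near two reference
peaks yields two events, and summary counts are deliberately not
deduplicated — the analysis is reference-centric, and collapsing would
hide multi-reference proximity. At $\sigma = 0$ the window is the peak
itself, PXP becomes impossible, and the event count equals the strict
intersection count — the scoped search only ever *adds* proximal
events, which is the point of the scope: biologically related binding
events rarely align base-for-base, because of assay resolution and
nucleic-acid folding. Default scopes are 1000 bp (DNA) and 250 nt
(RNA), the inflection region where event counts stop growing quickly
in scope sweeps (`scope_sweep()` emits the count-vs-scope table for
any dataset pair so users can check the elbow on their own data).

The candidate search uses interval trees (GenomicRanges) over
scope-extended reference windows; the classifier itself is plain
arithmetic, and the test suite checks the tree-based path against an
independent all-pairs classifier on hundreds of random instances.

### Binding profiles

Each event contributes coverage to a positional profile anchored at the
midpoint $m = \lfloor (s + e)/2 \rfloor$ of its reference peak. The
half-width is $\sigma + \lceil L_{\max}/2 \rceil$ with $L_{\max}$ the
longest reference peak in the run, which guarantees every scoped event
fits the window. For every base of the experimental peak inside the
window, the event's category track is incremented at that base's offset
from $m$; the `Reference` track accumulates each participating
reference peak's own coverage once, giving the "average reference
peak" the category tracks are read against. Midpoint anchoring (rather
than start-anchoring or length-normalized metagenes) keeps counts
interpretable: a track value is literally "this many events of this
category covered this offset". Per-chromosome profiles are the same
construction on the chromosome partition of the events, built with the
global half-width so they sum position-wise to the global profile —
an invariant the tests assert.

### Annotation

An event's merged footprint is the bounding interval
$[\min(s_r, s_x), \max(e_r, e_x))$ of its two peaks (for PXP this
includes the gap — the footprint is the co-regulated neighborhood, and
a gene in the gap between two proximal peaks is a plausible joint
target). Genes whose spans intersect the footprint by ≥ 1 bp are
attached; footprint sequences are emitted as FASTA for motif tools.
Footprints are union-merged into non-overlapping *loci*, the unit of
stage 3.

### Stage 3: cross-condition comparison

Two completed runs are compared at the locus level: a locus pair (one
per condition) is *common* when the intervals intersect by ≥ 1 bp;
loci with no cross-condition intersection are *unique*. No scope is
re-applied here — proximity was already folded in when events were
called, and re-expanding would double-count it. Class gene lists are
unions over member loci, so a gene hit by distinct loci can appear in
more than one class; this is reported as-is rather than arbitrated.
Counts are reported at the locus level, not the event level, so the
Venn numbers are not inflated by many-to-many event pairings.

## The synthetic-data generator

`generate_cobound_peaks()` emulates a pair of peak-called experiments
with known ground truth: reference peaks placed uniformly (proportional
to chromosome length) without self-overlap; each reference receives an
experimental partner with probability `co_fraction`, its start
displaced by a draw from the offset model and its width from the length
model; background experimental peaks are placed uniformly and, by
default, rejection-sampled out of every scoped reference window so that
any detected event traces back to a planted partner (a `contaminated`
mode skips the rejection for realistic-noise tests). The truth table
records every planted partner and its intended category, computed from
the planted geometry independently of the classifier under test.

Defaults — two 10-Mb chromosomes, 1000 reference peaks of 150–350 bp,
`co_fraction` 0.5, partner offsets uniform in ±250 bp, 500 background
peaks — describe a modest metazoan ChIP-like study: peak widths and
densities in the few-hundred-bp / one-per-10-kb range are typical of
point-source factors. What the generator does *not* emulate: peak-width
and offset correlations with signal strength, chromatin-driven
clustering of peaks, mappability gaps, and replicate structure. Tests
passing on these fixtures therefore validate the *interval logic and
accounting*, not peak calling or any biological claim about real
datasets.

Two calibration facts the tests rely on, both consequences of the
model rather than tuned values: with partners at offset 0 and bin size
much larger than peak width, CMS(reference → experimental) estimates
`co_fraction` with bias only from distinct peaks colliding in one bin
(kept below 0.02 by using a 400-Mb genome for the 10,000-peak
convergence check); with partner offsets up to ±50 bp on 100-bp peaks,
boundary-crossing losses depress the estimate by roughly 2%, so a
planted 0.6 is recovered near 0.59.

## Numerical and interface choices

* Problem sizes in the test suite (instances of 50–400 peaks per side
  plus one 2000-per-side instance for the classifier oracle; 10
  replicates of 5000 peaks for fraction recovery; one 10,000-peak
  convergence check) were chosen as the smallest sizes at which the
  asserted properties are non-trivial and stable.
* Determinism: every generator call is a pure function of its spec
  including the seed (the caller's RNG state is saved and restored);
  rerunning any pipeline stage on the same inputs reproduces each
  table byte for byte. Run manifests list every emitted file and the
  fully resolved parameters, and differ across reruns only in their
  timestamp.
* Degenerate inputs fail loudly at the pipeline boundary: empty BED
  files, a reference with no occupied bins, infeasible simulation
  requests and malformed records (including zero-width and inverted
  intervals, with file and line in the message) are errors, not
  warnings or silent defaults. The one deliberate softening: event
  footprints running past a chromosome end during sequence extraction
  are clipped with a warning, since the footprint (peak + gap) can
  legitimately overhang the assembly edge.
* Chromosome names are matched by exact string equality. When two
  inputs share no chromosome names at all, a warning points at the
  likely `chr1` vs `1` convention clash instead of silently returning
  empty results — and instead of guessing a prefix normalization that
  would hide genuine mismatches.
* Plots (heatmap, profile, category bars) are rendered from the
  emitted CSVs, never from internal state, so the tested artifacts are
  the tables.

## Known limitations

* No statistical significance is attached to any overlap count or CMS
  value; the outputs are ranked hypotheses for experimental follow-up.
* Comparison of more than two conditions is composed from pairwise
  runs rather than supported natively.
* Scores are not corrected for genome composition or mappability;
  datasets with very different peak counts should be read through the
  asymmetric normalization (each direction separately).
* BED scores and columns beyond 6 are ignored by design; the method
  consumes locations only.
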