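# cobindkit

Tools for comparing peak-called protein–nucleic-acid binding datasets.
ChIP-seq, CUT&RUN and eCLIP experiments each reduce to a BED file of
called peaks; the biological question is usually combinatorial — which
transcription factors and RNA-binding proteins bind the *same* loci, and
which targets appear or disappear when a partner factor is perturbed.
`cobindkit` answers this in three stages, for any organism with an
annotated genome:

1. **explore** — screen N datasets at once. The genome is split into
   fixed bins (default 1000 bp) and every dataset is reduced to its set
   of occupied bins. For an ordered pair (reference *r*, experimental
   *e*) the co-binding correlation score is

   CMS(r, e) = |bins occupied by both| / |bins occupied by r|,

   an asymmetric fraction in [0, 1], rendered as an N×N heatmap
   (rows = reference).
2. **compare** — deep pairwise analysis. Every experimental peak within
   a *scope* (default 1000 bp DNA / 250 nt RNA) of a reference peak
   becomes one event, classified as **CRO** (complete overlap — one peak
   contains the other), **ORF** (partial overlap past the reference 5′
   edge), **ORE** (partial overlap past the 3′ edge) or **PXP**
   (proximal: within scope but not intersecting). Events are aggregated
   into positional binding profiles around reference-peak midpoints,
   globally and per chromosome, and annotated with genes (GTF) and
   sequences (FASTA) for downstream GO/motif analysis.
3. **comparexp** — compare two completed runs (e.g. wild-type vs
   knockdown) and report overlap loci unique to each condition and
   common to both, with per-class gene lists.

A synthetic-data module simulates peak sets with a planted co-binding
fraction, controlled partner offsets and background peaks, so the whole
pipeline is validated without downloading public datasets.

## Worked example

Simulate a study with the default conditions (1000 reference peaks,
planted co-binding fraction 0.5, 500 background peaks on two 10-Mb
chromosomes), then compare the two peak sets:

```r
library(cobindkit)

spec <- synthetic_spec(seed = 42)
sim  <- generate_cobound_peaks(spec, out_dir = "demo")
res  <- run_bindcompare("demo/ref.bed", "demo/exp.bed", "demo_out",
                        scope = 1000, plots = FALSE)
res
#> bindcompare result: 539 events over 472 merged loci (scope 1000)
#>    CRO=70  ORF=176  ORE=205  PXP=88
#>   outputs in: demo_out
```

About half the reference peaks have a planted partner, and the category
split says how those partners sit: 70 are fully nested (CRO), 381
overlap one edge (ORF + ORE), and 88 only come within the 1000-bp scope
(PXP). The same pair scored by binned co-binding:

```r
round(correlation_matrix(list(ref = sim$ref, exp = sim$exp)), 3)
#>       ref   exp
#> ref 1.000 0.441
#> exp 0.459 1.000
```

i.e. 44% of reference-occupied kilobase bins are also occupied by the
experimental dataset — the planted 0.5 co-binding fraction minus
partners that drift across a bin boundary. Widening the scope finds
more events at a decreasing rate, which is how the defaults were
calibrated:

```r
scope_sweep(sim$ref, sim$exp, c(0, 250, 1000, 2000))
#>   scope n_events
#> 1     0      451
#> 2   250      497
#> 3  1000      539
#> 4  2000      627
```

`run_bindcompare()` writes `events.bed`, `events.csv`, `summary.csv`,
`profile.csv`, `profiles_by_chrom/*.csv` and a `manifest.json`
(plus `genes.txt` / `events.fa` when a GTF / FASTA is supplied); every
plot is derived from these tables. The same functionality is available
from a shell via the installed `cobindkit` script:

```sh
cobindkit compare --ref demo/ref.bed --exp demo/exp.bed --out demo_out
cobindkit explore --beds a.bed b.bed c.bed --out screen
cobindkit comparexp --exp1 run_wt/ --exp2 run_kd/ --out diff
```

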