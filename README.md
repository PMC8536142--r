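# strdecomp

Alignment-free comparison of genomic region classes by k-mer spectrum
correlation decomposition.

## The problem

Introns and intergenic regions (IIRs) of eukaryotic genomes carry sequence
structure that is conserved far beyond what alignment-based tools can
detect at genome scale. A practical way to quantify it is *k-mer analysis*:
count all 4^k overlapping words of length k on one strand of a region
class, and compare two region sets by the Pearson correlation r of their
frequency vectors. A high correlation between, say, the intron spectrum of
one genome and the intergenic spectrum of another indicates shared
composition structure — but not *which* words carry it.

`strdecomp` implements the full toolchain around this statistic for R:

* **Region extraction** — genes, exons, CDS, introns and intergenic
  regions from FASTA + GFF3 (or a minimal GenBank feature table), with
  per-class composition statistics and BED/GFF3 export.
* **Spectra and word algebra** — k-mer spectra (k = 1..11, single strand,
  ambiguous windows skipped), tandem-repeat word enumeration by minimal
  repeat unit length b, the extended base-code families (polyW, polyS,
  homoW/S/R/Y/K/M), Hamming-1 neighborhoods and G+C-content word bins.
* **Markov null models** — zero- and first-order reference models at a
  target G+C with strand-symmetric structure; replicate ensembles give the
  significance reference (mean ± sd) for every statistic.
* **Correlation decomposition** — the share of the covariance numerator of
  r attributable to any word set:
  `c(S) = Σ_{w∈S} (x_w − x̄)(y_w − ȳ) / Σ_{all w} (x_w − x̄)(y_w − ȳ)`.
  Contributions are exactly additive over any partition of word space and
  may be negative. Mismatch-tolerant variants pool a word with its 3k
  Hamming-1 neighbors (0-mm vs ≤1-mm contributions and their ratios).
* **Pattern analysis** — strand-pattern classification of STR words
  (inverse complement vs shift sequence, e.g. TGTGTGT vs CACACAC for
  ACACACA), single-mismatch deviation profiles with ambiguity bands and
  strong-tendency calls, the deviation rule engine, and a two-way
  high/low-correlation genome grouping.
* **Synthetic genomes** — annotated multi-chromosome genomes with
  first-order Markov background, codon-like period-3 CDS structure, and
  planted STR tracts with controlled substitution preferences, so the
  whole pipeline is testable without downloads.

## Worked example

Two synthetic 0.5 Mbp genomes with (AT)n and polyA tracts planted in their
introns and intergenic regions; how much of the intron–intergenic
correlation do b ≤ 2 tandem-repeat words explain, compared with a matched
Markov reference?

```r
library(strdecomp)

mk <- function(seed) synthetic_genome_config(
  chromosomes = c(chr1 = 500000L), gc = 0.40, gene_density = 150,
  str_planting = list(
    list(region = "intronic",   unit = "AT", rate_per_mbp = 250),
    list(region = "intergenic", unit = "AT", rate_per_mbp = 250),
    list(region = "intronic",   unit = "A",  rate_per_mbp = 250),
    list(region = "intergenic", unit = "A",  rate_per_mbp = 250)),
  seed = seed)

g1 <- generate_genome(mk(1)); g2 <- generate_genome(mk(2))
r1 <- derive_regions(g1);     r2 <- derive_regions(g2)

x <- compute_spectrum(extract_sequences(r1$intronic,   g1$sequences), k = 7)
y <- compute_spectrum(extract_sequences(r2$intergenic, g2$sequences), k = 7)

pearson_correlation(x, y)
#> kmer_correlation: r = 0.8337 (k=7; x vs y)

grouped_contributions(x, y, "str_b")
#>         set n_words contribution
#> 1        b1       4    0.1051717
#> 2        b2      12    0.1215356
#> 3        b3      60    0.0118954
#> 4 remaining   16308    0.7613973

str_reference_bound(ks = 7, gc_levels = 0.4, length = 1e6,
                    n_replicates = 5, seed = 1)
#>   k max_contribution max_percent gc_at_max
#> 1 7       0.01036514    1.036514       0.4
```

The 16 tandem-repeat words with repeat unit length b ≤ 2 — 0.1 % of the
7-mer word space — carry about 23 % of the intron–intergenic correlation,
roughly 22× the maximum such contribution between replicate spectra of a
first-order Markov model at the same G+C content. That contrast (large in
IIRs, reference-level in CDS) is the package's core read-out; the b = 3
row stays near the null because codon-like period-3 structure only matters
in coding comparisons.

Deviation patterns of the planted words (which base substitutes inside
tracts) are profiled with `deviation_profile()` and checked against the
rule engine with `expected_deviation_ranking()` / `rule_coverage()`.

## Full pipeline

```r
cfg <- run_config(genomes = list(gA = mk(1), gB = mk(2)), ks = c(7),
                  reference = list(order = 1, gc = 0.4, length = 1e6,
                                   replicates = 5),
                  out_dir = "run_out", seed = 1)
run_pipeline(cfg)
```

writes per-genome spectra, genome×genome correlation matrices per region
pair, reference-subtracted mean correlations, contribution tables (b
partition and base-code families), 0-mm/1-mm ratio tables, strand-pattern
calls, deviation profiles with rule coverage, and a manifest with the
configuration hash. The same pipeline is scriptable from the shell via
`inst/cli/strdecomp-cli.R` (subcommands `simulate`, `regions`, `spectrum`,
`run-all`).

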