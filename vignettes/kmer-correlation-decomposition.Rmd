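---
title: "Methods: k-mer spectrum correlation decomposition for genomic regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer spectrum correlation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strdecomp)
```

This vignette is the package's own account of its statistical methods: the
model behind each statistic, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method leaves room.

## 1. The statistic

For a set of sequences (a region class of a genome) the *k-mer spectrum*
is the vector of counts of all 4^k words of length k in overlapping
windows along **one strand**; windows containing any non-ACGT letter are
skipped and windows never span two sequences. Counts are converted to
frequencies (count / valid windows) so that region classes of unequal size
are comparable, and two spectra are compared by the Pearson correlation r
over the 4^k-dimensional frequency vectors.

Two modelling commitments follow from the questions the statistic serves:

* **Single-strand counting, no canonicalization.** Collapsing each word
  with its reverse complement would erase exactly the signal the
  strand-pattern analysis looks for (violations of equal distribution of a
  word and its inverse complement on one strand, the k-mer analogue of
  Chargaff's second parity rule).
* **No cross-k comparisons.** Correlations at different k are on different
  scales (longer words are closer to unique, so r decreases with k); the
  interface refuses to correlate spectra of different k.

## 2. Correlation decomposition

The numerator of r is a sum over words of centered cross-products. The
*contribution* of a word set S is its share of that numerator:

$$c(S) \;=\; \frac{\sum_{w \in S} (x_w - \bar x)(y_w - \bar y)}
                 {\sum_{w} (x_w - \bar x)(y_w - \bar y)}.$$

We decompose the covariance (numerator), not r itself: this makes
contributions exactly additive — over any partition of word space they sum
to 1, which the test suite asserts to 1e-9 — at the price that c(S) is a
*share of covariance*, not a correlation. Contributions can be negative
(anticorrelated words) and, when the denominator is small, individual
shares can exceed 1; both are reported as-is. A zero covariance (exactly
orthogonal centered spectra) leaves every contribution undefined and is a
hard error rather than a NaN.

Word sets of interest are built by `enumerate_str_words()` (all words of
minimal repeat-unit period exactly b — 4 words for b = 1, 12 for b = 2,
60 for b = 3, so b-classes are disjoint), `word_family_sets()` (the
extended base-code families polyA/C/G/T, polyW/S, homoW/S/R/Y/K/M) and
`gc_bin_sets()` (a partition by G+C letter content).

**Mismatch tolerance.** `mismatch_contribution(x, y, w, max_mm = 1)` pools
a word with its 3k Hamming-distance-1 neighbors, leaving the denominator
unchanged, so the ≤1-mm contribution is directly comparable to the 0-mm
one; `contribution_ratio_table()` reports the ratio c1/c0 per word, with
rows at c0 = 0 flagged instead of divided. Note a subtlety of
mean-centering: a neighbor with zero counts still enters with centered
value −x̄, so constructions "where only two words occur" give c1 = c0 only
up to O(x̄²) terms — at k = 7 an effect below 1e-6.

## 3. Markov reference models

Observed contributions mean little without a null. The reference is a
replicate ensemble of random sequences: five independent simulations per
condition, spectra computed exactly as for real data, and every downstream
statistic evaluated per replicate pair and summarized as mean ± sd. Mean
correlations of real pairs are reported as `real − reference` with the two
standard deviations combined in quadrature; because reference correlations
can be negative, the difference can exceed 1.

* **Order 0** preserves base composition only (parameterized by target
  G+C).
* **Order 1** additionally carries nearest-neighbor structure. The method
  statement fixes only the G+C range (25–50 %), not the transition
  structure, so the package declares one: a reversible chain built from a
  symmetric dinucleotide distribution in which the joint probability of
  two adjacent bases of the same W/S class is boosted by a persistence
  factor λ (default 1.2, within the range of dinucleotide odds ratios
  observed in real genomes), with base weights solved (by `uniroot`, to
  1e-14) so the stationary G+C equals the target exactly. The stationary
  distribution always satisfies p(A) = p(T), p(C) = p(G), so the model is
  strand-symmetric — a property the parity tests rely on. λ = 1 recovers
  an order-0 model; at G+C = 50 % a λ > 1 keeps the expected spectrum
  non-flat, so replicate-pair covariances stay away from the degenerate
  zero-denominator regime.

Sequence simulation is a compiled sequential chain driven by R's RNG, so a
seed fully determines the output; a master seed spawns per-replicate child
seeds. **Reference length** defaults to 10 Mbp per replicate in the
acceptance computations — a desk-scale stand-in for much longer reference
simulations. At 10 Mbp the deterministic (model-structure) part of every
b ≤ 2 contribution is unchanged and the sampling noise on the k = 7 and
k = 11 statistics is small against the bounds being checked; the residual
seed-to-seed variation of the k = 7 maximum is about ±0.02 percentage
points.

With this reference, the combined contribution of the sixteen b ≤ 2 STR
words to replicate-pair correlations stays below ~2 % at k = 7 and well
below 0.2 % at k = 11 across G+C 25–50 % (`str_reference_bound()`), which
is the yardstick against which genomic STR contributions an order of
magnitude larger are judged significant.

## 4. Region classes

Regions derive from gene/exon/CDS features (GFF3, 1-based inclusive, or a
minimal GenBank feature table), normalized internally to 0-based half-open
intervals:

* genic = union of gene spans; intergenic = its complement;
* exonic / CDS = unions of the respective features, merged per strand;
* intronic = per gene, the gene span minus that gene's exons, then minus
  **all** exons genome-wide.

The last rule is a declared policy for overlapping genes (the region
definitions upstream of this package do not specify one): it guarantees
that no base is simultaneously exonic and intronic, so genic + intergenic
= 100 % and the per-base oracle in the test suite can label every position
uniquely. Orientation policy: introns and intergenic sequences are taken
from the forward assembly strand (strand analysis requires a fixed
strand); exon/CDS sequences follow annotated gene orientation so codon
(period-3) structure survives extraction. Both policies are overridable.

## 5. Pattern analyses

**Strand patterns.** For an STR word w, the contribution of w is compared
with that of its inverse complement and of its *shift sequence* (the same
infinite repeat read one position later). "Nearly equal" is undefined in
the source analyses; the package declares a relative-difference tolerance
(|a−b| / max(|a|,|b|) ≤ tol, default 0.25) and records it in every call so
classifications are reproducible. For homoW/homoS words at odd k the
inverse complement *is* the shift sequence; the classifier returns the
structural call `inv_compl_eq_shift` rather than pretending the two
comparisons are distinct.

**Deviation profiles.** For a family word, each Hamming-1 neighbor's count
is attributed to the substituted base; percentages of the total neighbor
mass are reported, with neighbors that are themselves members of the same
family excluded to avoid self-counting. Ambiguity bands: a homopolymer
profile is ambiguous when all three values lie in [30, 40] %; a
dinucleotide-repeat profile when all four lie in [20, 30] % with at most
one value rounding to 30; a strong tendency is any value above 42.5 %.
Profiles from several genomes are computed per genome and averaged
(pooling before normalization is available but not the default, since
genome sizes would otherwise weight the mixture).

**The deviation rule engine** encodes the observed substitution
regularities as ordered rules: (1) the first rank is a W base — A if the
repeat contains G, T if it contains C; for unit-2 repeats both W bases
take ranks 1–2 with the repeat's own W base first; (2) for homoR/homoY and
polyW the second rank is the class-matching S base (G for R-repeats, C for
Y-repeats); (3) for polyW the first two ranks swap. Two recorded details
deserve note. First, the engine keeps (GT)n → A, T as a recorded
exception to the own-W-base-first clause of rule 1 (the source table
itself lists it that way, against its "mostly" wording, while (TG)n is
T, A). Second, for homoR the source table's illustrating cell contradicts
its own rule text; the engine follows the rule text ((AG)n → A, G — the
second rank is the class-matching S base, exactly as the homoY cell
(CT)n → T, C follows it). `rule_coverage()` reports the fractions of
observed profiles matched by the expectations, ambiguous, or neither.

**Genome subsets.** The two-way split of a genome×genome correlation
matrix into high/low-correlation subsets is implemented as a transparent
pool-growing heuristic (seed at the genome with the highest mean
off-diagonal correlation; admit genomes whose mean correlation to the pool
exceeds a threshold, default 0.5, until stable). It is an explicit
algorithmic surrogate for what is otherwise a visual call on a heatmap,
and its threshold is surfaced.

## 6. The synthetic-genome generator

`generate_genome()` produces the stated world the tests operate in:

* first-order Markov background at the configured G+C (default 40 %, a
  typical eukaryotic value) with the λ = 1.2 persistence of the reference
  models;
* non-overlapping genes at a configurable density (default 200 genes/Mbp,
  a compact-genome figure appropriate for the 0.1–1 Mbp test genomes) with
  geometric-tailed exon (mean 200 bp) and intron (mean 400 bp) lengths;
* CDS letters drawn from a period-3 positional base profile (blend
  strength 0.5) in gene orientation, giving coding regions the b = 3
  signal real codon usage produces;
* STR tracts planted in a chosen region class at a Poisson rate per Mbp,
  with geometric length tails (heavy right tail, as for real STR loci) and
  recorded ground truth (locus, unit, strand, injected mismatches).

Planted tracts are **maximal repeats**: a flanking background base that
would extend the repeat is replaced. Without this, chance one-base
extensions blur the distinction between a word and its shift sequence —
which is precisely the boundary-phase signal the strand-pattern analysis
reads. For the same reason tract *length parity* matters: a tract of
length k in phase 0 contains the word once and its shift zero times, while
long tracts contain both nearly equally. The directional tests therefore
plant short tracts (minimum length k, geometric extension mean 1–2): the
regime where boundary phase dominates. Two strand modes are provided:
`"symmetric"` (fixed unit phase, each tract reverse-complemented with
probability 1/2) drives word ≈ inverse complement; `"forward"` (forward
strand only, random unit rotation) drives word ≈ shift.

Mismatch injection is i.i.d. per tract position at the configured rate,
with the substituted base drawn from the preference vector π renormalized
against the original base. Note that in symmetric mode the
reverse-complemented half of the tracts realizes π against the
*complementary* repeat base, so the pooled substitution mixture deviates
from π by design; parameter-recovery tests therefore plant forward-only.

What the generator does **not** emulate: replication slippage (tract
length evolution), indels, transposons and other interspersed repeats, CpG
islands or isochore structure, UTRs (CDS equals exons), and overlapping or
nested genes. A green planted-signal test therefore establishes that the
pipeline *recovers what was planted* — enrichment ratios, substitution
rankings, strand patterns — not that real genomes look like the
simulation.

## 7. Numerical choices and degenerate inputs

* Spectra are unnamed numeric vectors indexed by the base-4 encoding
  (A=0, C=1, G=2, T=3, first character most significant), the same order
  `Biostrings::oligonucleotideFrequency` emits; at k = 11 this avoids
  ~300 MB of names per spectrum. Word sets store 0-based indices.
* Zero variance in a spectrum (all frequencies equal) makes r undefined:
  hard error. Empty sequence sets give zero spectra (and then that error).
* Empty word sets contribute exactly 0; the full word space exactly 1.
* Ranks in ratio tables are competition ranks ("1224") over all 4^k
  per-word contributions, computed per genome pair and averaged at the
  reporting layer (pooling across pairs before ranking is a flag).
* Ties in "nearly equal" comparisons resolve toward the more ambiguous
  call (both comparisons passing yields `ambiguous`, never a silent
  preference for one pattern).
* All randomness flows from explicit seeds; a master seed spawns child
  seeds via `sample.int(.Machine$integer.max - 1)`, keeping every derived
  seed a valid 32-bit integer.

## 8. Known limitations

* First-order references only; higher-order or genome-fitted models are
  out of scope, so contributions of words reflecting 3-mer-and-longer
  background structure (e.g. codon bias) exceed the reference even in the
  absence of repeats — which is why coding-region comparisons are read
  against the b = 3 row, not the b ≤ 2 rows.
* The contribution decomposition is covariance-based; it quantifies shares
  of co-variation, not causal word importances, and shares of a
  near-orthogonal pair are numerically volatile.
* Spectrum memory is 4^k doubles; k is capped at 11.
* The GenBank reader is deliberately minimal (LOCUS/FEATURES with
  gene/mRNA/CDS/exon keys, join/complement locations, /gene or /locus_tag
  qualifiers); richer files should go through GFF3.
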