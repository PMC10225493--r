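---
title: "dioscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dioscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dioscan` re-implements, as one tested toolkit, four analyses that recur in
genome studies of dioecious plants: (i) discovery of a sex-determining
region (SDR) from sexed resequencing cohorts via sex-specific k-mers;
(ii) windowed selective-sweep scans contrasting wild and domesticated
panels; (iii) dating of LTR retrotransposon insertions from the divergence
of their two terminal repeats; and (iv) karyotype-evolution analysis from
synteny block tables. Every analysis ships with a generator that simulates
its inputs with known truth, so the full pipelines can be exercised and
falsified at desk scale. This vignette records the models, the parameters
that matter, and the design decisions taken where the methods literature
leaves choices open.

## 1. Sex-specific k-mers and SDR discovery

### Model

In an XY system the Y haplotype carries sequence absent from every female
genome: a hemizygous male-specific region plus Y-diverged alleles inside
the non-recombining SDR. Fixed-length k-mers (default `k = 40`) from such
sequence appear in every male sample and in no female sample. To keep the
catalog tractable the k-mer space is subsampled by a literal prefix
(default `"AG"`, a 1/16 sample); k-mers are *not* canonicalized — the
prefix filter operates on literal strings, and strand symmetry is restored
by scanning each read *and its reverse complement*.

Classification of a k-mer as male-specific (MSK) requires:

* pooled count over **all** samples of both sexes strictly greater than
  `min_total_count` (default 10) — the validity filter against sequencing
  error;
* count zero in every female sample;
* count at least one in every male sample
  (`require_presence_all_focal = TRUE`).

Female-specific k-mers (FSKs) are defined symmetrically, and the label-swap
symmetry is asserted by the test suite. The validity threshold is read as a
pooled total because a per-sex reading would contradict the zero-count
rule: a k-mer with more than ten counts in females cannot simultaneously
have zero female counts.

Reads are labelled by catalog membership: at least `min_read_hits` MSK hits
and zero FSK hits makes a read male-specific (symmetric for FSK); hits from
both catalogs make it ambiguous. Labelled reads are placed on the male
assembly by an aligner-free seed-and-extend rule (unique exact k-mer seed
across both orientations, then at most `max_mismatch = 2` substitutions
over the full read, positional deduplication by (chromosome, start,
strand)). External BAM/SAM alignments can be ingested instead
(`place_reads_external()`, with MAPQ, primary, and duplicate filters) when
a real aligner is preferred.

### SDR calling

Placed male- and female-specific reads are tiled into fixed windows
(default 100 kb, the Manhattan-plot unit; 10-kb and 50-kb grids are
alternative settings of the same `window` parameter). Seed windows must
show male-specific depth above `median + z * MAD` (`z = 4`) of the male
track. Two numerical guards matter on sparse tracks and were fixed at
design time:

* **Support floor.** On a mostly-zero track the median and MAD are both 0,
  so the robust threshold degenerates and any stray read would seed a
  window. Seed windows therefore also need `min_reads` (default 10) raw
  reads. Reads genuinely originating at the SDR boundary bleed at most
  `read_length / window` (0.1% at defaults) of a window's depth into the
  neighbouring window, orders of magnitude below the floor at any usable
  coverage.
* **Female veto.** A window is vetoed only when the female-specific track
  is *both* above its own robust threshold *and* supported by `min_reads`
  raw reads. Without the floor a single stray female-labelled read (e.g.
  an X-allele read accepted by the 2-mismatch placement rule inside the
  diverged SDR) would veto a true SDR window.

Seeds separated by at most `merge_gap = 2` windows merge; regions with
fewer than `min_windows = 2` windows are dropped; ranking is by total
supporting reads.

### What the simulation does and does not emulate

`simulate_xy_genome()` draws i.i.d. bases and plants (a) Y substitutions at
`sdr_divergence` per site inside the SDR and (b) one Y-only insertion of
`msr_length` bases. `simulate_reads()` draws uniform single-end (or
paired) reads at Poisson depth with uniform substitution errors, quality
constant `I` (the pipeline never reads qualities). Real genomes add
repeats (multi-mapping), indel errors, GC-coverage bias, and
recombination-graded SDR boundaries — none are modelled, so a green
end-to-end test establishes correctness of the pipeline's logic at its
stated assumptions, not robustness to repeat-rich genomes; that is what
the external-alignment mode is for. `background_polymorphism` (default 0)
optionally adds X/Y heterozygosity outside the SDR; the default keeps the
identity `X == Y outside SDR` exact, which several invariant tests rely
on.

## 2. Selective-sweep scan

### Statistics

Sites pass the standard panel filters first: biallelic, minor allele
frequency at least 5% over all called alleles, missing fraction strictly
below 0.1. Per 50-kb window (step = window by default; the overlapping
20-kb step of `--window-pi`-style scans is available via `step`):

* **π** — per-site unbiased heterozygosity `2 j (n − j) / (n (n − 1))`
  summed and divided by the *full window length* in bp (invariant sites
  count toward the denominator, the VCFtools `--window-pi` convention).
* **F~ST~** — Weir & Cockerham (1984) variance components a, b, c per
  site, including the observed-heterozygosity terms; the window summary is
  the ratio-of-sums `Σa / Σ(a+b+c)` (`fst_weighted`, the selection
  statistic) with the mean-of-ratios also reported. Negative estimates are
  reported as computed.
* **π ln-ratio** — `ln(π_wild / π_domestic)`; `NA` when either window has
  fewer than `min_sites` sites or the domestic π is 0.
* **Tajima's D** — count-form `θ̂_π`, `θ̂_W = S/a1`, and the standard
  variance constants. With missing data, n is the rounded mean
  called-allele count over the window's segregating sites. At n = 2 the
  variance constants vanish while the numerator is identically zero; D is
  defined as 0 there rather than NaN.

Sweep windows are those at or above the empirical `q = 0.99` quantile of
**both** F~ST~ and π ln-ratio. The quantile uses the nearest-rank-above
method (sorted values, index `ceiling(q n)`), and the comparison is `>=`,
so ties at the threshold are outliers — on a constant track every window
is an outlier, which the tests document as intended tie behaviour.
Adjacent or overlapping outlier windows merge into regions; genes overlap
a region if they share at least 1 bp after converting GFF3 1-based
inclusive coordinates to 0-based half-open. Published per-dataset
thresholds of this kind of scan (e.g. an F~ST~ cutoff near 0.56) are
dataset-derived quantiles, not constants, and are therefore recomputed
from the data every time.

### Simulated panels

`simulate_population_vcf()` draws ancestral frequencies from
`Beta(0.5, 0.5)` (a U-shaped folded spectrum), keeps them for the wild
population, and adds truncated-normal drift (`drift_sd = 0.05`) for the
domesticated population; both frequencies are clipped to
`[1/(2n), 1 − 1/(2n)]` so sites stay polymorphic and the MAF filter keeps
meaning. Sweep windows move each site's domestic frequency to the nearer
of `ε`/`1 − ε` (`ε = 0.01`, near-fixation without monomorphic records)
with probability `s` and thin site density by `f`. The per-window site
density (`sites_per_window = 100`, i.e. 2 SNPs/kb at 50-kb windows — a
typical resequencing-panel density after filtering) is a simulator choice:
the stated world of the recovery tests, fixed once. Linkage is absent
(sites are independent), so the simulation validates the window
statistics and the dual-outlier selection logic, not haplotype-based
confirmation methods.

## 3. LTR insertion dating

The two LTRs of a retrotransposon are identical upon insertion; each then
accumulates substitutions at rate `r` per site per year, so their K2P
divergence K estimates `2 r T` and the insertion age is `T = K / (2 r)`
with `r = 1.8e-8` by default. The aligner is a plain Needleman–Wunsch
(match +1, mismatch −1, gap −2) with deterministic tie-breaking (diagonal,
then up, then left); pre-aligned pairs are accepted verbatim. Columns with
a gap or N in either sequence are excluded pairwise before computing the
transition proportion P and transversion proportion Q — complete-column
deletion, the distance-matrix convention, documented here because tools
differ silently on this point. `K = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`;
arguments of the logarithms at or below zero raise a saturation error
rather than returning a complex or clamped value.

The simulator evolves both copies from a common ancestor under the exact
K80 transition probabilities at `κ = 2` (transition/transversion rate
ratio), making the K2P estimator consistent; the recovery test (200
replicates of 5-kb pairs at 1 Myr) checks mean bias below 5%. Because K2P
corrects multiple hits only up to saturation, recovery is only asserted
for `2rT ≤ 0.3`.

## 4. Karyotype evolution

Homologous synteny blocks (HSBs) against an ancestral karyotype are
consumed as a 5-column table; blocks shorter than `min_block_length`
(default 1.2 Mb, the usual large-scale segment resolution) are dropped.
An evolutionary fusion region (EFR) is the interval between two adjacent
retained blocks on a chromosome, labelled `ancestry-switch` when the
flanking ancestral ids differ; zero-length EFRs (touching blocks) are kept
and flagged. Event counts are parsimony lower bounds:

* fusions = Σ over derived chromosomes of (maximal runs of constant
  ancestral id − 1);
* fissions = Σ over ancestral chromosomes of (distinct derived chromosomes
  carrying its blocks − 1).

Orientation is carried but ignored (inversions are not events in this
model), and translocations are not modelled — hence *lower* bounds, which
matches the "at least N fusions" phrasing customary in karyotype papers.
Chromosome-count arithmetic (ancestral − fusions + fissions = derived)
holds only when no other rearrangement classes intervened; published
counts that violate it implicitly include translocation-type events, which
is exactly why this module reports the reproducible parsimony bound
instead.

`simulate_karyotype()` guarantees the parsimony counts are exact on its
output: all fusions are applied before all fissions, fused junctions
always join blocks of different ancestral ids (automatic, since each
ancestral id exists exactly once before fissions), and fissions split
strictly inside one block, never at a junction. A `junction_gap` of 100 kb
of unassigned sequence is placed at each fusion junction so that
`detect_efrs()` has non-degenerate truth intervals to recover; real EFRs
are of this order of magnitude. With arbitrary (cancelling) event
sequences the parsimony counts are only a lower bound, which a property
test asserts as `counts ≤ applied`.

## 5. Numerical and reproducibility choices

* **Coordinates.** 0-based half-open everywhere internally; BED on output;
  VCF 1-based positions and GFF3 1-based inclusive intervals are converted
  on ingestion.
* **Seeds.** One integer seed per generator call; each generator derives a
  private stream seed from `(seed, stream label)` so adding a generator
  never shifts another's output. Identical seed ⇒ byte-identical output,
  asserted for every generator.
* **Normalization.** Depth tracks report raw counts plus counts-per-million
  placed reads; all thresholds that face users are on the CPM scale except
  the raw-read support floors.
* **Overflow.** K-mer counts are 32-bit; overflow raises an error rather
  than wrapping.
* **Performance.** The k-mer kernels pack k ≤ 64 bases into 128-bit keys
  and count by sort/run-length rather than hashing; the multi-sample path
  keeps keys packed and only decodes the classified MSK/FSK rows into
  strings. Read simulation and labelling are single-pass C++ under R's
  RNG. The end-to-end SDR recovery test (10 seeds at 9 Mb × 6 samples ×
  10×) dominates the suite's runtime; all other tests are seconds.

## 6. Known limitations

* The internal read placer is exact-seed based and intended for
  simulation-scale genomes; repeat-rich real assemblies should use the
  external alignment mode.
* No coalescent machinery, recombination, or linkage in the population
  simulator; no indel or quality-aware error model in the read simulator.
* Tajima's D with heavy, unevenly distributed missingness uses a single
  rounded n per window, a bias the tests do not cover.
* The sweep scan implements the pooled two-population contrast; per-group
  pairwise scans must be run per pair.
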