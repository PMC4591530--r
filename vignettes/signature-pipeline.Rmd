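---
title: "Comparing metagenomes without annotation: the metasig pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metagenomes without annotation: the metasig pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

## The problem

Shotgun metagenomes from environmental time series — here, seawater and
coral (*Madracis decactis*) microbiomes sampled across a turbulence-driven
upwelling episode at an isolated mid-Atlantic archipelago — can be compared
in two complementary ways: through database annotation (taxonomic and
functional profiles) and through *annotation-independent* genomic
signatures computed directly from the reads. metasig implements the second
route end to end, plus the profile summaries and virulence-factor
bookkeeping that sit alongside it, and a fully seeded generator so every
stage is testable with synthetic data.

## Dinucleotide odds ratios and the Karlin distance

For a read library, let $f^*_X$ and $f^*_{XY}$ be the mono- and
dinucleotide frequencies computed over every read together with its
inverted complement (strand symmetrization, on by default; a flag turns it
off for sensitivity analysis). The odds ratio

$$\rho^*_{XY} = \frac{f^*_{XY}}{f^*_X\, f^*_Y}$$

is near 1 for every $XY$ when neighbouring bases are independent, so the
16-vector $\rho^*$ captures neighbour-dependence structure — a genomic
signature that is stable across fragments of a genome and insensitive to
base composition per se. Two libraries $f, g$ are compared by the mean
absolute difference

$$\delta^*(f,g) = \frac{1}{16}\sum_{XY}\left|\rho^*_{XY}(f) - \rho^*_{XY}(g)\right|,$$

reported, as is conventional for these small values, multiplied by 1000.
`classify_delta()` buckets values into high (< 11), intermediate, and low
(> 30) similarity; the boundaries are parameters because different
habitats warrant different cut-offs (a coral-tissue comparison may use 20
as the upper boundary), and we deliberately close the middle interval
(`[t_low, t_high]` is intermediate) since strict inequalities would leave
the boundary values unclassified.

Counting details that matter: k-mers are counted per read (no window ever
spans a read boundary — concatenation would create artifactual junction
words), and windows containing `N` are skipped. All characters outside
`A/C/G/T` are normalized to `N` at ingest, so IUPAC ambiguity codes never
bias a signature.

```{r delta-example}
polyA <- read_set(c(r = "AAAA"), "polyA")
rep3  <- read_set(c(r = "ACGTACGTACGT"), "acgt")
sig <- function(rs) dinuc_signature(count_oligos(rs, 1), count_oligos(rs, 2))
karlin_delta(sig(polyA), sig(rep3))
```

This worked example is fully hand-checkable: the symmetrized poly-A
library has $\rho^*_{AA} = \rho^*_{TT} = 2$ and the (ACGT)-repeat library
$\rho^*_{AC} = \rho^*_{CG} = \rho^*_{GT} = 96/22$, $\rho^*_{TA} = 64/22$,
giving $1000 \cdot 20/16 = 1250$ exactly.

## Tetranucleotide z-scores

The second signature standardizes tetranucleotide counts against the
maximal-order Markov expectation from the library's own tri- and
dinucleotide counts:

$$E(n_1n_2n_3n_4) = \frac{N(n_1n_2n_3)\,N(n_2n_3n_4)}{N(n_2n_3)}, \qquad
Z = \frac{N - E}{\sqrt{V}},$$

with the conditional-variance approximation
$V = E\,[N(n_2n_3)-N(n_1n_2n_3)][N(n_2n_3)-N(n_2n_3n_4)]/N(n_2n_3)^2$.
Degenerate denominators ($V \le 0$, or any required count 0) yield $Z = 0$
by convention, so the 256-vector is finite everywhere. Libraries are
compared by the Pearson correlation of their z-vectors; a zero-variance
vector is flagged and correlates 0 against everything rather than
aborting a whole-matrix run.

Two properties are worth keeping in mind when interpreting these scores.
First, $Z$ measures deviation from the library's *own* Markov fit, so for
sequences that genuinely are order-1 Markov the z-scores are pure sampling
noise centred on zero — replicate libraries correlate strongly only
because they share one realized genome, whose idiosyncratic
tetranucleotide usage is the signal. Second, scaling a library (doubling
every read) scales $Z$ by $\sqrt{2}$ and therefore preserves sign
patterns and correlations.

## Profile clustering and abundance ratios

Taxonomic profiles (taxa-by-sample tables, e.g. order-level exports from
an annotation service) are normalized per sample, compared by the Pearson
correlation distance $d = 1 - r$ between sample columns, and clustered
with the Ward minimum-variance criterion. The default variant applies the
Lance–Williams update to the dissimilarities as supplied — the behaviour
of the historical R `"ward"` method that this style of analysis has
traditionally used — with the squared-update variant (`ward.D2`
equivalent) behind a flag. Clustering uses *all* taxa at the chosen rank;
the top-10 list produced by `top_taxa()` (ties broken lexicographically)
is presentation only. Trees serialize to newick with branch lengths
derived from merge heights, so a two-leaf tree at height $h$ is
`(A:h,B:h);` and cophenetic distances are preserved up to the conventional
factor of two against rooted path lengths.

`group_ratio()` computes the summed-abundance ratio between two disjoint
taxon sets in one sample — the cyanobacteria:proteobacteria (or
cyanobacteria:heterotrophs) index used to track the balance between
autotrophy and heterotrophy across a turbulence gradient (near 1 in calm
oligotrophic conditions, collapsing below 0.05 when heterotrophs bloom
under high turbulence and nutrient load).

## Virulence-factor summaries

Hit tables from a protein similarity search against a virulence-factor
catalogue (standard 12-column tabular format, optional 13th annotation
column) are filtered at `E < 1e-4` (strict inequality), labelled by an
ordered, user-editable pattern table (first match wins), and summarized
per sample: total hits, hits per $10^5$ bp of library, iron-acquisition
hits (with the Haemophilus/Pasteurellales iron subset counted inside
them), and *V. cholerae*-related hits. Percentages follow the published
table conventions — iron and *V. cholerae* as % of total hits,
Haemophilus as % of iron-related hits — rounded half-even to one decimal;
because published tables of this kind contain at least one cell
inconsistent with standard rounding, comparisons against printed values
should use a ±0.1 tolerance. Aggregation sums counts and recomputes
percentages from the sums; the aggregate normalized cell is the column
sum of per-sample normalized values (matching the published convention),
with a bp-weighted alternative emitted alongside when library sizes are
known. The exact keyword set mapping catalogue entries to categories is
not published anywhere we could verify, so the shipped rules are an
explicit, editable default, and category counts on real data are
reproducible only up to that mapping.

## The synthetic-data generator

All generator defaults are fixed once, to emulate the study conditions
the pipeline targets:

* **Genomes** are order-1 Markov chains — sufficient because dinucleotide
  structure, the quantity $\delta$ measures, is exactly what an order-1
  chain controls. The built-in contrast pair
  (`contrasting_genome_models()`) differs only in transition structure
  (same-base persistence 0.55 vs 0.10, both GC-balanced), separating by
  $\delta \approx 900$ at 1 Mbp. Note that two *i.i.d.* models cannot be
  separated by $\delta$ no matter how different their GC content, since
  $\rho^* \approx 1$ for any independent-letter sequence; contrast must
  come from neighbour dependence.
* **Reads** are uniform-start fragments with truncated-normal lengths
  (floor 30 bp), default 361 ± 128 bp — the length profile of the first
  library in the study design we emulate. No sequencing-error model is
  applied: the signatures are composition statistics and there is no
  basis for choosing error parameters.
* **Communities** default to three replicate libraries (one per filter
  membrane in the emulated design) with per-read genome assignment by
  mixing proportion.
* **Abundance tables** are Dirichlet draws around group centroids with a
  concentration parameter (default 100) controlling replicate noise.
* **Hit tables** draw per-category counts from Poisson distributions at
  stated rates per $10^5$ bp and phrase annotations so the default rules
  recover the planted category.

Every generator takes an explicit seed and is byte-reproducible. What
passing tests on these data do *not* show: robustness to sequencing
error, chimeras, uneven strand coverage, or real taxonomic structure —
the generator makes no attempt at those.

## Numerical choices and degenerate inputs

* $\rho^* := 0$ when $f^*_X f^*_Y = 0$ (only reachable on pathological
  toy inputs).
* $Z := 0$ on degenerate denominators, as above.
* Zero-variance profiles abort `pearson_distance()` with the offending
  sample named; zero-variance z-vectors are zeroed with a warning
  instead, because signature matrices are typically computed in bulk.
* Ward ties are resolved by `stats::hclust`; the test oracle breaks ties
  lexicographically, and equivalence is checked on tie-free random
  fixtures.
* The e-value filter is strictly `<`, so a hit at exactly the threshold
  is dropped.
* Manifest vocabulary is closed (habitat ∈ seawater/coral; health ∈
  healthy/bleached/n-a) to catch typos at load time.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments run at deliberately
modest scale, chosen as the smallest sizes at which the compared effects
are comfortably resolved: separation experiments use two communities ×
two replicate libraries of 300 reads (361 ± 128 bp) over 30 kb genomes,
repeated 50 times; clustering recovery uses 12 taxa × 2 groups × 5
samples at concentration 100, repeated 100 times. At these sizes the
within/between orderings are recovered in essentially every replicate;
real libraries (tens of thousands of reads over megabase-scale pangenomes)
carry far more signal per comparison but the same orderings.

## Limitations

* Reproduction of published delta values from deposited read archives
  depends on preprocessing (quality-control settings, strand and
  replicate-weighting conventions) that the original analyses did not
  record; group-averaged deltas can differ at the margins.
* The package consumes annotation-service table exports; it does not
  produce taxonomic assignments itself, nor run similarity searches.
* Statistical testing between sample groups is intentionally excluded:
  the published group comparisons do not state which test produced them,
  so there is nothing principled to reproduce.
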