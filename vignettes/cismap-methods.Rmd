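---
title: "cismap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cismap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismap)
```

## The problem

A transcription factor (TF) that is silenced or over-expressed changes the
expression of hundreds of genes, but expression profiling alone cannot say
which of those genes the TF binds directly. `cismap` implements the
standard computational triage: define a core promoter window for every
gene, locate candidate binding sites in it, and ask whether the regulated
genes carry more sites than the genome at large. A second, matrix-free
route asks which short DNA words are over-represented within individual
promoters, whether that over-representation is evolutionarily conserved,
and whether the genes carrying a word are enriched among the regulated set
— a way to discover co-factor elements (classically, GC-box/SP1-type
motifs next to AP-2 sites) without assuming a matrix for them.

## The matrix route

**Core promoters.** For each gene we take the window from `upstream` nt
before to `downstream` nt after the transcription start site (TSS) of its
longest annotated transcript; defaults are 900 and 100 nt, giving a 1,000
nt window with the TSS at offset 901. Ties in transcript length are broken
by the lexicographically smallest transcript ID (and then by smallest TSS
coordinate) — annotation sources rarely document a tie rule, so we pin a
deterministic one. User-facing positions follow the genomics convention
TSS = +1 with no position 0; upstream positions are negative.

**Scoring.** A count matrix $C_{b,i}$ (base $b$, position $i = 1..L$) is
converted to a position weight matrix of log-likelihood ratios
$$M_{b,i} = \log_2 \frac{(C_{b,i} + \kappa) / (\sum_b C_{b,i} + 4\kappa)}{q_b},$$
with additive pseudocount $\kappa = 1$ per cell and background $q$. A
window $s_1..s_L$ scores $\sum_i M_{s_i, i}$; both strands are scanned and
every window whose score **strictly exceeds** a fraction $\tau = 0.66$ of
the maximum attainable score $S_{\max} = \sum_i \max_b M_{b,i}$ is
reported, overlapping and nested matches included. Windows containing `N`
are skipped.

Numerical choices pinned here because the field's conventions vary and the
reference analyses rarely print them: pseudocount $+1$ per cell (count
matrices routinely contain zeros, and the LLR must stay finite); log base
2; uniform background by default, with `estimate_background()` available
when the user has intergenic sequence (published analyses typically use
intergenic frequencies but do not print them); strict inequality at the
$\tau S_{\max}$ cutoff.

**Percentile thresholds.** The reported sites are pooled genome-wide,
sorted by decreasing score, and the score at rank
$\lceil \rho\, n \rceil$ becomes the cutoff for the "top $\rho$" class
($\rho \in \{0.10, 0.20, 0.30\}$ by default); ties at the cutoff are
included. The percentile is over *sites*, not genes, and the cutoff from
the full pool is then applied to any gene subset.

**Enrichment.** For a minimum site count $k$ and threshold $\rho$, the
gene universe is the set of genes with $\ge k$ sites *at any score*; the
2×2 table crosses regulated/not (regulated genes removed from the
"rest-of-genome" column) with $\ge k$ top-$\rho$ sites/not, tested with a
one-sided Fisher exact test (enrichment direction; two-sided available).
This "any-score universe" construction is deliberate: it is the only
construction under which the published summary counts the acceptance suite
uses as inputs reproduce their printed p-values, and it matches tables
that print the any-score rows without p-values, marking them as the
baseline. One-sided testing is our choice; published work rarely states
sidedness, which is why the acceptance check allows a factor-of-3 band on
p.

## The word route

**GC classes.** Promoters are split at the cohort's median GC content
(computed over non-`N` bases; strictly-above goes to the rich class) and
the two classes are analyzed independently — GC-rich words would otherwise
be "over-represented" in every GC-rich promoter merely through
composition.

**Binomial over-representation.** For each word $w$ of length 5–9, let
$n_g(w)$ be the number of greedy left-to-right non-self-overlapping
occurrences of $w$ in promoter $g$, counted on both strands (the
reverse-strand count equals the forward count of the reverse complement; a
palindromic word is counted once per strand, a documented double count).
The trials denominator is $N_g = 2 (\ell_g - |w| + 1)$ minus `N`-touching
windows, the pooled frequency is $f(w) = N(w) / \sum_g N_g$ with
$N(w) = \sum_g n_g(w)$, and the per-gene significance is the binomial tail
$P_g(w) = P(X \ge n_g(w)),\; X \sim \mathrm{Bin}(N_g, f(w))$. The set
$S(w)$ collects genes with $P_g(w) < 0.01$. The greedy left-to-right
resolution of self-overlaps, the both-strand trials denominator, and the
use of non-overlapping counts in $N(w)$ are package policy: the
prose such methods descend from says self-overlaps are discarded and both
strands counted, but does not fix either detail.

Because $f(w)$ is pooled over the class *including* the tested gene, small
cohorts self-dilute: heavily planting a word in a large fraction of a
small cohort raises $f(w)$ and costs power. The test fixtures are sized
accordingly (about 100+ genes per class); at genome scale the effect is
negligible.

**Conservation.** A word's over-representation is conserved when
$S_{\text{species1}}(w)$ and $S_{\text{species2}}(w)$ share more
one-to-one orthologs than chance: over the universe of ortholog pairs, a
one-sided Fisher test of "species-1 gene in $S_1(w)$" against "its partner
in $S_2(w)$". p-values for all tested words — all lengths, both GC
classes, one family — are adjusted with Benjamini–Yekutieli
($c(m) = \sum_{i\le m} 1/i$; valid under arbitrary dependence, which
overlapping words certainly exhibit), and words with $q < 0.1$ are flagged
conserved. Each species' $S(w)$ is the union over its GC classes before
the overlap is formed: the class split is a background-correction device
within a species, and orthologs frequently fall in different classes in
the two species, so pairing classes across species would destroy signal —
this is the one place where we had to choose a geometry the method prose
leaves open.

**Regulated-set enrichment and annotation.** Per word, a one-sided Fisher
test of $S(w)$ membership against membership in the up- or down-regulated
subset over the all-promoters universe; words with $p < 0.05$ are ranked
and the top 10 reported with their target counts, conservation flags, and
TF annotations. Annotation matches a word against a small editable IUPAC
consensus library: two degenerate letters are compatible when their base
sets intersect, and a word matches a consensus when the shorter string is
fully contained position-compatibly in the longer at some offset, on
either strand of the word — "full overlap", with overhangs rejected, again
a pinned interpretation of an under-specified phrase.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the real analyses
face, at desk scale: per-gene GC drawn from a truncated normal (default
mean 0.5, sd 0.08, truncated to [0.25, 0.75]), bases i.i.d. given GC;
a configurable fraction of genes regulated (default 0.023, matching a
~500-in-21,000 regulated set) with signed fold changes ≥ 1.5 in magnitude;
optional PWM sites planted in regulated genes at a Poisson rate (default
mean 2, the "at least two sites" regime), sampled from the matrix's
smoothed column distributions and **resampled until they clear the
scanner's 66% cutoff** — a generator guarantee (itself under test) that
makes planted truth detectable by construction, not an assumption about
the scanner; optional word plantings (non-overlapping copies) in chosen
target sets; and a second species, generated independently except that a
target's planted content is copied into its ortholog with probability
`conservation_prob` (default 0.8 — real regulatory turnover keeps
human–mouse site conservation well below 1 but high for functional
elements; the acceptance checks use the extreme values 0 and 1, which are
the informative controls). Orthology is the identity pairing with optional
drop/permute fractions for negative controls. Everything is a pure
function of the seed.

What the generator does *not* emulate — and therefore what a green test
does not establish: CpG islands and TATA positioning, dinucleotide
structure, alignable orthologous sequence (conservation here is
presence/absence of planted content, as in alignment-free conserved
over-representation methods), assay noise in the regulated list, and
genome-scale universe sizes. Quantities that depend on a specific
promoterome — absolute site counts, printed score magnitudes, percentile
cutoffs such as "≥ 11.44" — are out of reach by design; the suite instead
pins exhaustive-oracle equivalence, strand symmetry, calibration of the
binomial and FDR machinery, and recovery of planted truth.

## Stand-in matrices

The shipped TFAP2A matrix (`MA0003_TFAP2A_synthetic.pfm`) is **not** the
JASPAR MA0003 matrix: it is built by stacking the 53 published high-score
promoter 9-mers shipped in `tfap2a_reported_sites.tsv` — the standard way
a frequency matrix is built from a site collection — because the original
matrix cannot be fetched in an offline build. Scores from it rank-agree
with the published scores only partially (Spearman ≈ 0.65 on the 32
distinct 9-mers; logged by the acceptance suite): the published scores
come from the real matrix and unprinted intergenic background frequencies,
while the stand-in is estimated from the selected high-scoring tail
itself, which compresses the score range. The SP1-style matrix
(`MA0079_SP1_synthetic.pfm`) is a hand-built GC-box and carries `synthetic`
in its name for the same reason. Users with the genuine matrices should
simply point the readers at them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `upstream` / `downstream` | 900 / 100 nt | core promoter window around the TSS |
| `min_fraction` | 0.66 | fraction of $S_{\max}$ a window must exceed |
| `pseudocount` | 1 | additive smoothing per matrix cell |
| `log_base` | 2 | base of the LLR logarithm |
| `background` | uniform | $q_b$; estimate from intergenic FASTA if available |
| `top_fractions` | 0.30, 0.20, 0.10 | percentile site classes |
| `min_sites` | 1, 2 | minimum qualifying sites per gene |
| `k_range` | 5–9 | word lengths |
| `alpha` (word) | 0.01 | per-gene binomial cutoff defining $S(w)$ |
| `fdr` | 0.1 | Benjamini–Yekutieli cutoff for conservation |
| `alpha` (enrichment) | 0.05 | reporting cutoff for regulated-set word tests |

## Degenerate inputs and tie-breaks

Empty site pools error on percentile computation; an all-equal score pool
qualifies every site at any fraction. A uniform matrix has
$S_{\max} = 0$ and the strict cutoff reports nothing. All-`N` promoters
are excluded from the GC split with a warning; `N`-touching windows are
skipped everywhere and removed from binomial denominators. Orthology pairs
violating one-to-one-ness are dropped in full (both offending pairs). A
fold change of exactly 0 is rejected rather than silently assigned a
direction. Words absent from a class have $f(w) = 0$ and $P_g = 1$ by
convention.

## Known limitations

No higher-order background models or p-value-calibrated matrix thresholds;
no dinucleotide/gapped matrices; no suffix-automaton word counting (plain
hashing is ample at desk scale); conservation is alignment-free only. The
score-calibration diagnostic against published site scores is soft by
construction (see *Stand-in matrices*).
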