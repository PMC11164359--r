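---
title: "Comparative mitogenomics with mitocomp: methods and design decisions"
author: "mitocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and scientific model

`mitocomp` implements the analytical core of a comparative mitochondrial
genomics study of insect (ant-like) mitogenomes: parsing and writing
annotated circular genomes, strand-asymmetry and regional composition,
codon-usage statistics (RSCU, ENC, CBI, positional GC), pairwise
Ka/Ks estimation by Nei--Gojobori pathway counting, control-region
structure detection, K2P + neighbor-joining phylogenetics with bootstrap
supports, and a seeded synthetic-data generator that makes every analysis
testable by parameter recovery.

The modeling assumptions, throughout:

* **Genetic code.** All coding-sequence statistics use the invertebrate
  mitochondrial code (NCBI translation table 5) by default: 62 sense
  codons, stops TAA/TAG, and synonymous-family classes 12 two-fold,
  6 four-fold, 1 six-fold (Leu) and 1 eight-fold (Ser). The table is
  built at load time from `seqinr::translate()`; the degeneracy-class
  derivation is `mitocomp`'s own, so any NCBI code id works
  (`genetic_code("standard")`, `genetic_code(2)`, ...).
* **Coordinates.** Features live on a 0-based half-open interval system
  on the majority (J) strand; minority-strand (N) features are
  reverse-complemented on extraction; features may run past the sequence
  end on circular molecules (`end > length`) and are resolved modularly.
* **Strand conventions.** AT-skew $= (A-T)/(A+T)$ and GC-skew
  $= (G-C)/(G+C)$ are computed on the J strand as deposited. Regional
  class rows (PCGs, tRNAs, rRNAs) concatenate features *as deposited*,
  not re-oriented, so regional counts remain consistent with whole-genome
  strand accounting; individual gene rows are in coding orientation.
* **No alignment inference.** Ka/Ks and tree construction operate on
  user-supplied (or simulator-produced) codon alignments; `mitocomp`
  deliberately contains no aligner.

## Codon-usage statistics

**RSCU** of codon $c$ in a family of size $k$ is $k\,n_c / \sum n$;
values in every observed family sum to $k$ (a tested invariant).

**ENC** generalizes Wright's estimator to code-derived classes. Per amino
acid with $n \ge 2$ codons the homozygosity is
$\hat F = (n\sum_i p_i^2 - 1)/(n-1)$, averaged within each family-size
class, then $\mathrm{ENC} = \sum_k m_k/\bar F_k$, clamped to
$[20, 62]$ for table 5. Empty classes are imputed as uniform ($1/k$) with
a warning rather than failing, because small single-gene tables routinely
miss the six- or eight-fold class. The ENC-plot null curve uses Wright's
standard-code formula $2 + s + 29/(s^2 + (1-s)^2)$ regardless of code, as
is conventional for ENC plots.

**CBI** is $(N_\mathrm{pref} - N_\mathrm{rand})/(N_\mathrm{tot} -
N_\mathrm{rand})$ over amino acids with $\ge 2$ synonyms. The preferred
codon defaults to the *dataset-modal* codon of each family (ties broken
alphabetically); fixed preferred sets from other software can be supplied
via `preferred=` for comparability. This choice is deliberate: modal
preference needs no external convention, but it means CBI is measured
relative to the data's own bias direction.

`codon_usage_stats()` defaults to `mode = "concatenate"` (pool the 13
PCGs, then compute ENC/CBI once). Pooling is the stabler default for
mitogenomes because several PCGs are individually too short for reliable
ENC; `mode = "per_gene_mean"` is available when per-gene dispersion
matters.

```{r}
g <- generate_genome(synthetic_config(seed = 1))
nm <- g$features$name[g$features$kind == "PCG"]
st <- codon_usage_stats(setNames(lapply(nm, extract_gene, genome = g), nm))
st
c(enc_observed = st$enc, enc_null = enc_null_curve(st$s))
```

## Ka/Ks estimation

`kaks_pair()` implements Nei--Gojobori (1986) pathway counting:

* **Sites**: at each codon position the synonymous fraction is the number
  of synonymous single-nucleotide neighbors over the *non-stop* neighbors
  at that position, so $s + n = 3$ for every sense codon.
* **Differences**: all minimal mutational pathways between two codons
  (permutations of the differing positions) are enumerated, pathways
  through stop codons are discarded, and synonymous/nonsynonymous step
  counts are averaged over the surviving pathways, preserving
  $s_d + n_d =$ Hamming distance. If *no* stop-free pathway exists the
  pair is scored all-nonsynonymous (a documented convention; such pairs
  are vanishingly rare in real alignments).
* **Correction**: `method = "ng86_jc"` applies Jukes--Cantor
  $-\tfrac{3}{4}\log(1 - 4p/3)$ to $p_S$ and $p_N$. `method =
  "kumar_k2p"` is the MEGA-style "modified Nei--Gojobori": transition /
  transversion counts are tracked per site class and the Kimura
  2-parameter correction is applied separately to each class, with
  `kappa`-weighted site counting. The Kumar method is under-documented in
  the literature, so the plain NG86+JC estimator is kept as the
  cross-checkable default and both are reported by the acceptance run.
* **Gaps / stops / ambiguity**: offending codon columns are removed
  pairwise (MEGA's pairwise-deletion convention), not listwise.

Bootstrap standard errors resample *codon columns* with replacement,
preserving codon structure. Implementation note: per-pair per-column
statistics are precomputed once into a matrix `M`, and each replicate is
the matrix product `M %*% W` with `W` the column-multiplicity matrix, so
1,000 replicates over a 13-gene alignment cost seconds, not minutes.

Under simulation the estimator is unbiased in its intended regime
(pairwise divergence $\lesssim 0.1$ substitutions/site): with a 6-taxon
star tree at pairwise divergence 0.05 and $10^4$ codons, $\omega \in
\{0.1, 0.3, 1.0\}$ is recovered within $\pm 10\%$ by `kumar_k2p` matched
to the generating $\kappa$. At higher divergence the JC/K2P corrections
under-correct the (highly saturated, AT-rich) synonymous class and the
ratio biases low --- the classic counting-method limitation, documented
rather than hidden.

## Phylogenetics

`k2p_distance()` uses pairwise deletion and errors (rather than returning
`NA` silently) when the K2P logarithms saturate. `nj_tree()` is an
independent Saitou--Nei implementation with the Studier--Keppler
criterion $Q(i,j) = (r-2)d(i,j) - R_i - R_j$. Two determinism choices:

* ties in $Q$ are broken by the lexicographically smallest pair of
  *representative* leaf labels, so the tree never depends on input order;
* negative branch-length estimates are clamped to zero with the deficit
  moved to the sister branch (messaged), keeping path lengths intact.

NJ is exact on additive matrices; the tests verify exact topology *and*
branch-length recovery on random additive matrices up to 8 taxa, against
a least-squares quartet oracle and an independent UPGMA implementation on
ultrametric input. Only NJ is implemented (the study's ML/BI analyses
need external inference engines and different data scales); bootstrap
supports come from column resampling + re-estimation, mapped onto the
full-data tree with `ape::prop.clades(rooted = FALSE)`. Replicates whose
distances saturate are dropped and counted, not imputed.

## Noncoding / control-region detectors

`find_tandem_repeats()` is a seed-and-extend detector for approximate
tandem arrays: candidate periods are seeded where one period matches the
next at the identity threshold, extended copy-by-copy with a fractional
final copy, scored against the per-column majority consensus, **reduced
to the primitive period** (smallest divisor of the detected period that
still explains the array), and resolved greedily (longer array, then
higher identity, then smaller period). The primitive-period reduction
exists because a perfect $p$-periodic array also matches at $2p, 3p,
\dots$ and the extended $2p$ candidate can otherwise win the overlap
resolution.

`find_hairpins()` flags exact Watson--Crick inverted repeats (no wobble,
no thermodynamics): all maximal stems are enumerated and selected
greedily longest-first without overlap; the tests pin it to an
$O(n^2 \cdot \mathrm{stem})$ exhaustive oracle. `consensus_motif()`
produces minimal IUPAC codes per gap-free column; with the default
`min_freq = 0` every observed base enters the code, which is how
degenerate spacer motifs such as `TAAATTAYA` arise across species.

```{r}
crs <- extract_gene(g, "CR")
find_tandem_repeats(crs)[1:3, ]
consensus_motif(c("TAAATTACA", "TAAATTATA", "TAAATTACA"))$consensus
```

## The synthetic generator

`generate_genome()` emits a fully annotated, biologically structured ant
mitogenome; `evolve_coding()` evolves coding sequences along a tree.
Together they make every statistic testable by parameter recovery.

Key design decisions and default parameters:

* **Targets hit exactly.** Whole-genome composition (A+T `0.835`,
  AT-skew `-0.02`, GC-skew `-0.31`) is steered by sampling, then
  *filling the unconstrained positions (spacers, tRNA/rRNA bodies,
  control-region filler) with the exact residual base multiset*. This
  both hits the target to rounding error and concentrates the surplus
  A+T outside the PCGs, as in real mitogenomes (PCGs ~80% A+T, RNA/CR
  regions ~90%).
* **Codon bias beyond composition.** PCG codons are drawn from
  position-specific base frequencies (third positions A+T-enriched,
  first/second constrained) sharpened *within* each synonymous family by
  the exponent `codon_bias`. The default `1.15` was calibrated once so
  that synthetic PCGs show ENC ≈ 34, AT3 ≈ 92% --- codon bias in excess
  of composition, placing genomes below the ENC null curve as observed
  in real AT-rich mitogenomes. `codon_bias = 1` gives pure compositional
  sampling (used by the neutrality/slope property tests); `0` flattens
  families to uniform.
* **Architecture.** 13 PCGs (ATN starts, TAA stops, no internal stops),
  22 tRNAs, 2 rRNAs, CR; the derived ant gene order (trnM translocated
  before trnI--trnQ) or the ancestral insect order; an engineered 7-nt
  atp8/atp6 overlap (the largest overlap) and a 24-nt trnF--nad5 spacer
  (the largest spacer); a CR carrying a configurable tandem-repeat
  array, poly-A/poly-T runs and TATA motifs.
* **Simulator.** `evolve_coding()` is a codon-level Gillespie
  simulation: relative rate $\kappa$ for transitions, $\times\,\omega$
  for nonsynonymous changes, stop-creating changes forbidden, rates
  normalized once so one branch-length unit equals one expected
  substitution per nucleotide site for the root sequence. No indels, no
  rate heterogeneity --- outputs are gap-free alignments by
  construction.
* **Determinism.** Both entry points seed the RNG internally and restore
  the caller's RNG state; identical configs are byte-identical.

## Pipeline

`run_comparative(run_config(...))` orchestrates every module over a set
of genomes (objects or GenBank paths). Stage failures are isolated and
reported in the manifest instead of aborting the run; single-genome runs
skip the pairwise/phylogenetic stages with a notice. Exported TSVs carry
provenance headers with the seed and a config hash but *no timestamp*,
so re-runs are byte-identical --- the end-to-end determinism property is
asserted in the test suite and the acceptance run.

```{r}
res <- run_comparative(run_config(
  list(g, generate_genome(synthetic_config(seed = 2))),
  bootstrap_reps = 20, seed = 1))
res$status
head(res$kaks[, c("gene", "mean_ka", "mean_ks", "mean_ratio")])
```

## Validation summary

The test suite (unit + property + acceptance) checks, among others:
composition against brute-force counting (1,000 random sequences) with
exact reverse-complement skew negation; ENC limits 20/62 and monotone
bias response; per-family RSCU sums; Ka/Ks pathway counting against an
independent exhaustive-enumeration oracle over all $62^2$ sense-codon
pairs; $\omega$ recovery within $\pm 10\%$; NJ exactness on additive
matrices ($n \le 8$); noncoding detectors against exhaustive scans; and
byte-identical pipeline re-runs. `scripts/acceptance.R --seed <int> --out
<path>` regenerates the whole synthetic study and writes the headline
quantities as JSON.
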