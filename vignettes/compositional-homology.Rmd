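---
title: "Methods: quantifying compositional homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying compositional homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comphom)
```

This vignette documents the statistical model behind each analysis in
`comphom`, the reasoning behind the default parameters, and the known
limitations. It is a methods reference, not a tutorial; see the README
for a worked example.

## 1. The chi-score

Two protein sequences are compared by their amino-acid composition
alone. Their residue counts form a 2 × K contingency table — one row
per sequence, one column for each residue type observed in at least one
of the two sequences (columns with a zero total are dropped, so K ≤ 20).
The chi-square test-of-homogeneity statistic

$$
\chi^2 = \sum_{ij} \frac{(O_{ij} - E_{ij})^2}{E_{ij}},
\qquad E_{ij} = \frac{(\text{row } i\ \text{total})(\text{column } j\ \text{total})}{N}
$$

is normalized to the **chi-score** $\sqrt{\chi^2 / N}$, where $N$ is the
total residue count of the pair. For a two-row table this is exactly
Cramér's V, so the score lives in $[0, 1]$ with sharp endpoints:

* 0 if and only if the two relative compositions are identical
  (e.g. any sequence versus a permutation of itself);
* 1 if and only if the sequences share no residue types.

No p-value is attached: with sequences of hundreds of residues almost
any compositional difference is "significant", and the score is used as
an effect-size distance, not a test. `chi_score(..., equal_weight =
TRUE)` first rescales both sequences to equal totals, removing the
length asymmetry when one sequence is much longer than the other;
the default keeps the raw counts. `score_vs_uniform()` scores a
sequence against a flat 5%-per-residue pseudo-sequence of the same
length, giving a standardized "how biased is this at all" reference,
reported as the `ref_uniform` column of `chi_score_matrix()`.

Sampling noise sets a floor on the score of finite same-composition
sequences: under multinomial sampling $\chi^2$ has mean approximately
K − 1, so two independent L-mers from one composition score around
$\sqrt{(K-1)/2L}$ (≈ 0.1 for L = 400, K = 20). Scores should therefore
be compared against same-length references (scrambles or resampled
families), which the synthetic generators provide.

## 2. Module segmentation

A single sequence is segmented into compositionally distinct modules in
four stages.

1. **Boundary profile** (`boundary_profile`): at every position $p$
   with at least `window` residues on each side, score the chi-score
   between the `window`-wide left and right flanks. The default
   `window = 30` is the smallest flank for which the 20-column
   contingency table is meaningfully populated; smaller windows make
   the profile noise-dominated.
2. **Candidate detection** (`detect_candidates`): local maxima of the
   profile are accepted greedily in decreasing score order, subject to
   a minimum spacing of `min_module` (default 30) residues; ties break
   toward the smaller position so results are deterministic.
3. **Boundary optimization** (`optimize_boundaries`): each candidate is
   refined within ± `window`/2 by re-scoring with *full* flanking
   segments (from the previous boundary to the next), for at most 10
   sweeps or until no boundary moves. Full segments are more powerful
   than fixed windows once approximate cut points are known.
4. **Validation** (`validate_boundaries`): each boundary must beat a
   permutation null. The two adjacent segments are pooled and
   `n_perm` (default 1000) random permutations are drawn.

The null needs care, and the default is deliberately stricter than the
obvious choice:

* The naive null re-splits each permutation at the *same* cut and asks
  for z ≥ `z_threshold`. This ignores that the observed cut was
  *selected* as the best of ~L positions, and in our calibration runs
  it retained spurious boundaries in the large majority of
  structureless sequences.
* The default **scan-aware null** (`null = "scan"`) therefore scores
  each permutation by its *maximum* flank chi-score over all admissible
  cuts of the shuffled span, so the observed selected maximum is
  compared against selected maxima. Because the null-maximum
  distribution is right-skewed, retention uses its empirical
  percentile, not a moment z-score.
* With $B_0$ initial candidates tested on one sequence, requiring each
  percentile to exceed `conf` would still inflate the family-wise
  error. Retention therefore requires percentile ≥
  $\text{conf}^{1/B_0}$ (a Šidák correction), with
  `conf = pnorm(z_threshold)`; the default `z_threshold = 1.645`
  corresponds to one-sided 95% confidence for a single pre-specified
  boundary. Failing boundaries are pruned one at a time (worst
  percentile first), re-optimizing the survivors after each removal.

The per-boundary z-score against the null moments is still reported for
interpretability. The legacy fixed-cut rule is available as
`modularity_params(null = "fixed-cut")` for comparison.

The acceptance suite quantifies this design at a fixed problem size: on
50 seeded i.i.d. 400-mers and 50 seeded two-module 200+200 sequences
with strong (80%) single-residue bias, the suite requires ≥ 90% of the
former to yield zero boundaries and ≥ 90% of the latter to yield
exactly one boundary within ±10 of the true junction.

## 3. Alignment similarity and the scrambled-self baseline

Linear conservation is measured by global Needleman–Wunsch alignment
(via `Biostrings::pairwiseAlignment`) with BLOSUM62 and affine gap
penalties of 10 (open) and 0.5 (extend) — conventional
EMBOSS-needle-style settings. Percent identity is the fraction of
alignment columns with identical residues; percent similarity counts
columns whose residue pair has a *positive* substitution score
(identities included). By default both are computed over all alignment
columns, gap columns counting in the denominator and scoring zero; a
`denominator = "shorter"` option reproduces the convention that a
perfect substring match scores 100%. Because co-optimal alignments are
common, the implementation canonicalizes the argument order before
aligning so that the reported percentages are exactly symmetric.

Global alignment always produces *some* alignment, so raw percentages
are uninterpretable without a null. `scrambled_baseline()` aligns a
sequence against seeded random permutations of itself: same length,
same composition, no conserved order. A pair is "linearly unalignable"
when its similarity is statistically indistinguishable from this
baseline — which is exactly the situation where a small chi-score
carries independent information. The decoupling is demonstrated
quantitatively in the acceptance suite on five same-composition
6000-mers: mean off-diagonal chi-score below 0.05 with pairwise
similarities indistinguishable (Welch test) from the scrambled
baseline.

## 4. Sequence features

* **NCPR**: mean signed charge (K, R = +1; D, E = −1; H = 0) in a
  centered window (default 25, odd required), truncated at the ends.
* **FCR**: fraction of K/R/D/E residues.
* **Isoelectric point**: bisection root of the Henderson–Hasselbalch
  net-charge curve on pH ∈ [0, 14] to 10⁻³, using the
  Bjellqvist-style pKa table by default (an EMBOSS-style table is
  provided as an alternative; the two typically differ by ~0.1–0.3 pH
  units, which is why downstream comparisons should fix the table).
  Only side chains of C, D, E, H, K, R, Y and the termini titrate.
* **CDK consensus**: minimal sites are `[ST]P`; optimal sites are
  `[ST]PX[KR]`. `phospho_dead()` rewrites every minimal-site S/T to A,
  preserving length and changing composition only at matched positions.
* **AT-hooks**: a G-R-P core (configurable pattern) requiring at least
  two additional K/R residues within the ±3-residue flanks, matching
  the canonical basic-context definition. Motif definitions in the
  literature vary; counts are definition-dependent and should be read
  as such.
* **Site windows**: `site_window_matrix()` builds a 20 × (2·flank + 1)
  position frequency matrix over aligned site-centered windows,
  normalizing each observed column to 1 and leaving out-of-range
  columns empty — suitable input for a sequence logo.
* `sites_vs_length_fit()` regresses site counts on segment length
  (ordinary least squares) to test whether site density, rather than
  placement, is the conserved quantity.

## 5. Partition quantitation

From per-ROI intensity/area measurements (columns `cell_id`,
`timepoint`, `stage`, `i_chr`, `a_chr`, `i_cyt`, `a_cyt`), the
partition coefficient is

$$
P = \frac{I_{chr} A_{chr}}{I_{chr} A_{chr} + I_{cyt} A_{cyt}} \in [0, 1].
$$

`fold_change_series()` normalizes each cell to its own reference-stage
(default metaphase) mean, so cells with different expression levels are
comparable; `summarize_by_stage()` averages within cell before
comparing across cells (cells, not ROIs, are the independent units) and
applies a two-tailed Welch t-test between two stages. Negative
intensities are clamped to zero with a warning rather than silently
propagated.

## 6. Synthetic generators and their limits

All generators are seeded and reproduce byte-identical output for
identical arguments, without disturbing the caller's RNG state.

* `idr_composition()` is a disorder-like composition — rich in S, T, P,
  K, R; poor in W, C, F — representative of basic, phospho-regulated
  IDRs. It is a single point in composition space, not a model of
  disorder generally.
* `make_family()` samples i.i.d. members of one composition: the
  sharpest possible test bed for "composition conserved, order not",
  but with no evolutionary correlation structure whatsoever.
* `make_modular()` concatenates i.i.d. segments and reports the true
  junctions; real composition switches are gradual, so recovery rates
  on these sharp junctions are an upper bound.
* `make_roi_series()` programs stage-mean partitions (defaults 0.24 /
  0.40 / 0.56 for metaphase / anaphase / telophase) and multiplies
  intensities by lognormal noise with `meanlog = -sdlog^2/2` so the
  noise is mean-one and the noise-free case is exact.

## 7. Numerical choices

* All scores are plain double arithmetic; the chi-score is clamped to
  [0, 1] to absorb last-bit rounding.
* The scan null is vectorized: permuted compositions are scored at all
  cuts via cumulative counts, using the closed form
  $\chi^2(\text{cut}) = \frac{N^2}{n_1 n_2} \sum_a \frac{(O_{1a} - n_1 K_a/N)^2}{K_a}$
  for the two-row table, which avoids rebuilding contingency tables.
  Null distributions are cached per (previous, position, next) triple
  during pruning.
* Typical problem sizes: chi-score matrices over tens of sequences are
  instantaneous; segmentation of a 400-mer at `n_perm = 1000` takes
  seconds; the heaviest routine is all-vs-all alignment of long
  (> 5000 residue) sequences.

## 8. Limitations

* The chi-score treats composition as a bag of residues; two sequences
  with identical composition but opposite charge *patterning* score 0.
  Use `ncpr_track()` alongside it.
* Segmentation power depends on module length and bias strength; weak
  or short modules will be (correctly) left unvalidated at the default
  confidence.
* The pI model ignores structural context and modified residues, and
  the pKa table choice shifts absolute values; comparisons are reliable
  only within one table.
* The Welch test in `summarize_by_stage()` assumes per-cell means are
  approximately normal across cells; with very few cells the p-value is
  indicative only.
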