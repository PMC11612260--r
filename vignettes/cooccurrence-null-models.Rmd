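---
title: "Co-occurrence null models and mechanism inference with coocnull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence null models and mechanism inference with coocnull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnull)
```

## The model

A community matrix records, for one stratum of a survey (a sampling year, an
ecoregion, a vegetation zone, and a biological unit — a functional feeding
group or a taxonomic family), which taxa (rows) were present at which sites
(columns). `coocnull` asks whether the pattern of presences departs from
what fixed sampling intensities alone would produce, and, if so, why.

The co-occurrence index is the Stone–Roberts **C-score**. For taxa $i$ and
$j$ with site counts $r_i$, $r_j$ and $S_{ij}$ shared sites, the pair forms

$$CU_{ij} = (r_i - S_{ij})\,(r_j - S_{ij})$$

checkerboard units — exactly the number of ordered site pairs at which the
two taxa are mutually exclusive (equivalently, of $2 \times 2$ submatrices
of the form 10/01). The C-score is the mean of $CU_{ij}$ over all
$M(M-1)/2$ taxon pairs. It is zero when every pair co-occurs wherever both
ranges overlap completely and grows as pairs segregate.

The null hypothesis is the **fixed–fixed** ensemble: binary matrices with
exactly the observed row totals (each taxon occurs as often as observed)
and column totals (each site holds as many taxa as observed). This is the
conservative choice: any structure explainable by differences in taxon
prevalence or site richness is absorbed into the null. Null matrices are
generated by the **sequential swap** Markov chain, which repeatedly draws
two rows and two columns at random and, when the induced $2 \times 2$
submatrix is a checkerboard, flips it to the other checkerboard — an
operation that conserves all margins. The chain runs from the observed
matrix; a cold start from a random member of the marginal class is
available through `random_fixed_marginal_matrix()`.

Each fitted test (`cscore_test()`) reports:

* the **standardized effect size** $SES = (C_\mathrm{obs} - \bar C_\mathrm{sim}) / \mathrm{sd}(C_\mathrm{sim})$
  (sample standard deviation). Under the null, SES is approximately
  zero-mean with about 95% of values in $(-2, 2)$.
* two tail probabilities, $p(\mathrm{obs} \le \mathrm{exp})$ and
  $p(\mathrm{obs} \ge \mathrm{exp})$, as counts over the simulated values
  divided by the number of iterations, with ties counted in both tails (so
  the two never sum below 1). A conservative $(\mathrm{count}+1)/(n+1)$
  variant is selectable.
* a classification at level $\alpha$ (default 0.05): **negative**
  (segregated) when $p(\mathrm{obs} \ge \mathrm{exp}) \le \alpha/2$,
  **positive** (aggregated) when $p(\mathrm{obs} \le \mathrm{exp}) \le \alpha/2$,
  otherwise **random**.

**Direction convention, stated once and prominently:** a *high* C-score —
the *upper* tail of the null distribution — means *segregation*, i.e.
**negative** co-occurrence; the lower tail means aggregation, i.e.
positive co-occurrence. The tail that is "positive" in the distributional
sense corresponds to negative association between taxa.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `n_iter` | 5000 | null samples | standard resolution for randomization p-values at $\alpha/2 = 0.025$ |
| `burn_in` | `max(1000, 10·R·C)` | successful swaps | scales the decorrelation effort with matrix size; floor guards tiny matrices |
| `thin` | `R·C` | attempted swaps between samples | one sweep-equivalent between retained samples |
| `alpha` | 0.05 | two-tailed | the 2.5% tail rule |
| `min_taxa`, `min_sites` | 5, 4 | rows, columns | smaller matrices are degeneracy-prone and weak |
| `z_threshold` | 2 | z-scores of per-taxon CU sums | "considerably more checkerboards" operationalized as a 2-sigma outlier |
| `gap_threshold` | 3 | 0–10 tolerance scale | roughly the spacing between tolerance classes on the Hilsenhoff scale |
| `n_permutations` | 999 | PERMANOVA relabelings | standard; exact enumeration replaces it automatically when the group-assignment count is no larger |

Burn-in and thinning have no canonical values in the literature; the
defaults above were chosen once, as a policy linear in matrix size, and
are configurable everywhere. `n_iter` as low as 1000 is used for the
large calibration batteries below; single-matrix analyses should keep
5000.

Two p-value conventions coexist deliberately: the null-model tails use raw
count/n (matching the resolution at which such tests are usually
reported, e.g. 0.0004 at 5000 iterations, and exact 1.0 for saturated
tails), while the PERMANOVA uses the $(\#\{F^* \ge F\}+1)/(B+1)$ form
standard for that test. Both are documented on their functions.

## The mechanism decision tree

A non-random matrix enters `mechanism_test()`:

1. **Driver taxa.** Per-taxon CU sums typically expose one or few taxa
   carrying the segregation (often a taxon present only where most others
   are absent). Taxa whose CU sum is a $>2\sigma$ outlier are flagged;
   when none is, the single maximum contributor is used (flagged
   below-threshold); when all taxa contribute equally no driver exists
   and the table is returned empty.
2. **Pollution tolerance.** For each driver and the partners it forms
   checkerboards with ($CU > 0$), the absolute tolerance gap on the 0–10
   scale is computed. The call is *differential* when the majority of
   scored pairs have a gap of at least `gap_threshold`, *similar*
   otherwise, *unknown* when more than half of the involved taxa lack
   scores. Raw gaps are always attached for re-judgment.
3. **Microhabitat.** Site environmental variables (complete-case by
   variable, so the variable set is data-driven per matrix; constant
   variables dropped) are standardized and reduced to three principal
   components via `prcomp`; sites are grouped by the driver's
   presence/absence, and a one-way Euclidean PERMANOVA on the component
   scores tests the grouping. $p \le \alpha$ gives *different*, otherwise
   *homogeneous*; missing data give *unknown*. Singleton groups are
   allowed (the pseudo-F remains defined) but flagged low-power.
4. **Verdict** (`decide_mechanism()`, a pure function, exhaustively
   unit-tested over its $3 \times 3 \times 3$ input space):
   * random → *neutral*;
   * negative → *differential_tolerance* if tolerances separate, else
     *differential_habitat* if microhabitats differ, else
     *competitive_exclusion* when both calls are resolved and show
     neither — competition is a conclusion by elimination — else
     *indeterminate*;
   * positive → *shared_habitat* if microhabitats are homogeneous, else
     *shared_tolerance* if tolerances are similar, else
     *biological_homogenization* when the habitat difference is
     positively established, else *indeterminate*.

The last rule is a design decision worth spelling out: homogenization is
itself an elimination verdict ("aggregated, yet not by shared habitat"),
and an elimination requires the habitat call to be resolved. An unknown
habitat call under a positive classification therefore yields
*indeterminate* rather than homogenization by default.

PCA sign convention: each component is oriented so its largest-magnitude
loading is positive, making loadings reproducible across platforms.

## The synthetic-data generator

`generate_study()` fabricates the full input suite — long-format
occurrences, a taxon-attribute table, a site environmental table — for a
plan of strata, with the planted ground truth written alongside. Matrix
sizes default to 12 taxa × 10 sites, inside the 5–66 × 4–24 envelope the
analysis is designed for.

* **Planted segregation** (`plant_segregation()`): one random bipartition
  of the sites is drawn per matrix and every planted pair straddles it
  (first member on one side, second on the other; shared-site count
  exactly 0). A *common* bipartition is used deliberately: it models a
  two-assemblage checkerboard and is the strongest planted signal.
  Independent per-pair splits were tried and rejected during development
  because the random cross-pair structure they create largely cancels
  under the fixed–fixed null — the "planted" pattern then no longer
  dominates the matrix, which defeats the purpose of a ground truth. An
  optional `leakage` probability softens the exclusion. Unplanted filler
  taxa are filled i.i.d. at probability `fill`; they matter, because a
  matrix whose taxa all contribute equal CU sums has no identifiable
  driver, so default plans keep fillers (12 taxa, 4 pairs).
* **Environment** (`generate_env()`): independent standard normals per
  site and variable, with a mean shift of `env_shift` standardized units
  at focal sites. In planted-mechanism strata the focal sites are the
  presence sites of the top-CU taxon, computed at generation time and
  recorded in the truth sidecar.
* **Tolerances** (`generate_tolerances()`): `"similar"` draws all scores
  in 4–6 (no pair separated at the default threshold); `"separated"`
  puts focal taxa at 0–1 and the rest at 8–10.

What the generator does **not** emulate: realistic occupancy and richness
heterogeneity (real margins are far more skewed), shared sites across
strata, spatial or temporal autocorrelation, abundance structure beyond
presence, or correlated environmental variables. Passing the planted-
recovery tests therefore demonstrates that the machinery detects and
attributes the structure it is pointed at under known conditions — not
that any particular real survey will show such structure, nor that the
power observed here transfers to matrices with very uneven margins.

## Numerical choices and degenerate inputs

* Tie detection in tail probabilities uses a relative tolerance of
  $10^{-9}$ — C-scores are ratios of integers, so true ties are exact and
  anything closer than this is a tie.
* All-zero rows/columns are removed before the size filter (`"repair"`,
  the default and the conservative reading of how degenerate matrices
  should be salvaged); `"discard"` drops the whole matrix instead. Repair
  is idempotent and logged.
* A matrix with no checkerboard submatrix anywhere is alone in its
  marginal class: the chain is frozen and the result is flagged
  *unusable* rather than given $p = 1$.
* Zero null variance makes SES undefined (flagged, excluded from SES
  distribution analyses and counted in the log), not a number.
* PERMANOVA with all points identical is *indeterminate*; perfect
  separation gives an infinite pseudo-F whose p lands at the enumeration
  minimum naturally.
* Per-matrix seeds derive from the master seed plus a 31-bit polynomial
  hash of the stratum key, so adding strata to a batch never changes
  existing results; every seed is recorded in the fit and the manifest.
* The sequential swap is known to sample the fixed-marginal class with a
  small bias (it does not correct for the number of neighbors of each
  state). The calibration battery below shows the realized type-I rate at
  $\alpha = 0.05$ stays near nominal at the sizes analyzed here; the bias
  is accepted rather than corrected (no degree-weighted or trial-swap
  variant is implemented).

## SES distribution analysis

Across a batch, `run_group_effects()` summarizes SES against the null
band (mean zero, 95% within ±2), tests for differences across biological
units with a Kruskal–Wallis test (midranks, tie correction, chi-square
approximation), and reports pairwise two-sided Wilcoxon rank-sum
p-values — exact enumeration when both groups have at most 8 values
without ties, the tie-corrected normal approximation otherwise.
Unadjusted p-values are the default (a Holm option exists), matching the
common practice of reporting raw pairwise values; the zero-mean band
check and the group-difference tests are deliberately kept separate, as
they answer different questions.

## Problem sizes used in the checks

The package's own acceptance battery (also re-run by
`scripts/acceptance.R`) uses: 200 matrices ≤ 8×8 for exact oracle
equivalence of the C-score; 10,000 attempted swaps for marginal
conservation; 200 null 10×10 matrices × 1000 iterations for calibration
(realized non-random rate expected in 0.03–0.07); 50 seeds × 10×10 with
5 planted pairs for power (negative with SES > 2 in ≥ 90%); exhaustive
enumeration on 2 × 3 points plus 500 null replicates for PERMANOVA size;
and 50 seeds × 12 taxa × 10 sites × 3 pairs for end-to-end mechanism
recovery. These sizes were chosen as the smallest at which the binomial
noise of the checks is acceptably below the tolerances being asserted.

## Known limitations

* Only the C-score and the fixed–fixed null are implemented; other
  indices (CHECKER, V-ratio, COMBO) and null families
  (fixed-equiprobable, etc.) are out of scope, though the chain/statistic
  separation leaves the extension point.
* No exact enumeration of p-values for large matrices; everything is
  Monte Carlo.
* PERMANOVA is one-way, two-group, Euclidean on the retained components
  (an option to run on standardized raw variables exists via
  `permanova()` directly); no nesting, no other distances, no imputation.
* Published analyses run with other software's swap schedules will differ
  in the third decimal of p-values; with 5000 iterations that is expected
  Monte-Carlo scatter, not a discrepancy in the statistic.
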