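---
title: "Reconstructing clonal hierarchies from bulk variant allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal hierarchies from bulk variant allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehier)
```

## The problem

Acute myeloid leukemia is clonally heterogeneous: the malignant cell
population is a mixture of clones related by descent, each clone defined by
one additional somatic mutation on top of its parent's genotype. Single-cell
sequencing reads this structure off directly, but routine diagnostics
produce only **bulk** variant allele frequencies (VAFs): for each mutation,
the fraction of sequenced allele copies carrying the variant, with no
information about which mutations co-occur in the same cell.

`clonehier` answers the question: *which rooted mutation trees (clonal
hierarchies) could have produced a given set of bulk VAFs?* Rather than
returning one best tree, it enumerates the complete tree space, classifies
each tree as compatible or not, and ranks all trees by how well they fit —
making the *ambiguity* of the reconstruction explicit.

## Model and assumptions

The method rests on four assumptions:

1. each mutation is acquired exactly once and never reverts
   (infinite-sites / irreversibility), so clonal pedigrees are rooted
   labeled trees;
2. all mutations are heterozygous and copy-number neutral, so a clone
   contributes its frequency once to each variant allele it carries;
3. the sample is purely leukemic (or has known purity), so clone
   frequencies live on a simplex;
4. measurements are rescaled so the most abundant variant allele sits at
   100% — for a single founding mutation present in every malignant cell
   this pins the founder allele to 100.

With clones numbered root-first by nondecreasing depth (clone 1 = root,
mutation *j* = the mutation distinguishing clone *j* from its parent), the
clone-membership matrix *A* with *a~ij~* = 1 iff clone *j* carries
mutation *i* is **unit upper triangular**: every clone carries its own
defining mutation (diagonal) and exactly the mutations of its ancestors
(strictly-upper entries). Hence det *A* = 1, and the linear system

> *A x* = *b*,  *b* = measured VAFs, *x* = unknown clone frequencies,

always has a unique solution obtained by back-substitution:
*x~n~* = *b~n~*, *x~j~* = *b~j~* − Σ~k>j~ *a~jk~ x~k~*. The data are
**compatible** with a tree precisely when this solution is componentwise
non-negative. Because the founder row of *A* is all ones and *b₁* = 100,
compatible founder-mode solutions automatically satisfy Σ *x~i~* = 100.

The tree space is enumerated exhaustively through the Prüfer bijection:
sequences of length *n*−2 over {1..*n*} ↔ unrooted labeled trees, giving
*n*^(*n*−2) trees for a fixed root and *n*^(*n*−1) rooted trees overall.
Enumeration is deliberately exhaustive — no search heuristics — which caps
practical clone numbers; the package refuses more than 8 clones unless the
limit is raised explicitly.

```{r}
s <- vaf_sample(c("m1", "m2", "m3"), c(100, 60, 30))
rec <- reconstruct(s)
rec
```

Two hierarchies fit these frequencies exactly — the linear chain
m1→m2→m3 with clone frequencies (40, 30, 30) and the branched tree
m1→{m2, m3} with (10, 60, 30) — illustrating that exact bulk data need not
identify the tree uniquely.

## Measurement error and ranking

Real VAFs carry error, so an incompatible tree may still be the true one.
For every tree the package therefore also solves the convex quadratic
program

> minimise ‖*W*(*A x* − *b*)‖₂ subject to *x~i~* ≥ 0, Σ *x~i~* = 100,

where *W* is a diagonal weight matrix (1 / CI half-width when confidence
intervals are supplied, identity otherwise). Trees are ranked by the
residual, combined across timepoints as the root of the summed squared
per-timepoint residuals (timepoints are fitted independently — clone
frequencies genuinely differ between diagnosis and relapse — and the
aggregation treats them symmetrically). A tree is *optimal* when no tree
achieves a smaller residual, and *exact* when back-substitution is feasible
at every timepoint.

Numerical choices worth knowing:

* **Exactness** is decided by feasibility of the algebraically exact
  back-substitution solution (min *x~i~* ≥ −`tol`, default 1e−9), not by a
  residual threshold: a literal ‖*Ax*−*b*‖ < 1e−15 test is unreachable for
  generic QP output in double precision. The residual threshold is kept as
  the configurable `exactness_threshold` constant.
* Round-off negatives within `tol` are clamped to zero and the vector
  rescaled to preserve its total before reporting.
* Ties in the ranking are broken lexicographically on a canonical
  root-plus-Prüfer encoding of each tree, making orderings bitwise
  reproducible; tied residuals share the better (minimum) rank.
* The QP matrix *AᵀWᵀWA* is positive definite (det *A* = 1, *W* > 0), so
  the dual active-set solver always returns the global optimum.
* Sensitivity diagnostics: by Cramer's rule the deepest clone satisfies
  *x~n~* − *x~n~′* = *b~n~* − *b~n~′* exactly, and the l2 condition number
  of *A* (`condition_number()`) bounds the relative amplification of VAF
  error into clone-frequency error.

## Root modes

**Founder mode** (default) roots every candidate tree at the allele(s) at
the post-normalization maximum; when several alleles tie at 100 each is
tried as root and the enumerations are merged. **Wild-type mode** handles
samples whose VAFs are all clearly below the expected maximum — evidence of
two founding clones or an unsequenced common founder: a reference allele
present in all cells is appended at 100 and all trees are rooted there.

Because errors can push the founder-clone VAF sum above 100 and destroy
feasibility of the true tree, `relaxation_percent = x` multiplies all
mutated VAFs by (100−x)/100, i.e. artificially admits x% healthy cells;
on exact data whose clone frequencies summed to 100 the reconstructed
wild-type clone then takes exactly x%:

```{r}
p <- simulate_patient(4, n_cells = NULL, seed = 7)
rec_wt <- reconstruct(p$bulk_by_timepoint, mode = "wildtype",
                      relaxation_percent = 5)
round(rec_wt$fits[[1]]$x_by_timepoint$diagnosis, 3)
```

Relaxation is refused in founder mode, where the root allele must remain at
100 by construction.

## Robustness experiments

Three experiments quantify how fragile a reconstruction is:

* `multinomial_resample()` — sampling error: clone counts redrawn from
  Multinomial(n_cells, f), bulk VAFs recomputed per replicate.
* `perturb_vafs()` — measurement error: i.i.d. N(0, sd²) noise per allele.
  Draws leaving [0, 100] are excluded and redrawn per allele by default
  (preserving the replicate count; whole-replicate redraw is available via
  `policy`). Perturbed samples are **not** re-normalized: losing the exact
  100% anchor is precisely the failure mode that makes root identification
  unstable when the founding clone is small, and re-normalizing would
  silently erase it.
* `uniqueness_experiment()` — exhaustive: for every fixed-root topology on
  *n* clones, many clone-frequency vectors are drawn uniformly from the
  simplex (flat Dirichlet — the least-informative reading of "random
  frequencies"; other choices would shift the quantitative uniqueness
  fractions), exact bulk VAFs computed, and the number of exactly fitting
  topologies recorded.

`robustness_experiment()` wraps the first two around the full
reconstruction and reports how often the truth stays exact/optimal, whether
the optimum is unique, and the truth's rank distribution. Noise is drawn
independently per timepoint (whether diagnosis and relapse noise should be
coupled is unspecified in the underlying design; independent draws are the
conservative choice). So that the truth remains rankable even when noise
displaces its root allele from the VAF maximum, the truth's root is always
included among the enumerated roots alongside every detected
(tied-)maximal allele; with multiple timepoints, the per-timepoint argmax
alleles are pooled the same way. Ranks are therefore computed over the
union of these fixed-root tree spaces.

```{r}
u <- uniqueness_experiment(4, n_datasets = 2000, timepoints = 2, seed = 42)
u
```

With two timepoints roughly 70% of n = 4 datasets are pinned down to at
most two candidate hierarchies.

## Synthetic patients

`simulate_patient()` generates the full ground-truth chain the analyses
are validated against: a uniformly random fixed-root tree (uniform Prüfer
sequence), per-timepoint clone frequencies from a flat Dirichlet
(optionally bounded below, `min_clone_freq`), a multinomial single-cell
clone table of `n_cells` cells per timepoint (or exact frequencies with
`n_cells = NULL`), bulk VAFs computed from the table as
*b~i~* = Σ~j~ *a~ij~ f~j~* and normalized, and optional Gaussian VAF noise.
Defaults mirror the study conditions the method was characterised under:
diagnosis + relapse timepoints, 2–7 clones, hundreds of sequenced cells,
noise sd in the 0.5–5 percentage-point range. Every generator is a pure
function of its seed; one patient seed fans out to per-component child
seeds through a fixed counter scheme, so adding timepoints or replicates
never shifts earlier draws.

What the generator does **not** emulate: allelic dropout, doublets and
genotyping error in the single-cell table (treated as ground truth),
copy-number changes and homozygous variants, tumor purity below 100%
except through the explicit wild-type/relaxation machinery, and clustering
of raw SNVs into cluster centers (the package starts from VAFs or cluster
centers). Passing tests on synthetic data therefore demonstrates
correctness of the combinatorics, algebra and optimisation — not that real
bulk panels satisfy the biological assumptions.

## Problem sizes used in the test suite

The shipped tests exercise exhaustive enumeration up to n = 6
(1,441 fixed-root matrices), 200-seed self-consistency sweeps, 1,000-fold
resampling/perturbation replicates, and the n = 4 uniqueness experiment at
10,000 datasets per topology with two timepoints — the full scale of the
corresponding characterisation experiments; all run in a few minutes on a
single core thanks to the matrix-valued back-substitution used by
`uniqueness_experiment()`.

## Known limitations

* Exhaustive enumeration scales as n^(n−2); beyond ~8 clones the approach
  is infeasible by design (cluster SNVs into cluster centers first).
* Bulk VAFs from different timepoints must share an allele universe;
  alleles missing at one timepoint are read as frequency 0 there (with a
  warning), which conflates "not measured" with "absent".
* The method cannot distinguish hierarchies whose VAF cones overlap — that
  ambiguity is the object of study, not a defect, and is reported rather
  than hidden.
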