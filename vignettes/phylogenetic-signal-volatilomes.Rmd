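---
title: "Phylogenetic signal in binary volatilome profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal in binary volatilome profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvocphylo)
```

## The problem and the data model

Microbial volatile production is reported species-by-species across
heterogeneous studies with non-standardized detection methods, and the
sampling effort is strongly skewed toward medically and industrially
important taxa. `mvocphylo` therefore works on the coarsest robust summary:
a **binary genus × volatile incidence matrix**. Agglomerating to genus level
and keeping only presence/absence discards quantitative information on
purpose — abundances are not comparable across platforms, and per-species
duplication would mostly reflect study effort. The genus of a record is its
first whitespace-delimited token, because source tables mix binomials,
strain labels, and bare genus names. Volatile-name normalization is limited
to case-folding and whitespace collapse: stereochemistry and chemical
synonymy are *not* resolved (isomer reporting is inconsistent at the source;
a user-supplied synonym map can be passed to `agglomerate_to_genus()` when
the user has curated one).

A trait is **testable** when it is reported in at least two genera and
absent from at least one (`filter_volatiles()`, defaults `min_present = 2`,
`min_absent = 1`): a singleton or constant trait carries no signal that
permutation could detect.

### Printed-percentage conventions

Prevalence percentages are rounded **half away from zero to one decimal**,
and the prevalence cut compares the *rounded* value to the threshold. These
two choices exist solely to reproduce printed prevalence tables faithfully:
a volatile produced by 22 of 221 genera (9.95%) prints as 10.0% and is
retained by a "at least 10%" rule. Base R's banker's rounding would drop it.

## The D statistic

For a binary trait on a rooted, strictly bifurcating tree, every internal
node is estimated as the unweighted mean of its two children (tips carry the
observed state), and the trait is scored by the sum of sister-clade
differences Σd — the sum over edges of the absolute difference between the
nodal values at the edge's ends. Σd is zero only for a constant trait and
grows as presences are scattered across unrelated clades.

The raw score depends on tree size, shape, and prevalence, so it is scaled
between two simulated expectations computed **on the same tree at the same
prevalence k**:

* the **random null**: the observed 0/1 vector permuted uniformly across
  tips (prevalence preserved exactly);
* the **Brownian threshold null**: a Brownian motion is evolved from the
  root (child = parent + Gaussian increment with variance equal to branch
  length) and the k tips with the largest values are set to 1.

`D = (d_obs − mean d_B) / (mean d_R − mean d_B)`, and the reported
`signal` column is exactly `1 − D`. D is approximately 1 for random traits
and 0 for Brownian-threshold traits *by construction*, since the observed
score of a trait drawn from either null has that null's mean as its
expectation; the package's calibration tests verify both means to ±0.1 on a
200-tip tree.

### Nodal estimation ignores branch lengths — deliberately

Only the Brownian simulation consumes branch lengths; the Σd recursion is
purely topological. This mirrors the published construction of the D
statistic for binary traits and keeps the observed score and the permutation
null free of any branch-length assumption. Consequently the choice of
branch lengths only shifts the Brownian reference point. Source trees built
from rRNA guide alignments may arrive without usable lengths; the package
supports both options explicitly via `ensure_branch_lengths()` — `"ones"`
(unit lengths, i.e. a speciational/cladogram clock; the default, which
leaves existing lengths untouched) or `"keep"` (error if any length is
absent) — and the pipeline manifest records
which was used, since neither choice can be asserted as canonical for
previously published tables.

### P-values and tail conventions

Two one-tailed permutation P-values are reported:

* `p_random` = fraction of random-null scores **≤** the observed score:
  small when the trait is more clumped than random;
* `p_brownian` = fraction of Brownian-null scores **≥** the observed score:
  small when the trait is more dispersed than Brownian.

A strongly conserved trait therefore shows `p_random ≈ 0` together with
`p_brownian` near 0.9–1.0. By default these are **raw proportions**, so an
observed score below all permutation scores gives an exact 0 — the value
printed in published signal tables. The conservative (r+1)/(n+1) convention
is available as `p_convention = "add_one"`. Significance filtering
(`classify_conservation()`) uses `p_random < alpha` with a **strict**
inequality, default `alpha = 0.05`; published tables are consistent with the
permutation P-value alone deciding significance, so the Brownian P is not
part of the default rule but can be added (`rule = "both"`).

### Degenerate inputs and ties

* Non-binary trees are refused with a pointer to `resolve_polytomies()`,
  which resolves each multifurcation by uniformly random pairing with
  zero-length inserted branches — zero lengths leave the Brownian
  covariance (and hence the null) unchanged, and the randomization is
  seeded.
* Brownian tip values are continuous, so threshold ties have measure zero;
  a seeded random tie-break (`threshold_to_prevalence()`) guards degenerate
  inputs such as zero-length subtrees.
* If the random and Brownian null means coincide (conceivable only on tiny
  trees), the D denominator is undefined and the function raises a
  numerical-degeneracy error rather than returning a huge ratio.
* All stochastic functions take an explicit integer seed, and batch drivers
  derive per-volatile seeds from the master seed, so whole runs are
  byte-reproducible (`run_pipeline()` asserts this via its manifest).

## Community-level analyses

The multivariate layer uses the standard tools for presence/absence data:

* **Distance**: asymmetric binary (Jaccard) dissimilarity — the standard
  "binary method" for qualitative profiles; joint absences are
  uninformative. All-zero profiles are flagged, and an empty-union pair is
  assigned distance 0 with a warning rather than NaN.
* **Ordination**: metric principal coordinates (classical MDS) via
  eigendecomposition of the double-centered squared-distance matrix.
  "MDS" is ambiguous between metric and non-metric variants; only the
  metric one is implemented, and negative-eigenvalue mass is reported so
  users can judge the embedding quality.
* **PERMANOVA**: one factor at a time (taxonomic rank), via
  `vegan::adonis2`, with p = (1 + #{F_perm ≥ F_obs})/(n_perm + 1). With the
  conventional 999 permutations the smallest attainable p is 0.001. Default
  ranks tested by the pipeline: superkingdom, phylum, family.
* **Diversity**: richness is the genus's volatilome size (row sum),
  frequency the per-volatile producing fraction; the two superkingdoms are
  compared with the Mann-Whitney U test (midranks, tie-corrected normal
  approximation with continuity correction).
* **Set overlap**: `exclusive_intersections()` computes UpSet-style
  exclusive membership patterns; counts always partition the union.

## The synthetic-data generator

The generator exists so that every stage — including end-to-end recovery of
planted signal — can be tested without the original databases, which are
not redistributable in analysis-ready form. It emulates the *statistical*
structure the method assumes, not volatilome chemistry:

* `yule_tree()`: a pure-birth tree (birth rate 1, the time unit) with tips
  `G0001…`; ultrametric, binary, strictly positive branch lengths.
* `clade_conserved_trait()`: the indicator of a focal clade, optionally
  blurred by independent per-tip flips (`flip_noise`, default 0) —
  "production conserved in one lineage, imperfectly reported".
* `brownian_trait()` and `random_trait()`: the two null regimes of the D
  statistic itself.
* `synthetic_volatilome()`: a labelled mixture of conserved and random
  columns with prevalences drawn uniformly from `prevalence_range`
  (default 5–20 tips, echoing the small producing-genus counts typical of
  significant volatiles), plus a fabricated two-superkingdom lineage
  obtained by splitting the tree at the root — mirroring the
  bacteria-versus-fungi top-level contrast — with deeper clades providing
  the lower ranks. Ground truth (regime, focal clade, prevalence, noise)
  travels with every column.

What the generator does **not** emulate: reporting-effort bias correlated
with taxonomy, chemical-class structure among volatiles, correlated
production of biosynthetically related compounds, or non-ultrametric source
trees. Passing recovery tests on synthetic data therefore demonstrates the
statistical machinery, not robustness to those real-data pathologies.

## Problem sizes used by the test and acceptance suites

Calibration runs use a 200-tip Yule tree with 200 traits per regime at 30%
prevalence and 200 permutations per trait; recovery runs plant 30 conserved
among 170 random columns at prevalence 5–20 with no flip noise and test at
α = 0.05, expecting >80% sensitivity and <10% false positives. Analysis
defaults remain 1000 permutations for D and 999 for PERMANOVA; the reduced
per-trait permutation count in the replicated calibration suites trades a
little per-trait P-value resolution for many independent replicates, which
is the right trade-off when the quantity of interest is the *mean* of D
over replicates.

## Known limitations

* Genus extraction by first token will mis-split non-standard labels
  (e.g. "Candidatus X"); such rows should be pre-curated.
* Label matching between matrix and tree is exact (case-folded); no
  taxonomy reconciliation is attempted, and unmatched taxa are dropped with
  a logged list.
* The D statistic is defined for binary traits only; continuous-signal
  statistics (Pagel's λ, Blomberg's K) are out of scope.
* P-values from n permutations are granular at 1/n; reported zeros mean
  "below resolution", not p = 0.
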