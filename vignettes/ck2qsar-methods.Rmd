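---
title: "Methods: 2D QSAR modelling of CK2 inhibitors with ck2qsar"
author: "ck2qsar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D QSAR modelling of CK2 inhibitors with ck2qsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ck2qsar)
```

## The modelling problem

Casein kinase II (CK2) is a constitutively active serine/threonine kinase
whose overexpression is associated with several cancers; most inhibitors
target its ATP pocket and are characterized by an IC50 against the
holoenzyme. `ck2qsar` implements a complete two-dimensional quantitative
structure–activity relationship (QSAR) workflow for such inhibitors: from
a SMILES (or SDF) structure it computes ten 2D descriptors, relates them
to activity on the pIC50 scale
($\mathrm{pIC}_{50} = -\log_{10} \mathrm{IC}_{50}\,[\mathrm{mol/L}]
= 9 - \log_{10} \mathrm{IC}_{50}\,[\mathrm{nM}]$)
by partial least squares (PLS) regression, validates internally
(leave-one-out $q^2$) and externally (held-out test set), and applies a
frozen ten-descriptor linear equation for CK2 pIC50 prediction of new
candidates such as naphtho[2,3-*b*]furan-4,9-dione derivatives.

Everything is 2D: no conformers are generated, no geometry is minimized,
and every quantity derives from the connection table alone.

## The ten descriptors

All surface-area descriptors share one primitive, the per-atom
*approximate accessible van der Waals surface area* (VSA). Atom $i$ is a
sphere of van der Waals radius $R_i$ (Bondi radii, shipped in
`inst/extdata/params/vdw_radii.csv`); each bonded neighbour $j$, placed
at an idealized 2D bond length $d_{ij}$ (element-pair/order table with a
covalent-radius-sum fallback, minus 0.1 Å per bond-order increment),
removes a spherical cap of height

$$h_{ij} = \mathrm{clamp}\!\left(R_i - \frac{d_{ij}^2 + R_i^2 - R_j^2}{2 d_{ij}},\; 0,\; 2R_i\right),
\qquad d_{ij} \in [\,|R_i - R_j|,\; R_i + R_j\,],$$

so that $\mathrm{VSA}_i = \max(0,\; 4\pi R_i^2 - \sum_j 2\pi R_i h_{ij})$.
The analogous volume expression (sphere volumes minus cap volumes) gives
`vdw_vol`. Hydrogens are explicit for all surface and charge work and
contribute their own areas.

The binned descriptors sum $\mathrm{VSA}_i$ over atoms whose property
falls in a fixed bin:

* **PEOE_VSA+0, PEOE_VSA+1** — partial charge $q_i \in [0, 0.05)$ and
  $[0.05, 0.10)$ e. Charges come from the Gasteiger–Marsili partial
  equalization of orbital electronegativities (PEOE): electronegativity
  is the quadratic $\chi_i(q) = a_i + b_i q + c_i q^2$, and at iteration
  $k$ each bond transfers
  $\Delta q = (\chi_{hi} - \chi_{lo})/\chi^{+}_{lo} \cdot f^k$ from the
  less to the more electronegative partner, with damping $f = 0.5$, the
  cation electronegativity $\chi^{+} = a + b + c$ of the donor in the
  denominator (fixed at 20.02 for hydrogen), and six iterations by
  default — the classical convergence horizon. Formal charges seed the
  iteration, so total charge is conserved exactly. Conjugated
  singly-bonded N/O (anilines, phenols, esters, amides) use sp2
  parameters.
* **Q_VSA_HYD, Q_VSA_PNEG** — hydrophobic ($|q_i| \le 0.2$ e) and
  negative-polar ($q_i < -0.2$ e) surface. The 0.2 e polar cutoff is the
  conventional choice and is configurable (`qPolar`).
* **SlogP_VSA7/8/9, SMR_VSA5** — atoms binned by their Wildman–Crippen
  atomic logP contribution ($(0.25,0.30]$, $(0.30,0.40]$, $(0.40,\infty)$)
  or molar-refractivity contribution ($(0.44, 0.485]$). Every atom is
  assigned exactly one published Wildman–Crippen atom type by rule
  matching in the published priority order; unmatched atoms receive the
  per-element wildcard class, never silently dropped.
* **weinerPath** — the Wiener path number, half the sum of the
  topological (shortest-path) distance matrix of the
  hydrogen-suppressed graph.

Bin edges, radii, electronegativity coefficients and contribution values
all live in editable CSV tables under `inst/extdata/params/`, because
vendor implementations of these descriptor families drift in exactly
these constants; fixing and shipping them is what makes the pipeline
reproducible.

## Structure input

The SMILES parser covers the common organic dialect (organic subset plus
bracket atoms, branches, ring closures including `%nn`, explicit bonds,
dot-separated components) and raises typed conditions naming the
offending token position for malformed input. Aromatic systems are
kekulized by a backtracking perfect matching so implicit hydrogen counts
and hybridizations follow standard valence rules; chirality, isotopes
and cis/trans marks are accepted and ignored (everything here is 2D).
Disconnected structures (salts, mixtures) are *rejected* at the distance
matrix, not silently stripped — a silent fragment choice would change
descriptors invisibly. SDF (V2000) input is supported read-only through
ChemmineR; coordinates are ignored.

## The regression model

Descriptors are autoscaled (centred, unit variance) and fitted by NIPALS
PLS1. The latent model is exported as a single linear equation on the
raw descriptor scale — coefficients plus intercept — which predicts
identically to the latent form (asserted to $10^{-8}$ in the tests).
With `ncomp = "auto"` the component count maximizing the leave-one-out
$q^2$ is chosen, ties breaking to the smaller model. $q^2 = 1 -
\mathrm{PRESS}/\mathrm{SS}$ uses full refits (autoscaling redone) in
every fold. Fit quality is reported as the squared Pearson correlation
of observed vs predicted ($r^2$) and RMSE; for a least-squares fit on
training data the squared correlation coincides with explained variance,
which is why the published pair tables support this computation exactly.

Descriptor selection offers two published-workflow stages: a
contingency screen (each descriptor and the response binned into
quantile bins, default $B = 4$; $\chi^2$, Cramér's V, contingency
coefficient and uncertainty coefficient computed, retention by
V ≥ 0.3 or U ≥ 0.2 by default) and a relative-importance filter on the
fitted model, $|b_i|\sigma_i / \max_j |b_j|\sigma_j$, dropping scores
below 0.1. Both thresholds are configurable; the exact statistics and
cutoffs inside the original vendor software are not documented, so the
implementation makes every score visible and tunable instead of
hard-coding a guess.

The frozen CK2 equation is available as `ck2Equation()`:

$$\widehat{\mathrm{pIC}}_{50} = 16.00545 + 0.06444\,\mathrm{PEOE\_VSA{+}1}
- 0.03995\,\mathrm{Q\_VSA\_HYD} - 0.03312\,\mathrm{Q\_VSA\_PNEG}
- 0.06251\,\mathrm{SlogP\_VSA7} - 0.03254\,\mathrm{SlogP\_VSA8}
+ 0.03023\,\mathrm{SlogP\_VSA9} + 0.03672\,\mathrm{SMR\_VSA5}
+ 0.00160\,\mathrm{weinerPath} - 0.01269\,\mathrm{vdw\_vol}
+ 0.01078\,\mathrm{PEOE\_VSA{+}0}.$$

Although the source prints its left-hand side as IC50, the coefficient
magnitudes put the output squarely on the pIC50 scale (predicted values
5–8 paired with nanomolar IC50s), and the package interprets it so.

## Train/test splitting

`splitRangeMatched()` sorts records by pIC50, partitions them into five
contiguous activity strata, and assigns members of each stratum to the
test set at the requested fraction by a seeded draw. Five strata
guarantee that a 30-compound set keeps both extremes in training while
the external set spans the full activity range; an external set below
five compounds is refused, following standard external-validation
guidance.

## Synthetic data: what it emulates and what it does not

`genLinearDataset()` draws independent uniform descriptor columns on
VSA-like scales (per-column scale from 20–200 Å²), with a linear pIC50
signal plus Gaussian noise in pIC50 units, optionally mapped onto the
5.38–7.60 activity span typical of a nanomolar inhibitor series.
`genActivityTable()` draws IC50 log-uniformly in 25–4100 nM.
`genToyGraphs()` builds carbon skeletons (paths, cycles, stars, complete
graphs) whose Wiener numbers have closed forms, capped at carbon
valence.

These generators validate the *statistical machinery* — recovery of
known coefficients, behaviour of $q^2$ under pure noise, selection of
signal over null descriptors — and the graph machinery against exact
combinatorics. They do **not** emulate the correlation structure of real
descriptor blocks (VSA families are strongly collinear on real
molecules), the discreteness of binned descriptors, or assay error
structure; passing tests therefore demonstrate correctness of the
algorithms, not transferability of any particular fitted model to new
chemistry. Collinearity stress can be injected manually by mixing
columns of a generated `X`.

## Numerical choices

* PEOE: 6 damped iterations ($f = 0.5$), early exit below a $10^{-8}$
  transfer; charges agree with an independent cheminformatics toolkit
  within 0.02 e/atom on a 20-molecule panel (frozen reference values
  ship with the package).
* Cap heights and bond lengths are clamped so the sphere-overlap
  geometry is defined for any radius/distance combination; surface
  areas are floored at zero.
* Kekulization failures (odd sp2 count, no alternating pattern) are
  typed valence errors, not warnings.
* NIPALS deflation stops early when a weight or score norm falls below
  $10^{-12}$; constant descriptor columns are carried centred-only with
  zero coefficients.
* `auto` component selection evaluates every candidate count; ties go
  to the smaller model.
* All generators and splits restore the caller's RNG state.

## Problem sizes in the test suite

The suite validates PLS against the normal-equations solution on 50
random problems, the LOO $q^2$ bookkeeping against explicit $n$-refit
loops on 20 problems, coefficient recovery over 50 seeded datasets at
$n = 20$, $p = 10$, noise at 10% of signal spread, and null-calibration
of the contingency statistics over 100 seeds at $n = 200$. These sizes
mirror the scale of the modelled compound series (20 training, 10 test
compounds) while keeping every property check exact or tightly
concentrated.

## Known limitations

* The descriptor constants (bins, radii, polar cutoff) follow the
  documented conventions of the originating descriptor families, but
  vendor implementations differ in undocumented details; absolute
  descriptor values for a given molecule can therefore differ from any
  specific vendor's output even though all conservation laws and
  published definitions hold. The shipped parameter tables make every
  such choice explicit.
* Structures for most compounds of the original CK2 series are not
  deposited; the packaged SMILES for the six publicly named compounds
  are name-derived reconstructions and are used for demonstrations
  only, while the published tested/predicted activity pairs are carried
  as exact numeric fixtures.
* Wildman–Crippen typing implements the published rule set for the
  organic elements; exotic coordination chemistry falls back to the
  wildcard classes with a warning.
* Single-response PLS only; no applicability-domain estimate is
  attached to predictions (an all-zero descriptor vector is flagged as
  extrapolation during screening).

## Session info

```{r}
sessionInfo()
```
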