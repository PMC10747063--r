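---
title: "Compositional quantification of histone PTM peptidoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional quantification of histone PTM peptidoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneptm)
library(dplyr)
```

## The problem

Bottom-up histone proteomics quantifies *peptidoforms*: tryptic peptides of
the H3 and H4 N-terminal tails, each carrying one specific combination of
lysine methylation (me1/me2/me3) and acetylation (ac) marks. After
propionylation and Arg-C-like digestion, four peptide windows cover the
marks of interest:

* `H3K9-R17` (`KSTGGKAPR`, sites K9 and K14),
* `H3K18-R26` (`KQLATKAAR`, sites K18 and K23),
* `H3K27-R40` (`KSAPATGGVKKPHR` for H3.1, `KSAPTTGGVKKPHR` for H3.3;
  sites K27 and K36) — the only window whose sequence differs between the
  canonical H3.1 and the replacement variant H3.3, so it is the only place
  where variant-specific marks and the H3.1:H3.3 ratio itself can be read,
* `H4G4-R17` (`GKGGKGLGKGGAKR`, sites K5, K8, K12, K16).

Spectral quantification software (the upstream step, out of scope here)
exports one integrated peak area per sample × replicate × peptide window ×
modified form. This package implements everything downstream of that table.

## Quantitative objects

**Form compositions.** Within one replicate and peptide window, the relative
abundance of a form is its peak area over the window's total area. Each
composition is closed to 1; forms that were not detected in a replicate are
treated as *not observed* (absent rows), never as zeros — zero handling is
deferred to the statistics layer where it is explicit.

**Variant proportions.** Per replicate, the H3.1 proportion is the total
H3.1 K27–R40 area over the summed totals of both variant windows. The group
value is the *median* across replicates (robust against single noisy runs,
and the convention used for reporting ratios); per-replicate values are kept
for box-plots and tests. The printed form is `a : 1` with one decimal
(`"3:1"`, `"1.3:1"`, `"1.0:1.0"` in the balanced case) and is presentational
only.

**Site marks.** Site-level marks are marginals of the form composition:
the abundance of K27me1 is the summed abundance of all forms assigning me1
to K27. For the variant-resolved window, marks can be reported per variant
or combined across variants while honouring the sample's variant ratio:

$$\text{combined}(m) = p_{\mathrm{H3.1}}\cdot f_{\mathrm{H3.1}}(m) +
(1-p_{\mathrm{H3.1}})\cdot f_{\mathrm{H3.3}}(m).$$

With the seedling values (3:1 ratio, 27% H3.1-K27me1, 13% H3.3-K27me1) this
gives `0.75·27 + 0.25·13 = 23.5` ≈ 23% overall K27me1 — the package's
canonical worked example. The combined value is computed with the
group-median proportion by default (`weights = "group-median"`); per
replicate weighting is available behind a flag, because the alternative is
defensible and the choice matters slightly in unbalanced designs.

**Acetylation degrees.** Each form contributes its abundance to the count
of its acetylated lysines, giving the mono/di/tri/tetra-acetylation
spectrum of a window (hyperacetylation shows up as mass moving to degrees
3–4 on H4G4–R17).

## Statistics on compositions

Relative abundances are compositional: the constant-sum constraint induces
spurious negative correlation, so all inference happens on log-ratio scales.

* **Two-part alr.** Each feature is reduced to the 2-part composition
  (this form vs everything else) and transformed by
  $\mathrm{alr}_2(x) = \log_2\!\frac{x}{1-x}$. Base 2 makes group
  differences readable as fold changes of odds.
* **Tests.** Two-sided Student's pooled-variance t-tests per feature
  (`welch = TRUE` switches to the unequal-variance flavour). Two tiers:
  *significant* at $p < 0.05$, *trend* at $0.05 \le p < 0.1$. The boundary
  $p = 0.05$ is assigned to *trend*; the event has measure zero and the
  assignment is documented rather than consequential. No multiple-testing
  correction is applied to the tiers, but Benjamini–Hochberg q-values are
  printed in a separate column so both views are visible.
* **Zero replacement.** Multiplicative: zeros become $\delta$ and positive
  parts are rescaled by $(1 - z\delta)$, preserving their ratios. The
  default $\delta$ is 0.65 × the smallest positive fraction observed for
  that feature across the dataset — a standard heuristic that keeps
  replaced values below anything actually measured.
* **Pivot coordinates.** For clustering, compositions are mapped to the
  pivot-coordinate ilr basis,
  $z_j = \sqrt{\tfrac{D-j}{D-j+1}}\,\ln\!\frac{x_{(j)}}{\mathrm{gm}(x_{(j+1)},\dots,x_{(D)})}$
  (natural log; the alr above deliberately uses log2, the ilr uses the
  standard natural-log definition). Any ilr basis is an isometry, so
  Euclidean distances between pivot coordinates equal Aitchison distances
  and do not depend on the pivot order; only coordinate values do. The
  default pivot order is the input feature order.
* **Clustering.** Group-mean compositions (mean of observed replicate
  fractions per form, re-closed) are transformed after averaging and
  clustered by Euclidean distance with unweighted average linkage (UPGMA).
  Replicate-level clustering is available behind a flag. Features missing
  from any clustered unit are dropped matrix-wide first and logged — a
  deliberate completeness rule that keeps the geometry honest at the cost
  of discarding sparsely detected forms. The "all peptides" scope
  concatenates the per-window pivot coordinates.

## The synthetic-data generator

Raw study data live in a public proteomics repository and are not required:
the generator emulates the study design so every stage is testable.

For each group × replicate, one log-normal total area per peptide window
(`scale · exp(N(0, σ))`, σ defaults to 0.25); the K27–R40 pool total is
split between the H3.1 and H3.3 peptides exactly by the design's
`variant_p31`, and within each window the total is distributed over forms
by the design profile perturbed by per-form log-normal noise and
renormalised. Placing noise on totals and on the within-window composition
— rather than drawing the two variant totals independently — reflects that
both variant peptides come from the same injection and that the first
analysis step renormalises areas anyway; it also makes the variant-ratio
estimator's accuracy a property of the estimator and dropout rather than of
an arbitrary extra noise knob. Detection dropout then removes the lowest
`dropout_rate` fraction of a replicate's forms per window (bottom-k by
noisy abundance — MS detection loses the faintest species first, not random
ones).

The `paper_like_preset()` encodes nine groups (7-day seedlings, 20-day
root-/shoot-derived calli, NaB- and TSA-treated calli, 1-year calli).
Anchored parameters: the variant proportions converted from the printed
ratios (0.75, 0.565, 0.643, 2/3, 0.50, 0.583, …) and the seedling
variant-specific K27me1 levels (27% / 13%). *Every other profile entry is a
synthetic default*, constructed from independent per-site marginals (form
probability = product of site-marginal probabilities) and chosen to be
directionally consistent with the reported group differences; they are not
measured values. NaB-treated groups reuse the root-calli form profiles and
TSA-treated groups the shoot-calli profiles, encoding the reported
similarity structure, which is why the all-peptides dendrogram of the
20-day groups resolves three clusters: seedlings alone, root calli with
both NaB groups, shoot calli with both TSA groups. Root-derived callus
groups carry `dropout_rate = 0.12` (others 0), mirroring the poorer peptide
recovery from root material; σ = 0.25 keeps recovery non-trivial but
reliable at n = 6. What the generator does **not** emulate: retention-time
or spectral interference structure, correlated noise between co-eluting
forms, batch effects, and replicate-to-replicate biological variance of the
real study (unknown without reprocessing the deposit). Passing tests
therefore demonstrate correctness of the pipeline's arithmetic and its
statistical calibration under a plausible noise model — not agreement with
the deposited raw data.

`simulate_alr_features()` is the feature-level companion used to calibrate
the test layer directly on the alr scale (null: shift 0; large effect:
shift 2.0 at σ = 0.5, n = 6).

## Numerical and design choices

* Modification strings use a compact `site:mark` dialect (`"K27:me1;K36:me2"`,
  `""` = unmodified); parsing is order-insensitive and canonicalization is
  idempotent. Propionyl tokens are sample-prep chemistry and are dropped to
  `unmod` with a notice; a converter from Skyline-style bracketed mass
  shifts is provided (acetyl 42.0106 vs trimethyl 42.0470 require two
  decimals).
* me3 is admitted at K9 and K27; K36me3 parses but is flagged, matching how
  rarely it is reported on this window. H4 lysine methylation is admissible
  in the data model but carries no mass in the preset (the study design
  quantifies H4 acetylation).
* Merging groups (e.g. pooling root and shoot samples of one biological
  replicate into a whole-seedling record) sums areas per replicate index;
  unpaired replicates are retained. Pooling at the area level rather than
  averaging relative abundances is a decision, recorded in the run
  manifest.
* Group medians use `stats::median` (mean of the two central values for
  even n). UPGMA ties are broken by `stats::hclust`'s deterministic
  pair-index rule; tests compare against a brute-force oracle via
  cophenetic matrices, which are tie-break-invariant.
* All randomness flows through a single integer seed; identical seed and
  configuration give byte-identical tables and an identical manifest hash.

Problem sizes used by the test-suite calibrations: 1000 simulated features
for the type-I error check, 500 for power, 200 generator seeds for
ratio-text recovery, 200 random instances for each oracle-equivalence
check — sizes at which the Monte-Carlo error of the checked rates is well
below the asserted bands.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(
  input = "preset", seed = 1, out_dir = "ptm_run",
  comparisons = list(c("7ds", "cR"), c("7ds", "cS"), c("cR", "cS")),
  cluster_groups = c("7ds", "cR", "cS", "NaB-cR", "NaB-cS", "TSA-cR", "TSA-cS")
)
manifest <- run_pipeline(cfg)
```

This writes the canonical record table, compositions, variant proportions
(per replicate and per group with ratio text), site-mark and
acetylation-degree tables, one stats report per comparison, the linkage
table and Newick dendrogram, and a JSON manifest holding versions, seed,
configuration hash, every runtime decision (merge semantics, dropped
features, zero-replacement deltas) and output checksums.

## Limitations

* Site-level marks are only inferable inside the four covered windows;
  whole-histone stoichiometry is out of scope.
* K9–R17 and K18–R26 are sequence-identical between H3.1 and H3.3, so their
  marks are inherently variant-agnostic (`variant_scope = "n/a"`); only
  K27–R40 marks can be variant-resolved or variant-weighted.
* The completeness rule for clustering silently concentrates the analysis
  on consistently detected forms; with heavy dropout the retained feature
  set can be small (it is always logged).
* The pooled t-test assumes approximate normality of alr values within
  groups; with n = 5–6 this is an act of pragmatism shared with common
  practice, and the Welch flag does not rescue non-normality.
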