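---
title: "Screening and annotating BrNC-labeled hydroxyl and amino compounds"
author: "brpairscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and annotating BrNC-labeled hydroxyl and amino compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brpairscan)
```

## The measurement principle

Hydroxyl and amino metabolites ionize poorly (alcohols, phenols) or retain
poorly on reversed-phase columns (amines), which limits their coverage in
untargeted LC-MS. Acylation with 5-bromonicotinoyl chloride (BrNC) fixes
both problems at once — the pyridine nitrogen provides an efficient
protonation site and the aromatic ring adds hydrophobicity — and, because
the tag carries one bromine, it imprints every derivative with a
recognizable isotope signature: natural bromine is an almost equimolar
mixture of ⁷⁹Br and ⁸¹Br, so each derivative appears as a *pair* of MS1
peaks separated by

$$\Delta m/z \;=\; m(^{81}\mathrm{Br}) - m(^{79}\mathrm{Br}) \;=\; 1.998\ \mathrm{Da}$$

with intensity ratio

$$\frac{I(M\!+\!2)}{I(M)} \;=\; \frac{a(^{81}\mathrm{Br})}{a(^{79}\mathrm{Br})}
 \;=\; \frac{0.4931}{0.5069} \;=\; 0.9728 .$$

Mining an aligned feature table for co-eluting doublets with this spacing
and ratio finds the labeled sub-population without any isotope-labeled
reagent. All masses in the package derive from one pinned constants table
(IUPAC 2021 monoisotopic masses, electron mass included in ion m/z), which
is what makes the four-decimal fragment values below bit-stable:

```{r constants}
tc <- tag_constants()
round(c(acylium = tc$frag_acylium_mz, hydroxyl = tc$frag_hydroxyl_mz,
        amino = tc$frag_amino_mz, delta = tc$br_delta, ratio = tc$br_ratio), 4)
```

The three fragments are reagent-derived product ions: the acylium cation
C₆H₃BrNO⁺ appears for every derivative, protonated 5-bromonicotinic acid
([C₆H₄BrNO₂+H]⁺) marks hydroxyl derivatives, and protonated
5-bromonicotinamide ([C₆H₅BrN₂O+H]⁺) marks amino derivatives. The electron
mass matters here: without it the acylium ion computes to 183.9398 rather
than 183.9393.

## Pair screening and its tunable parameters

`find_pairs()` reports every co-eluting feature pair whose mass spacing
and intensity ratio match the bromine signature. The defaults in
`pair_config()` are:

* `tol_ppm = 10` — applied to the **heavy** member's m/z. Ten ppm of the
  1.998 Da spacing itself (≈0.02 mDa) would be far below instrument
  accuracy; mass tolerance is a property of the measured m/z.
* `ratio_low = 0.8`, `ratio_high = 1.2` — the accepted window for
  I(heavy)/I(light); the theoretical 0.9728 sits comfortably inside.
  The window is deliberately biased to single-tag derivatives: a
  two-bromine ion has I(M+2)/I(M) = 2·q/p = 1.9456 and is rejected.
  Multi-tag search (`n_tags_max > 1`) instead looks for the n·1.998
  spacing with a binomial ratio window and is off by default.
* `rt_tol = 0.05` min — aligned tables quantize retention time, so
  "identical retention time" is implemented as a small window.

Intensity is summed over samples unless a reference sample is named.
Deduplication (`dedupe_pairs()`) merges pairs whose light members coincide
within tolerance, transitively, keeping the most intense representative;
`blank_filter()` removes pairs not at least 3-fold above the procedural
blank (a fold of exactly 3 is kept).

## MS2 classification and spectral similarity

`diagnostic_class()` matches the three reagent fragments at a default 20
ppm — wider than the MS1 screen because product-ion calibration is looser.
`similarity()` implements the dominant spectral-similarity convention:
cosine on square-root-weighted intensities with greedy one-to-one peak
matching inside the alignment tolerance, precursor peak excluded (keeping
it would trivially inflate scores between unrelated derivatives sharing a
precursor). The score is symmetric, scale-invariant and bounded in [0, 1];
the 0.5 acceptance threshold used in annotation refers to this score. The
underlying similarity metric behind published scores of this kind is
rarely stated exactly, so a specific literature score (e.g. 0.71 for a
standard match) is not a reproduction target — only the >0.5 decision is.

## QSRR retention prediction

`qsrr()` fits a random-forest model predicting the *derivative* retention
time from descriptors of the *parent* structure — the pairing a standards
panel provides (descriptors of the mono-derivatized structure are
available behind `derivatized = TRUE`). The pipeline is:

1. **Descriptors** (`compute_descriptors()`): ~34 deterministic values per
   molecule — OpenBabel physicochemical properties (logP, MR, TPSA, HBA,
   HBD, MW), formula-derived constitutional terms (atom counts,
   monoisotopic mass, RDBE, H/C, O/C) and SMARTS functional-group and
   topology counts. The engine and its descriptor manifest are stored in
   the fitted model rather than asserting any particular descriptor count;
   engines differ and counts such as "371 descriptors" are
   engine-specific.
2. **Median imputation** of non-finite values (forests need complete
   matrices).
3. **Selection** (`select_features()`): variance filter, then a greedy
   keep-first correlation-redundancy filter (|r| > 0.95 drops the later
   column; near-copies such as multiple size measures would otherwise
   dilute forest importance across a cluster), then recursive elimination
   of the least important 20% by permutation importance down to `k = 11`.
4. **Forest fit** (500 trees) and seeded 5-fold cross-validation;
   `evaluate_qsrr()` reports test R² and the average absolute error (AAE)
   in seconds, retention being held in minutes internally.

Every stochastic step is seeded; train → `save_qsrr()` → `load_qsrr()` →
`predict()` is bit-stable.

## Five-level annotation

`annotate_pair()` matches the **light** (all-⁷⁹Br, monoisotopic) m/z of a
pair against theoretical derivative m/z of database candidates
(protonated adduct by default; positive-mode acquisition), with tag count
limited by the candidate's derivatizable-site count from `count_sites()`
(aliphatic OH on sp³ carbon, phenolic OH, primary and secondary aliphatic
amines; carboxyl OH and amide NH are excluded — they are not acylated
under the mild labeling conditions). Evidence thresholds are MS1 error
< 10 ppm, retention deviation < 0.5 min, MS2 similarity > 0.5, and the
confidence ladder is:

| Level | Evidence |
|-------|----------|
| 1 | retention + MS1 + MS2 confirmed against an authentic standard |
| 2 | retention + MS1 + MS2 matched to a database entry |
| 3 | retention + MS1 |
| 4 | MS1 only |
| 5 | molecular formula only (`generate_formulas()` with the pair's bromine count) |

Retention evidence uses the measured reference retention time when the
database has one and the QSRR prediction otherwise. Level 1 is only
assigned when the record is flagged as an authentic standard — the
package can verify consistency with a standards library, not run
standards itself. Ties among equal levels rank by |ppm|, then retention
deviation, then MS2 score. Adding evidence can never worsen a level;
removing it can never improve one.

The formula fallback enumerates CHNO(S) compositions with exactly the
pair's bromine count inside the mass tolerance, keeping only candidates
with non-negative integral ring-double-bond equivalents under standard
valences, sorted by |ppm|.

## Group comparison

`presence_intersections()` counts per-group presence (default rule: any
replicate above the detection threshold — alignment software typically
back-fills, so a single confident detection is meaningful; a "majority"
rule is available) and the full upset-style intersection table.
`pairwise_diff()` runs Welch t-tests per compound on log2 intensities
(half-minimum pseudo-count), BH correction, and calls significance at
q < 0.05 and |log2FC| ≥ 1 by default — volcano-style thresholds,
configurable. `plsda_vip()` is a NIPALS PLS-DA on autoscaled data with
dummy-coded groups; VIP scores use the standard weighted-loadings formula

$$\mathrm{VIP}_j = \sqrt{\,p \cdot \sum_a \mathrm{SSY}_a w_{aj}^2 \Big/ \sum_a \mathrm{SSY}_a}\,,$$

so the mean of squared VIPs is identically 1 (each weight vector has unit
norm). The implementation agrees with the mixOmics reference to machine
precision in the test suite. Published per-grade compound counts from any
particular study (total identifications, per-grade counts, shared or
differential compound numbers) depend on the authors' raw runs and are
not desk-reproducible; the package validates the *procedures* on
simulated data with known truth instead.

## The synthetic-data generator

`simulate_compounds()` / `simulate_features()` implement the forward
model the screen assumes, with a planted ground-truth registry
(`scorecard()` computes recall/precision against it):

* **Structures** come from a deterministic scaffold × chain-length SMILES
  grammar (alcohols, diols, amines, amino alcohols, alkyl phenols, benzyl
  alcohols, hydroxy acids, phenethylamines, methoxy phenols, amino-acid
  analogues), every product carrying at least one derivatizable site. The
  default regime stays below C9 — the small-metabolite range typical of
  derivatizable compounds — and chain length scales up only when more
  distinct compounds are requested.
* **Intensities** are multiplicative log-normal (σ = 0.2 on the natural
  log scale, i.e. ≈20% CV — consistent with the <20% replicate RSDs that
  validated labeling assays of this kind achieve); heavy = light × 0.9728
  × exp(N(0, σ_ratio)).
* **m/z error** is one shared calibration draw per compound applied to
  both isotopologues plus a five-fold smaller independent centroiding
  residual. Calibration error is common-mode for co-eluting isotopologues
  of one ion, which is why isotope *spacings* are measured far more
  precisely than absolute m/z — fully independent jitter would misstate
  the screen's operating characteristics.
* **Decoys** are singleton features; candidate m/z are rejection-sampled
  so no accidental 1.998 Da doublet can arise within twice the screening
  tolerance, keeping precision ground truth unambiguous.
* **Group effects** multiply the planted compounds' means in alternating
  groups (`n_effect`, `effect_fold`).

With a fixed seed `simulate_dataset()` writes byte-identical files.

What the generator does *not* emulate: chromatographic peak shapes
(aligned tables only), ion suppression, co-eluting isomers, charge states
above 1, and isotopic fine structure beyond the bromine envelope. Passing
tests therefore demonstrate correctness of the screening, annotation and
comparison logic under the stated error model, not robustness to every
artifact of real acquisitions.

### The QSRR recovery simulation

`simulate_qsrr_standards()` mirrors a 62-train / 20-test standards design:
retention is generated as a linear function of three descriptors
(autoscaled, coefficients 3, −2, 2.5 minutes around a 12-min center) plus
N(0, 0.1 min) noise. The informative triple is fixed at `logp`,
`frac_sp3`, `n_sp3_carbon` — three distinct, identifiable axes of the
panel's chemistry. This choice matters: on any homologous-series panel,
size, lipophilicity and polarizability measures are near-collinear, so
planting the dependence on one member of such a cluster (say MW, which MR
and heavy-atom count duplicate almost exactly) would make "recovering the
informative descriptor" ill-posed — the model could legitimately select
an interchangeable proxy. With identifiable axes, selection recovers the
planted triple and the held-out R² is ~0.97–0.99 with AAE of roughly half
a minute at this noise level.

## Numerical and degenerate-input choices

* Retention times are minutes everywhere internally; converters sit at
  the I/O boundary (`rt_unit = "sec"`, MGF `RTINSECONDS`).
* Zero intensity means "absent" for presence/absence analysis; blank
  intensity 0 always keeps a pair.
* Zero-variance compounds with equal means get p = 1 in `pairwise_diff()`.
* Empty spectra classify as `none` and score 0 with a warning.
* QSRR predictions are clipped to the training retention window.
* `link_ms2()` assigns each spectrum to at most one feature, greedily by
  precursor-m/z distance, making linking order-independent.
* Problem sizes in the test suite (tens of compounds, hundreds of decoys,
  200-compound differential panels) are chosen to exercise every code
  path at full statistical fidelity while keeping a complete run around a
  minute.

## Worked example

```{r example}
cfg <- sim_config(n_compounds = 20, n_decoys = 100,
                  ratio_noise_sigma = 0.05, mz_noise_ppm = 5, seed = 1)
sim <- simulate_compounds(cfg)
run <- simulate_features(sim, cfg)
pairs <- dedupe_pairs(find_pairs(run$features))
scorecard(pairs, run$truth)[c("recall", "precision", "n_detected")]
ann <- annotate_all(pairs, sim$db)
table(ann$level[ann$best])
```

## Known limitations

* `count_sites()` uses SMARTS heuristics; exotic tautomers or protecting
  groups can miscount derivatizable sites.
* The QSRR model interpolates: predictions for chemistry far outside the
  training panel are clipped, not extrapolated.
* Multi-tag screening assumes the all-light/all-heavy doublet; mixed
  isotopologues of multi-bromine ions are not searched.
* The similarity score is one (dominant) convention; scores from other
  metrics are not comparable number-for-number.
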