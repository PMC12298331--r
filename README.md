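# brpairscan

Screening, retention-time prediction, and hierarchical annotation of
hydroxyl and amino compounds labeled with 5-bromonicotinoyl chloride
(BrNC) in LC-HRMS metabolomics, plus cross-sample comparison and a
ground-truth simulator. Written for analytical chemists and metabolomics
bioinformaticians working with chemical-isotope-labeling data — for
example profiling alcohols, phenols, amines and amides in fermented
beverages such as sauce-flavor Baijiu.

## The idea

BrNC acylates OH and NH groups under mild conditions, adding the net
composition C6H2BrNO per site. Because natural bromine is a near-1:1
mixture of ⁷⁹Br and ⁸¹Br, every mono-tagged derivative shows up in MS1 as
a twin peak:

    Δm/z = m(⁸¹Br) − m(⁷⁹Br) = 1.998 Da
    I(M+2)/I(M)   = a(⁸¹Br)/a(⁷⁹Br) = 0.9728

`find_pairs()` mines aligned feature tables for co-eluting doublets with
this spacing (±10 ppm on the heavy m/z) and ratio (0.8–1.2). Reagent-derived
MS2 fragments then classify the derivative type:

| fragment ion | m/z | tells you |
|---|---|---|
| C6H3BrNO⁺ (acylium) | 183.9393 | BrNC-labeled |
| [C6H4BrNO2+H]⁺ | 201.9498 | hydroxyl derivative |
| [C6H5BrN2O+H]⁺ | 200.9658 | amino derivative |

A random-forest QSRR model (`qsrr()`) predicts derivative retention
times from molecular descriptors of the parent SMILES, and
`annotate_all()` assigns database candidates to five confidence levels —
1: standard-confirmed; 2: retention + MS1 + MS2 database match
(error < 10 ppm, Δt_R < 0.5 min, similarity > 0.5); 3: retention + MS1;
4: MS1 only; 5: molecular formula only. `pairwise_diff()` (Welch t-tests,
BH correction), `presence_intersections()` and `plsda_vip()` (NIPALS
PLS-DA variable importance, mean VIP² = 1) compare compound profiles
across sample groups.

## Worked example

Simulate a study with 20 planted BrNC derivatives and 100 unlabeled
decoys under realistic noise, screen it, and annotate against the
simulated compound database:

```r
library(brpairscan)

cfg <- sim_config(n_compounds = 20, n_decoys = 100,
                  ratio_noise_sigma = 0.05, mz_noise_ppm = 5, seed = 1)
sim   <- simulate_compounds(cfg)
run   <- simulate_features(sim, cfg)
pairs <- dedupe_pairs(find_pairs(run$features))

scorecard(pairs, run$truth)[c("recall", "precision", "n_detected")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
#> $n_detected
#> [1] 20

head(as.data.frame(pairs)[, c("pair_id", "rt", "mz_light", "mz_heavy", "ratio")], 3)
#>   pair_id       rt mz_light mz_heavy     ratio
#> 1   P0001 1.559949 320.0273 322.0249 0.8820056
#> 2   P0002 2.696297 336.0216 338.0193 0.8936957
#> 3   P0003 3.387188 364.0536 366.0519 0.9415090

ann <- annotate_all(pairs, sim$db)
#> annotation levels (best per pair): L1=0 L2=0 L3=20 L4=0 L5=0
```

All 20 planted pairs are recovered with no false positives; with
reference retention times but no reference spectra in the database, every
identification lands at confidence level 3, as the evidence hierarchy
dictates. The classic hand check: a light feature observed at m/z
322.0083 predicts its heavy partner at `br_shift(322.0083, 1)` =
324.0063.

The command-line wrapper mirrors the R interface
(`Rscript inst/cli/brpairscan.R simulate|pairs|ms2|qsrr-train|qsrr-predict|annotate|run-all ...`),
and `run_all()` executes the whole workflow from a YAML config, writing a
manifest with file hashes for provenance.

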