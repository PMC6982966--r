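# ck2qsar

2D QSAR modelling of casein kinase II (CK2) inhibitors in R.

CK2 is a constitutively active serine/threonine kinase overexpressed in
several cancers; its inhibitors are characterized by an IC50 against the
holoenzyme. `ck2qsar` is for computational medicinal chemists who want a
fully reproducible, dependency-light pipeline from structure to predicted
activity: it parses SMILES/SDF into a molecular graph, computes ten 2D
descriptors natively, fits and validates partial least squares (PLS)
regression models of pIC50 (= 9 − log10 IC50[nM]), and applies a frozen
published ten-descriptor linear equation to rank new candidates.

The ten descriptors are the charge-, logP- and molar-refractivity-binned
approximate van der Waals surface areas (PEOE_VSA+0, PEOE_VSA+1,
Q_VSA_HYD, Q_VSA_PNEG, SlogP_VSA7/8/9, SMR_VSA5), the Wiener path number,
and an approximate van der Waals volume. Partial charges come from the
Gasteiger–Marsili PEOE iteration; per-atom surfaces from a Labute-style
sphere-overlap approximation; atomic logP/MR contributions from the
Wildman–Crippen scheme. The frozen CK2 model is

```
pIC50 = 16.00545 + 0.06444·PEOE_VSA+1 − 0.03995·Q_VSA_HYD − 0.03312·Q_VSA_PNEG
        − 0.06251·SlogP_VSA7 − 0.03254·SlogP_VSA8 + 0.03023·SlogP_VSA9
        + 0.03672·SMR_VSA5 + 0.00160·weinerPath − 0.01269·vdw_vol
        + 0.01078·PEOE_VSA+0
```

All parameter tables (radii, PEOE coefficients, Wildman–Crippen
contributions, bond lengths, bin edges) ship as editable CSVs under
`inst/extdata/params/`.

## Worked example

Reproduce the published fit statistics from the packaged
tested/predicted pIC50 pair tables (the pure-table path, independent of
the descriptor engine):

```r
library(ck2qsar)
rep <- reportPairs(ck2TrainingPairs())
sprintf("n = %d  r2 = %.4f  RMSE = %.4f", rep$n, rep$r2, rep$rmse)
#> "n = 20  r2 = 0.9396  RMSE = 0.1264"
round(reportPairs(ck2TestPairs())$r2, 2)
#> 0.77
```

`r2 = 0.9396` is the squared Pearson correlation between tested and
PLS-predicted pIC50 over the 20 training compounds (printed as 0.94);
the external 10-compound test set gives 0.77.

Compute descriptors and screen the packaged name-derived structures with
the frozen equation:

```r
ns <- ck2NamedStructures()
computeDescriptors(ns$smiles[ns$id == "00082235"])
#> PEOE_VSA+0 PEOE_VSA+1  Q_VSA_HYD Q_VSA_PNEG SlogP_VSA7 SlogP_VSA8 SlogP_VSA9
#>  131.19633   43.46293  283.06715   69.35791    0.00000    0.00000    0.00000
#>   SMR_VSA5 weinerPath    vdw_vol
#>    0.00000 1296.00000  298.95142

runScreen(list(input = system.file("extdata", "structures",
                                   "named_structures.smi",
                                   package = "ck2qsar")))
#>         id predicted_pic50 predicted_ic50_nM flag
#> 1 01236034         10.6639            0.0217
#> 2 37867960          8.4492            3.5545
#> 3 01893208          6.7641          172.1405
#> 4       4w          5.5156         3050.9189
#> 5       4h          5.0621         8667.8768
#> 6 00082235          4.8947        12742.7412
```

Each row is a candidate ranked by predicted pIC50 (higher = more
potent), with the back-transformed IC50 in nM. Train your own model from
a compound CSV (`id,smiles,ic50[,set]`) with `runTraining()`, or from
the shell via the thin CLI:

```sh
Rscript inst/scripts/ck2qsar.R train --input compounds.csv --out run/ \
        --split random --seed 1 --components auto
Rscript inst/scripts/ck2qsar.R report --input inst/extdata/tables/training_pairs.csv
# n = 20  r2 = 0.9396  RMSE = 0.1264
```

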