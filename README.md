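# cwqsar

Correlation-weight QSAR models built directly from SMILES strings, for
modelling continuous endpoints such as acute fish toxicity
(pLC50, the decimal logarithm of LC50 in mg/L).  The intended users are
computational toxicologists and cheminformaticians who want a
fragment-based, descriptor-free baseline model with an explicit
applicability domain and a mechanistic reading of its weights.

## The method

A SMILES string is decomposed into *attributes*: single SMILES atoms
Sk (indivisible fragments such as `C`, `c`, `Cl`, `=`, `1`, `[N+]`,
`%11`) and canonically ordered adjacent pairs SSk (`cC`, `Cl(`, `=1`,
...).  Every attribute occurring in at least T compounds of the active
training set carries one optimizable *correlation weight* CW; rarer
attributes are blocked at zero.  The molecular descriptor is the plain
sum

    DCW(T, N) = sum CW(Sk) + sum CW(SSk)

and the model is the one-variable least-squares calibration

    pLC50 = C0 + C1 * DCW(T, N).

Weights are found by a seeded Monte Carlo optimization: N epochs, each
visiting all active attributes in random order and accepting a random
step `CW +/- delta` only if it strictly increases the target function,
either

    TF0 = R2_A + R2_P - 0.1 * |R2_A - R2_P|

(the determination coefficients of the active and passive training
sets), or

    TF1 = TF0 + 0.25 * IIC_C

where `IIC_C`, the index of ideality of correlation of the calibration
set, is the Pearson correlation multiplied by the ratio of the smaller
to the larger one-sided mean absolute error of the residuals.  TF1
penalizes one-sided calibration errors and, in practice, stops the
optimizer from chasing training-set perfection (overtraining).

Compounds are split 25/25/25/25 at random into active training, passive
training, calibration and validation roles.  The applicability domain
uses the statistical defects of attributes: with p the per-set
compound-frequency probabilities,

    dk = |pA-pP|/(nA+nP) + |pA-pC|/(nA+nC) + |pP-pC|/(nP+nC)

(1.0 when a set never saw the attribute), a compound's defect Dj sums dk
over its non-blocked attributes, and the compound is in-domain iff
`Dj < 2 * Dbar` with `Dbar` the active-training mean.  Attributes whose
weight keeps one sign over independent optimization probes are reported
as promoters of endpoint increase or decrease.

## Worked example

```r
library(cwqsar)

syn <- cw_synth(n = 120, noise = 0.1, seed = 7)   # synthetic benchmark
sp  <- cw_split(syn$data$id, seed = 7)            # four-way random split
fit <- cw_fit(syn$data, sp, cw_control(target = "TF1", seed = 1))
fit
#> Correlation-weight QSAR model
#>   target: TF1, T = 1, N = 15 epochs, seed = 1
#>   attributes: 41 active, 1 blocked
#>   calibration line: endpoint = 1.2534 + -0.4258 * DCW
#>   validation: n = 26, R2 = 0.7928, RMSE = 0.640
summary(fit)
#> Model statistics per set (target TF1 ):
#>  set  n     r2    ccc    iic     q2  rmse   mae   f
#>    A 31 0.8855 0.9393 0.6796 0.8625 0.520 0.406 224
#>    P 27 0.9218 0.9038 0.6905 0.8985 0.679 0.533 295
#>    C 36 0.8414 0.9112 0.9169 0.8209 0.719 0.546 180
#>    V 26 0.7928 0.8883 0.8571 0.7600 0.640 0.508  92
#> Compounds outside the applicability domain: 7
```

The summary is one row per set: n, determination coefficient R2, Lin's
concordance CCC, the IIC, leave-one-out Q2, RMSE and MAE in endpoint
units, and the Fischer F-ratio.  The validation row (never used during
fitting) is the honest predictivity estimate: here the model explains
79% of validation variance with RMSE 0.64 log units.  Predictions for
new molecules carry the domain flag:

```r
predict(fit, c("Oc1ccc(Cl)cc1", "CCN(CC)C(=S)S"), domain = TRUE)
#>   id       dcw predicted        dj in_domain
#> 1  1 -5.031095  3.395494 0.3459725      TRUE
#> 2  2 -5.254641  3.490673 0.2072029      TRUE
```

and sign-stable attributes over three optimization probes give the
mechanistic reading:

```r
pro <- classify_promoters(cw_probes(syn$data, sp, cw_control("TF1", seed = 1)))
head(as.data.frame(pro)[, c("attribute", "cw_probe1", "cw_probe2",
                            "cw_probe3", "nA", "classification")], 4)
#>   attribute   cw_probe1   cw_probe2  cw_probe3 nA classification
#> 1        OC  0.05573987  0.38182258  0.5449223 11       increase
#> 2        cO  0.80582368  0.05311859  1.5207063  2       increase
#> 3        c1 -0.73970733 -0.53187481 -0.5790557 16       decrease
#> 4        O( -0.59774332 -0.45078337 -0.6183276 11       decrease
```

`plot(fit, "history")` draws the per-epoch R2 trajectories on which
overtraining is diagnosed, and `plot(fit, "clusters")` the
observed-vs-predicted cloud split by residual sign.  A command-line
interface wrapping the same functions (subcommands `synth`, `split`,
`train`, `predict`, `domain`, `interpret`, `report`) is installed at
`system.file("cli", "cwqsar.R", package = "cwqsar")`.

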