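# zindoml

Delta machine learning of TDDFT excited-state energies from ZINDO.

## The problem

Virtual screening for organic emitters needs first-singlet (S1)
excitation energies for very large molecule libraries. TDDFT is
accurate but costs ~20 minutes per molecule; semiempirical ZINDO costs
~2 seconds but carries a systematic, molecule-dependent bias. Across
pi-conjugated organics the two are linearly related,

    E_S1(Linear) = m * E_S1(ZINDO) + c        (m ~ 1.08, c ~ 0.52 eV)

but the chemistry-specific scatter around that line limits the fit to
roughly 0.3 eV MAE. `zindoml` is for computational chemists who want
TDDFT-quality S1 energies at ZINDO cost: it learns the residual

    deltaE = E_S1(TDDFT) - E_S1(ZINDO)

with an ensemble of attention-based message-passing networks and adds
the learned correction back onto the ZINDO value (`prediction =
ML(x) + E_ZINDO`). The descriptors are mined from the same cheap
calculation: per-atom Mulliken charges, atomic potentials
`phi_i = sum_{j!=i} Z_j / r_ij`, natural-transition-orbital
particle/hole densities, and a HOMO-population-weighted radial
distribution function (MO-RDF, 726 channels on a 0.5–15 A grid,
sigma = 0.05 A). Model variants follow the "component(descriptor)"
naming scheme — `Linear(E_ZINDO)`, `MPNN(DA)`, `MPNN(DA, EA)`,
`Dense(MPNN(DA, EA), E_ZINDO, MO-RDF)`, etc. — and training uses
k-fold cross-validated ensembles with Adam, batch normalization,
dropout, a cyclical learning rate and early stopping.

The package also implements the dataset-construction protocol
(conjugated-core clustering, C/N/O/S/F 10–25-heavy-atom candidate
filters, nitroso removal, core-analogue test sampling, ring-based
external-set filtering, parity splits), the evaluation suite
(regression metrics, binned median errors, visible-range screening for
1.7 < E < 3.3 eV, oscillator-strength classification at f > 0.4), and
a synthetic-data generator so the whole pipeline runs and is tested
without any quantum chemistry.

## Worked example

Generate a synthetic delta-learning dataset (2000-molecule scale runs
in minutes; 400 here for a quick demonstration), train a 3-fold
ensemble of the `Dense(MPNN(DA, EA), E_ZINDO)` variant, and compare it
with the linear baseline on held-out molecules:

```r
library(zindoml)

ds    <- generateDataset(syntheticSpec(nMolecules = 400, seed = 7))
feats <- featurizeDataset(ds, withMordf = FALSE)
ids      <- datasetIds(ds)
testIds  <- kfoldSplit(ids, 4, seed = 7)$folds[[1]]
trainIds <- setdiff(ids, testIds)

variant <- parseVariant("Dense(MPNN(DA, EA), E_ZINDO)",
                        dense   = denseBlockSpec(c(64L, 32L), dropout = 0.2),
                        encoder = encoderSpec(nodeChannels = 45L,
                                              hiddenDim = 48L,
                                              fingerprintDim = 48L))
cfg <- trainConfig(k = 3L, lr = 1e-3, batchSize = 32L,
                   maxEpochs = 40L, patience = 15L, baseSeed = 7L)
ens  <- trainEnsemble(variant, feats, trainIds, cfg)
pred <- ensemblePredict(ens, feats, testIds)

truth <- vapply(feats[testIds], `[[`, numeric(1), "eHigh")
print(regressionMetrics(pred$e_pred, truth))
#> EvalReport (n = 100): r = 0.9940, MAE = 0.1397 eV, RMSE = 0.1610 eV
#>   median |err| = 0.1450 eV, 95% of errors below 0.2744 eV

eLow <- vapply(feats[testIds], `[[`, numeric(1), "eLow")
base <- linearFit(vapply(feats[trainIds], `[[`, numeric(1), "eLow"),
                  vapply(feats[trainIds], `[[`, numeric(1), "eHigh"))
print(regressionMetrics(linearPredict(base, eLow), truth))
#> EvalReport (n = 100): r = 0.9885, MAE = 0.1939 eV, RMSE = 0.2014 eV
#>   median |err| = 0.1812 eV, 95% of errors below 0.2993 eV
```

Already at this small scale and epoch budget the learned correction
beats the linear baseline; at the package's benchmark scale (2000
molecules, 100 epochs) the ensemble MAE falls to ~0.045 eV against the
baseline's ~0.20 eV, within ~15 % of the Bayes-optimal error for the
generator's noise level. Each `EvalReport` line gives the Pearson
correlation with the high-level truth, the mean/median absolute error
in eV, and the error below which 95 % of predictions fall.

A thin command-line wrapper for the same workflows (synth, run,
curate, evaluate) ships in `inst/cli/zindoml`.

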