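# secshift

Interactome rewiring analysis for co-fractionation and isothermal shift
proteomics.

## What this package is for

When budding yeast exhausts glucose and switches to respiratory growth on
ethanol (the diauxic shift), hundreds of proteins change their oligomeric
state, their metabolite partners and their thermal stability. Two
complementary proteome-wide readouts capture this rewiring:

* **CF-MS / SEC co-fractionation** — native lysate is separated on a
  size-exclusion column into 60 fractions (the first 40 protein-containing,
  spanning roughly 5 MDa down to 20 kDa); proteins and metabolites are
  quantified per fraction. Complex assembly or disassembly moves a
  molecule's elution profile; metabolites bound to protein split into an
  early-eluting bound pool and a late-eluting free pool.
* **iTSA** — soluble protein abundance after a brief heat challenge at
  fixed temperatures (48, 52, 56 °C) relative to room temperature; shifts
  in the apparent melting behaviour proxy changes in ligand binding, PTM
  state or complex membership.

`secshift` implements the full analysis chain for both readouts, plus a
synthetic-data generator with programmed ground truth so every stage can be
validated end to end:

| stage | statistic |
|---|---|
| differential abundance | median normalization, two-sided Student's t-test on log2 intensities, Benjamini–Hochberg FDR, \|FC\| > 2 |
| differential thermal stability | per-temperature median equalization, RT scaling, per-temperature t-tests, union across temperatures |
| differential fractionation | Manhattan distance between processed profiles; differential when MD > 1.5 × median MD; permutation "dis-elution" surrogate for replicated profiles |
| metabolite pools | total = Σ all 60 fractions, bound = Σ fractions 1–40, free = Σ 41–60; bound/free ratio medians compared by paired Wilcoxon |
| networks | peak deconvolution (maxima ≥ 10 % of main maximum), Pearson correlation between peak subprofiles, edges at PCC ≥ 0.7, Louvain communities |
| interaction rates | InteractionRate = 100 · n_interactions / (n_dipeptide_peaks · n_protein_peaks), per dipeptide group × pathway |

## Worked example

```r
library(secshift)
cfg <- pipeline_config(out_dir = "secshift_run", seed = 42,
                       n_proteins = 80, n_metabolites = 40)
res <- run_pipeline(cfg)
print(res)
```

```
secshift pipeline result
                                                  quantity        value
                 significant abundance, glucose vs ethanol  52.00000000
        significant abundance, glucose vs early_stationary  44.00000000
        significant abundance, ethanol vs early_stationary  53.00000000
          differential stability union, glucose vs ethanol   0.00000000
 differential stability union, glucose vs early_stationary  78.00000000
 differential stability union, ethanol vs early_stationary  63.00000000
            differential fractionation, glucose vs ethanol   4.00000000
   differential fractionation, glucose vs early_stationary  17.00000000
   differential fractionation, ethanol vs early_stationary  20.00000000
                   differential totals, glucose vs ethanol  22.00000000
          differential totals, glucose vs early_stationary  27.00000000
          differential totals, ethanol vs early_stationary  25.00000000
                 median bound/free ratio, early_stationary   0.08550819
                          median bound/free ratio, ethanol   0.02022841
                          median bound/free ratio, glucose   0.01517558
                                      communities, glucose 131.00000000
                                      communities, ethanol 106.00000000
                             communities, early_stationary  70.00000000
                         stability & fractionation overlap  17.00000000
```

Reading the numbers: the simulated world programs 17 fractionation-rewired
and 20 stability-rewired proteins between glucose and early stationary
phase. The Manhattan criterion recovers exactly the 17 programmed
disassembly events (`differential fractionation, glucose vs
early_stationary`), and all 17 also appear in the stability/fractionation
overlap. The median bound/free ratio rises from ~0.015 (glucose) to ~0.086
(early stationary), reflecting the programmed global increase in metabolite
binding. The large stability union (78) is an expected artefact of the
per-temperature median equalization when a quarter of the proteome has
genuinely shifted — see the methods vignette, "Known limitations".
Per-stage TSVs, GraphML networks and the ground-truth JSON are written to
`out_dir`.

A command-line interface wraps the same stages:

```sh
Rscript -e 'secshift::secshift_cli()' simulate --out inputs/ --seed 7
Rscript -e 'secshift::secshift_cli()' run-all --config cfg.json --out results/
```

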