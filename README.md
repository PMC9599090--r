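# plfcs

Cross-modal analysis of resting-state functional connectivity loss and
regional tau-PET burden along the Alzheimer's disease spectrum.

## The problem

In neurodegeneration studies, each subject's resting-state fMRI is
parcellated with a brain atlas (e.g. the 246-region Brainnetome atlas),
every region is treated as a network node, and the Pearson correlations
between regional BOLD signals form an N×N association matrix (Fisher
z-transformed).  A node's **functional connection strength** is its
weighted degree,

    mu_i = sum_{j != i} |z_ij| ,

and the **proportional loss of functional connectivity strength (PLFCS)**
expresses each node's strength relative to the normal-control (NC)
baseline,

    Loss_i = (mu_i - sigma) / sigma ,

where sigma is the average connection strength of the baseline group.
Regional tau burden is quantified from PET as the **standardized uptake
value ratio (SUVR)** against a cerebellar reference region.  The package
implements the full analysis that links the two modalities:

* association matrices, Fisher z-transform, node strength, group means;
* PLFCS against an NC baseline (global-scalar or per-node sigma, printed
  or inverted sign convention — both documented variants are exposed);
* regional SUVR from NIfTI PET volumes and a reference mask;
* NC-vs-CI (cognitive impairment = MCI + AD) node selection by two-sample
  t-test or subject-label permutation test;
* region-wise Pearson correlation of strength/loss with tau SUVR per
  diagnostic group; hub-vulnerability correlation (do strongly connected
  regions lose proportionally more?); clinical-scale correlations; and
  three-group ANOVA with Bonferroni post hoc.

Because studies of this kind rarely deposit scans, the package ships a
**synthetic cohort generator**: a hub-structured ground-truth covariance,
disease groups whose connections are attenuated in proportion to baseline
hubness, tau SUVR coupled to the designed loss with a chosen sign per
region, and MMSE/CDR-SB-like scores.  Every downstream stage is validated
end-to-end against cohorts whose ground truth is known.

Intended users: imaging neuroscientists and methodologists who want a
tested, scriptable reference implementation of the PLFCS analysis, either
on their own parcel-ready data (NIfTI volumes or ROI tables) or in
simulation studies.

## Worked example

```r
library(plfcs)

spec <- cohort_spec(n_regions = 60,
                    n_subjects = c(NC = 20, MCI = 20, AD = 20),
                    n_timepoints = 200, hub_exponent = 2,
                    beta = c(MCI = 0.2, AD = 0.4), seed = 1)
run <- run_pipeline(run_config("simulate", spec = spec, seed = 1))
print(run)
```

prints (abridged):

```
# Cross-modal connectivity-loss analysis report

## Group means of global metrics

- NC (n=20): FCs 8.5766, PLFCS 0.0000, SUVR 0.9983
- MCI (n=20): FCs 6.3968, PLFCS -0.2542, SUVR 1.0481
- AD (n=20): FCs 5.0144, PLFCS -0.4153, SUVR 1.2524

## Node selection (NC vs CI)

- 55 of 60 regions selected

## Hub vulnerability

- MCI: r = -0.8854, p = 2.41e-20 over 60 regions
- AD: r = -0.9495, p = 6.48e-31 over 60 regions
```

Reading the numbers: NC global PLFCS is 0 by construction (the baseline
against its own sigma); the disease groups sit below baseline (lost
strength) and above it in global tau SUVR, ordered NC < MCI < AD.  The
node-selection screen flags 55 of 60 regions as differing between NC and
CI at p < 0.05.  The strongly negative hub-vulnerability correlations
recover the designed mechanism: regions with higher control-group
connection strength lose a proportionally larger share of it in disease.

A thin command-line wrapper with subcommands (`simulate`, `extract`,
`connect`, `plfcs`, `suvr`, `stats`, `run`, `report`) is installed at
`inst/cli/plfcs_cli.R`:

```sh
Rscript inst/cli/plfcs_cli.R simulate --out cohort --regions 60 --subjects 20 --seed 1
Rscript inst/cli/plfcs_cli.R plfcs --manifest cohort/manifest.tsv --out loss.tsv
```

See `vignettes/plfcs-methods.Rmd` for the model, the analysis variants and
the design rationale.

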