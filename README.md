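# pcaUFE

PCA-based unsupervised feature extraction for case/control expression
matrices, and the full miRNA–mRNA interaction pipeline built on it:
outlier-feature selection, reciprocal-regulation pairing against
conserved miRNA target families, leave-one-out linear-discriminant
validation scored by Fisher's exact test, and a Storey q-value
cross-check. It is aimed at transcriptomics analysts who want candidate
miRNA–mRNA interaction lists small enough to curate by hand, together
with the machinery to verify, on synthetic data with known ground
truth, that the selection is calibrated and actually recovers planted
signal.

## The method

For a per-sample standardized features × samples matrix $X$
($\frac1N\sum_i x_{ij}=0$, $\frac1N\sum_i x_{ij}^2=1$), the *features*
are embedded through unit-norm eigenvectors $u_k$ of the gram matrix,
$XX^{\mathsf T}u_k=\lambda_k u_k$, with per-sample loadings
$v_k = X^{\mathsf T}u_k$. Components whose loadings separate cases from
controls (t test, $p<0.05$) form the set $\Omega$, and feature $i$ is an
outlier when the BH-adjusted upper-tail probability

$$P_i = P\Big[\chi^2_{|\Omega|} > \sum_{k\in\Omega}(u_{ki}/\sigma_k)^2\Big] $$

falls below 0.01, $\sigma_k$ being the standard deviation of the $k$-th
scores across features. Selection strength scales with the feature
count, not the sample count. Outlier miRNAs and mRNAs with significant
opposite-direction regulation (Welch t test, BH $p<0.05$) are paired
when the mRNA is a conserved target of the miRNA's family; selections
are validated by equal-prior LDA under leave-one-out cross-validation on
recomputed PC loadings, scored by Fisher's exact test. See the methods
vignette (`vignettes/pca-unsupervised-fe.Rmd`) for the full account.

## Worked example

```r
library(pcaUFE)

sim <- generateSynthetic(syntheticConfig(seed = 1))   # planted ground truth
fe  <- selectFeatures(sim$mrna)                       # PCA-based FE
fe
#> FeatureOutlierResult: 50 of 2000 features selected (adjusted p < 0.01 , df = 2 )

fe_i  <- selectFeatures(sim$mirna)
cm    <- callRegulation(sim$mrna,  selectedFeatures(fe))
ci    <- callRegulation(sim$mirna, selectedFeatures(fe_i))
pairs <- findReciprocalPairs(ci, cm, sim$targets)
head(pairs, 3)
#>      mirna_id   gene_id mirna_direction gene_direction  family
#> 1 hsa-miR-110 GENE00084            down             up mir-110
#> 2 hsa-miR-110 GENE00299            down             up mir-110
#> 3 hsa-miR-110 GENE00514            down             up mir-110
nrow(pairs)
#> [1] 160

discriminate(sim$mrna, selectedFeatures(fe), L = 2)
#> DiscriminationResult (L = 2 )
#>          True
#> Predicted case control
#>   case      20       0
#>   control    0      20
#> Fisher p = 1.45e-11 , odds ratio = Inf
```

All 50 planted mRNA outliers are recovered out of 2000 features, the 160
reciprocal pairs are the planted miRNA→target structure, and the
selected features separate the two cohorts perfectly under leave-one-out
LDA. On a published confusion matrix the Fisher scoring reproduces the
reported statistics:

```r
fisherExactTest(matrix(c(28, 2, 2, 28), 2))
#> $p.value    3.22e-12
#> $odds.ratio 154.7
```

A file-based run (`runPipeline()`) and a thin CLI
(`inst/cli/pcaufe.R`, subcommands `normalize`, `select`, `pairs`,
`discriminate`, `qvalue`, `simulate`, `run`) produce the same results
from TSV inputs and write per-stage reports plus a machine-readable
summary.

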