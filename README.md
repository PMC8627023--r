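# microTCA

Transfer-learning prediction of functional microexons in R.

Microexons — coding exons of 3–30 nt — are highly conserved, enriched near
protein–protein interaction surfaces and frequently alternatively spliced,
but no public resource labels them functional or neutral, so a classifier
cannot be trained on them directly. Non-frameshift microindels *are*
labeled (pathogenic in disease-mutation catalogs, neutral in population
sequencing) and resemble microexons in size, reading-frame behavior and
functional biology. microTCA learns "functional vs neutral" on microindels
and transfers that knowledge to microexons. It is aimed at
transcriptomics / splicing researchers who want a functional prior over
microexon catalogs, and at method developers who need a clean, tested
Transfer Component Analysis implementation with a genomic data model.

## Method

Both record classes are summarized by the same 25 features: record length;
max/min/mean windowed DNA conservation; max/min/mean secondary-structure
probability for coil/helix/sheet plus the predicted-class fractions;
max/min/mean disorder and accessible surface area; protein length and the
residue distances to both termini. Windows are the record span ±2
positions (for insertions: the two flanking bases ±2).

With standardized feature matrices X_S (n₁ microindels) and X_T
(n₂ microexons), the domain gap is the kernel maximum mean discrepancy

    MMD² = ‖ (1/n₁) Σᵢ φ(x_Sᵢ) − (1/n₂) Σⱼ φ(x_Tⱼ) ‖²_H
         = mean(K_SS) − 2·mean(K_ST) + mean(K_TT).

Transfer Component Analysis stacks both domains into the joint Gram matrix
K and takes the leading m eigenvectors W of

    (K L K + μI)⁻¹ K H K ,     H = I − 𝟙𝟙ᵀ/(n₁+n₂),  μ = 0.1,

where L is the MMD coefficient matrix (so tr(KL) = MMD²); the embedding
K·W minimizes the cross-domain discrepancy while preserving embedded
variance. An SVM with Platt-scaled probabilities is trained on the
transferred microindel components, evaluated by stratified 10-fold
cross-validation (precision, accuracy, MCC, recall, rank-statistic AUC),
and applied to the microexon components; a record is called functional at
probability ≥ 0.5. Novel single microexons, which cannot enter the
two-sample fit, are scored by the mean probability of their k = 5 nearest
already-scored neighbors in the standardized feature space.

## Worked example

The package ships a 19-record panel of literature-reported functional
microexons with their model probabilities:

```r
library(microTCA)
lit <- literatureMicroexons()
countAtThreshold(lit, 0.5)   # 16  of 19 called functional at p >= 0.5
countAtThreshold(lit, 0.6)   # 15  still called at the stricter 0.6
```

A fully synthetic end-to-end run (no external data needed) — generate a
covariate-shifted source/target pair, fit the transfer space, train and
evaluate the classifier, label the target:

```r
cfg <- runConfig(scenario = shiftScenario(), outDir = "run1")
res <- runPipeline(cfg)

res$report
#> EvaluationReport (10-fold CV, seed 20211126)
#>   precision 0.834 | accuracy 0.827 | MCC 0.651 | recall 0.845 | AUC 0.896

head(res$predictions, 3)
#>   record_id probability      label threshold   route
#> 1     tgt_1  0.08816870    neutral       0.5 tca_svm
#> 2     tgt_2  0.06119328    neutral       0.5 tca_svm
#> 3     tgt_3  0.89913063 functional      0.5 tca_svm

res$manifest$pre_tca_mmd    # 24.44    domain gap before transfer
res$manifest$post_tca_mmd   # 4.24e-05 and after
res$manifest$n_functional   # 148 of 300 target records called functional
```

The cross-validation block reports how well "functional vs neutral"
is learned *on the source domain after transfer*; the MMD pair shows the
latent space has collapsed the distribution gap; and because the synthetic
scenario keeps hidden ground-truth target labels, the transfer itself can
be scored — comparing `res$predictions` against the generator's hidden
labels gives 0.817 accuracy here. A later, novel record is scored with
`knnPredict(res$catalog, x, k = 5)`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/microtca.R` (`filter`, `simulate`, `run`, `mmd`,
`knn-predict` subcommands).

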