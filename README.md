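# ddihybrid

Multiclass prediction of drug–drug interaction (DDI) *types* for ordered
drug pairs, from structure alone.

When two drugs are taken together, one (the *perpetrator*, B) can change
the exposure of the other (the *victim*, A) — most often by inhibiting or
inducing a cytochrome P450 enzyme that clears the victim. Interaction
databases describe each directed pair with one of 19 templated
descriptions; predicting that class from nothing but a SMILES string and a
CYP450 annotation panel makes the assessment available at the earliest
stages of drug development, before any clinical data exist.

`ddihybrid` is for cheminformaticians and ML practitioners who need that
pipeline as composable, tested R functions: tibbles in, tibbles out,
`tidy()`/`glance()`/`autoplot()` on every fitted object, plus a
command-line front end.

## The method

Two feature families are computed per ordered pair (A, B):

**Chemical interaction features.** Each drug gets a fixed, ordered vector
of p = 60 molecular descriptors computed from its canonicalized SMILES
(constitutional counts, topological indices, MOE-type MR-VSA/logP-VSA
bins). The pair is featurized with one of three operators:

- cross product `F(k) = Fa(i) × Fb(j)`, `k = (i−1)p + j` → 3600 features
  (the default — richest representation),
- concatenation `(Fa, Fb)` → 120 features,
- elementwise sums then products → 120 features.

**CYP450 interaction features.** Over the fixed 12-enzyme panel (1A2, 2A6,
2B6, 2C18, 2C19, 2C8, 2C9, 2D6, 2E1, 3A4, 3A5, 3A7), the victim vector
has 1 at enzymes that metabolise A; the perpetrator vector has +1 at
enzymes B inhibits and −1 at enzymes B induces. Their elementwise product
is the interaction vector: +1 → victim exposure rises, −1 → it falls.

The pipeline then: drops classes below a frequency cutoff, splits 70/30
stratified, consensus-selects the 94 chemical features ranked important by
*both* a random-forest importance and a univariate ANOVA-F ranking
(training data only), appends the 12 CYP components (94 + 12 = 106
features), SMOTE-balances inside each training fold, grid-searches one of
five classifier families (naive Bayes, decision tree, random forest,
multinomial logistic regression, XGBoost) with stratified 5-fold CV, and
reports per-class precision/recall/F1, accuracy, and one-vs-rest ROC/AUC.

A synthetic generator ships as first-class, tested code: it emits valid
SMILES from a fragment grammar, samples CYP profiles at realistic rates,
and plants a documented decision rule (CYP sign patterns → mechanism
classes; molecular-weight × connectivity products → chemical classes) with
geometric class imbalance and 5% label noise, so the whole pipeline is
verifiable end to end without any licensed download.

## Worked example

```r
library(ddihybrid)

drugs <- tibble::tibble(
  drug_id = c("terf", "keto"),
  smiles  = c("CC(C)(C)c1ccc(CCCC2CCN(CC2)C(c2ccccc2)c2ccccc2)cc1",
              "CC(=O)N1CCN(CC1)c1ccc(OCC2COC(Cn3ccnc3)(O2)c2ccc(Cl)cc2Cl)cc1")
)
desc <- compute_descriptors(drugs)
desc[, c("drug_id", "MW", "nRing", "nAromRing", "nRotB", "MRVSA6")]
#> # A tibble: 2 × 6
#>   drug_id    MW nRing nAromRing nRotB MRVSA6
#>   <chr>   <dbl> <dbl>     <dbl> <dbl>  <dbl>
#> 1 terf     426.     4         3     8   192.
#> 2 keto     531.     5         3     8   165.
```

Each row is one drug's 60-descriptor vector (here a terfenadine-like
victim and a ketoconazole-like perpetrator); `MW` is molecular weight,
`MRVSA6` a molar-refractivity surface-area bin. The cross-product operator
expands the pair into 3600 interaction features:

```r
f <- cross_product_features(unlist(desc[1, -1]), unlist(desc[2, -1]))
length(f)
#> [1] 3600
round(f["A:MW*B:MW"], 1)
#> A:MW*B:MW
#>  226210.2
```

The CYP side: the victim is a 3A4 substrate, the perpetrator a 3A4 (and
2C9) inhibitor, so the interaction vector flags +1 at 3A4 — the classic
"inhibited clearance, rising victim concentration" pattern:

```r
v <- encode_victim("3A4")
p <- encode_perpetrator(inhibitors = c("3A4", "2C9"))
cyp_interaction(v, p)
#>  1A2  2A6  2B6 2C18 2C19  2C8  2C9  2D6  2E1  3A4  3A5  3A7
#>    0    0    0    0    0    0    0    0    0    1    0    0
```

The full pipeline on simulated data:

```r
res <- run_pipeline(quickstart_config(seed = 7))
glance(res)          # one-row summary: accuracy, macro/micro P/R/F1, AUC
tidy(res$metrics)    # per-class table
autoplot(res)        # per-class bar chart
```

A shell front end wraps the same functions:

```sh
exec/ddihybrid simulate --n-drugs 400 --n-pairs 5000 --seed 7 --out data/
exec/ddihybrid pipeline --config config.yaml
```

## Scope

DrugBank parsing/download, quantitative inhibition constants, transporter
interactions, and deep-learning baselines are out of scope. Performance on
licensed interaction databases is not reproducible from this repository;
everything the tests assert is computed on synthetic data with known
ground truth.
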