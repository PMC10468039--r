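# topocyto

Topological data analysis of diagnostic flow-cytometry point clouds for
relapse prognosis.

## What problem this solves, and for whom

In B-cell acute lymphoblastic leukaemia, clinicians estimate relapse risk at
diagnosis partly by eyeballing 2-D projections of flow-cytometry data: each
cell is a point in immunophenotypic marker space (CD10, CD19, CD20, CD38,
CD45, ...), and the *shape* of the per-patient point cloud — isolated cell
clusters, "empty spaces" between and inside them — carries prognostic
information. `topocyto` is for computational researchers who want that
assessment quantified: it turns each patient's cloud into persistent-homology
summaries and feeds them to statistical and machine-learning layers that
separate relapsing (R) from non-relapsing (NR) profiles.

## The method in brief

For a landmark subsample $X$ of a patient's rescaled cloud, the
Vietoris–Rips filtration assigns each simplex the largest pairwise distance
among its vertices, and persistent homology tracks connected components
(dim 0), loops (dim 1) and voids (dim 2) as bars $[r_b, r_d)$ with
persistence $p = r_d - r_b$. Three summaries are built per barcode:

- **descriptor vectors**: $(\max p, \min p, \bar p, \mathrm{sd}\,p)$ in
  dims 0 and 1;
- **PT curves**: $\#\{ \text{bars} : p > \tau \}$ (and the percentage) over
  a threshold grid, e.g. $\tau \in [0.04, 0.05]$ for loops;
- **persistence images**: Gaussian-smoothed, persistence-weighted mass on a
  $g \times g$ grid in (birth, persistence) coordinates.

Three prognostic pipelines sit on top: random-forest screening of pairwise
marker combinations (which markers carry shape information), a PT-curve
distance score
$\Pr(\text{relapse}) = \tfrac{1}{|P|}\sum_{\text{pairs}} d_{NR}/(d_{NR}+d_R)$
against cohort mean curves, and RBF-SVM / logistic-regression classification
of persistence images with stratified 6-fold cross-validation and in-fold
minority oversampling. Dim-0 persistence is union-find over the edge
filtration (deaths = MST edge weights); dims 1–2 use the cohomology-side
matrix reduction with clearing, validated exactly against a naive reduction
oracle in the test suite.

## Worked example

No patient data ship with the package; the synthetic generator plants the
R/NR topological contrast (R clouds get a persistent loop in the CD10–CD20
plane and more clusters) so the whole pipeline runs from nothing:

```r
library(topocyto)
spec   <- generator_spec(n_cells = 1000L)
cohort <- generate_cohort(spec, n_nr = 20, n_r = 8, master_seed = 42)
cfg    <- run_config(n_cells = 1000, n_landmarks = 120, seed = 42)

# approach 2: PT-curve distance score, fitted on the discovery split
a2 <- run_approach2(cohort, cfg)
round(with(a2$scores, tapply(score, paste(label, split), mean)), 3)
#>  NR discovery NR validation   R discovery  R validation
#>         0.459         0.478         0.654         0.599
round(a2$report$auc, 3)          # held-out validation AUC
#> [1] 1

# approach 3: persistence images (25x25, spread 0.05) + SVM (C=10, gamma=1e-3)
a3 <- run_approach3(cohort, cfg, methods = "svm")
round(a3$svm$cv_accuracy, 3)     # stratified 6-fold CV accuracy
#> [1] 0.806

# one patient's barcode in the CD10-CD20 projection
cl <- cohort$clouds$P001
bc <- persistence_vr(maxmin_landmarks(
        project_pair(gate_cd19(cl, 0.5), "CD10", "CD20"), 120)$cloud,
      maxdim = 1)
bc
#> dim 0: 120 bars (1 essential)
#> dim 1: 36 bars (0 essential)
```

Interpretation: relapse-like patients score above 0.5 on the distance ratio
(their PT curves sit closer to the R cohort mean), and the held-out AUC of 1
on this small cohort means the score ranks every validation R patient above
every NR patient. The 36 dim-1 bars include the planted annulus as the
single highly persistent loop. At the default test scale (80 NR + 16 R,
2000 cells, 200 landmarks) the acceptance suite requires CV accuracy
≥ 0.9 and held-out AUC ≥ 0.85, with permuted-label nulls at chance.

A command-line front end covers the same pipeline stage by stage
(`simulate | preprocess | ph | features | ptcurves | pimages | compare |
screen | classify | predict`):

```sh
Rscript -e 'topocyto::topocyto_cli()' simulate --out cohort --n-nr 20 --n-r 8 --seed 42
Rscript -e 'topocyto::topocyto_cli()' classify --manifest cohort/manifest.csv --grid 25 --seed 42
```

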