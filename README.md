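# zinbfactor

Low-dimensional signal extraction from zero-inflated count matrices —
single-cell RNA-seq in particular — with a **zero-inflated negative
binomial (ZINB) factor model** estimated by penalized maximum likelihood.

scRNA-seq counts carry technical *dropouts*: genes that are expressed but
recorded as zero. PCA on (log-)normalized counts mixes this technical zero
inflation into its leading components, which then often track detection
rate instead of biology. `zinbfactor` instead models each count as

```
Y_ij ~ pi_ij * delta_0  +  (1 - pi_ij) * NB(mu_ij, theta_j)
ln mu      = X beta_mu + (V gamma_mu)' + W alpha_mu + O_mu
logit pi   = X beta_pi + (V gamma_pi)' + W alpha_pi + O_pi
ln theta_j = zeta_j
```

with known cell-level covariates `X` (batch, QC, intercept), known
gene-level covariates `V` (length, GC, intercept — whose coefficient acts
as a cell-specific scaling factor, so the model runs on **raw counts** with
no prior normalization), offsets `O`, and `K` unobserved factors `W` with
loadings `alpha`: the low-dimensional signal. Estimation maximizes the
log-likelihood minus a ridge penalty that is equivalent to nuclear-norm
regularization of `W alpha`, via a warm start (log-normal ridge +
soft-thresholded-SVD matrix completion + ridge logistic regression)
followed by block-coordinate ascent with analytic-gradient BFGS
sub-solvers and SVD rebalancing of the factors. The package also ships the
model-based and genewise count simulators used to validate the procedure
(with explicit control of cluster separation and zero fraction), the
evaluation metrics (silhouette widths, pair-counting precision/recall,
pairwise-distance correlation, bias/MSE), and count-matrix IO, gene
filtering, and TC/FQ/TMM normalization baselines for the PCA comparison.

Intended users: anyone needing a dropout-aware replacement for PCA as the
dimensionality-reduction step before clustering, trajectory inference or
visualization, and method developers who need a controlled ZINB testbed.

## Worked example

Simulate clustered counts from a synthetic template at a 60% zero
fraction, fit the model, and compare the recovered factors to the truth:

```r
library(zinbfactor)

tpl <- syntheticTemplate(J = 120, K = 2, C = 3, profile = "deep", seed = 11)
sim <- simulateScenario(tpl, n = 150, J = 120, targetZeroFraction = 0.6,
                        b2 = 1, C = 3, seed = 12)
mean(sim$counts == 0)              # 0.594 — calibrated zero fraction

Y   <- filterGenes(sim$counts, minReads = 2, minCells = 2)
fit <- zinbFit(Y, K = 2)
fit
#> Object of class ZinbFit
#> 150 samples; 120 genes; 2 latent factor(s)
#> X: 1 column(s) (mu: 1, pi: 1); V: 1 column(s) (mu: 1, pi: 1)
#> dispersion: genewise; epsilon = 120
#> converged: TRUE after 4 outer iteration(s); penalized loglik -35791.8239

distanceCorrelation(sim$W, getW(fit))$average   # 0.942
silhouetteWidths(as.matrix(dist(getW(fit))), sim$labels)$average  # 0.425
round(c(AIC = zinbAIC(fit, Y), BIC = zinbBIC(fit, Y)))  # 73986, 78321
```

The distance correlation of 0.94 says the pairwise geometry of the true
two-dimensional signal is almost perfectly reproduced by the fitted `W`
despite 60% zeros; the silhouette of 0.43 on the true labels says the
three clusters are well separated in the fitted factor space. `getW(fit)`
is the `n x K` embedding to hand to any downstream clustering; `getMu`,
`getPi`, `getTheta` expose the fitted distribution, and `zinbAIC`/`zinbBIC`
support choosing `K`.

A thin command-line wrapper with `fit`, `simulate`, `evaluate` and
`preprocess` subcommands is installed at `inst/cli/zinbtool.R`:

```sh
Rscript "$(R -e 'cat(system.file("cli/zinbtool.R", package="zinbfactor"))' -s)" \
  simulate --n 500 --genes 200 --zfrac 0.6 --out simdir
```

See `vignettes/zinbfactor-methods.Rmd` for the full model, the estimation
procedure, the simulators' assumptions, and known limitations.

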