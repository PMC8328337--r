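# phlsm — penalized homophily latent space models for directed networks

`phlsm` fits Bayesian latent space models to directed binary networks of
the kind produced by follow-type social platforms and by directed
biological interaction maps: sparse, reciprocal, transitive, and with
power-law in-degrees (a few hubs collect most incoming edges while
out-degrees stay bounded). It is aimed at analysts who want interpretable
node embeddings, per-node popularity estimates, attribute effect estimates
with built-in regularization, and link prediction from one model.

## The model

For an adjacency matrix $Y$ with $y_{ij} = 1$ iff node $i$ follows node
$j$, edges are conditionally independent with

$$\mathrm{logit}\,P(y_{ij}=1) = \beta_0 + \beta' x_{ij} -
  \frac{\lVert z_i - z_j\rVert}{\gamma_j},$$

with latent coordinates $z_i \sim N_2(0, \sigma^2 I)$, pairwise homophily
covariates $x_{ij}$ built from node attributes (absolute log-differences
for continuous attributes, same-category indicators for categorical ones),
and a popularity scale $\gamma_j \in (0,1)$, $\sum_j \gamma_j = 1$, that
divides the distance to the target node — hubs are reachable from far
away. Identification fixes $\beta_0 = 1$. Coefficients get a ridge
(Normal) prior for low-dimensional covariates or an adaptive-LASSO
(Laplace) prior with per-coefficient Gamma-hyperprior tuning for
high-dimensional ones. Inference is Metropolis-Hastings within Gibbs with
a compiled (RcppArmadillo) core; a Gaussian-mixture latent prior handles
clustered networks, with KL-based label-switching cleanup.

The package also ships the benchmark simulator (power-law Dirichlet
popularity, $\sigma^2 = 3\times10^{-4}$), link-prediction /
variable-selection / recovery metrics, and a command-line interface.

## Worked example

Simulate a directed network of 100 nodes with one continuous and one
binary attribute (true effects $\beta = (0.5, -1)$: heterophily on the
first, homophily on the second), fit the ridge model, and evaluate:

```r
library(phlsm)

sim <- simulate_preset("example2", n = 100, seed = 7)
sim$net
#> directed_network: 100 nodes, 829 directed edges (density 0.0837)

fit <- phlsm_fit(sim$net, X = sim$X, penalty = "ridge",
                 config = phlsm_config(burn_in = 2000, monitor = 8000,
                                       thin = 10, seed = 1))
fit
#> phlsm_fit: 100 nodes, 2 covariates, ridge penalty
#>   800 stored draws (burn-in 2000, monitor 8000, thin 10)
#>   acceptance: z 0.31, beta 0.30, gamma 0.89

subset(summary(fit), parameter %in% c("beta1", "beta2", "sigma2"))
#>  parameter      mean       sd     q2.5       q50     q97.5
#>      beta1  0.373014 1.34e-01  0.14323  0.357459  0.605365
#>      beta2 -0.852376 9.57e-02 -1.02838 -0.852025 -0.663615
#>     sigma2  0.000693 9.19e-05  0.00053  0.000685  0.000893

P <- predict(fit)                      # posterior-mean edge probabilities
roc_auc(P, sim$net)$auc                # 0.959
link_metrics(P, sim$net, 0.5)          # TCR 0.931, TPR 0.382, FPR 0.019
recovery_metrics(fit, sim)$spearman_gamma_indeg   # 0.947
```

Reading the output: both credible intervals exclude 0 with the right
signs — the binary attribute is homophilous (negative), the continuous one
heterophilous — and shrinkage plus the modest network size pull the
posterior means toward 0 relative to the truth. The in-sample AUC of 0.96
and the 0.95 rank correlation between estimated popularity scales and
observed in-degrees show that the latent geometry and the popularity
ordering are both recovered; at the default 0.5 cut the classifier is
conservative on such a sparse network (high TCR, low FPR, moderate TPR),
which is why the threshold is exposed.

At benchmark scale the same pipeline uses
`phlsm_config()`'s defaults (15,000 burn-in + 50,000 monitoring
iterations, $M = 5\times10^6$).

## Command line

```sh
Rscript inst/cli/phlsm.R simulate --preset example2 --reps 2 --seed 1 --out sim/
Rscript inst/cli/phlsm.R fit --network sim/rep001_edges.tsv \
    --attrs sim/rep001_attrs.csv --penalty ridge --seed 1 --out run/
Rscript inst/cli/phlsm.R predict --run run/ --network sim/rep001_edges.tsv
Rscript inst/cli/phlsm.R evaluate --run run/ --network sim/rep001_edges.tsv \
    --truth sim/rep001_truth.json
```

`fit` writes gzipped CSV chains, a posterior summary, the log-likelihood
trace and a JSON manifest (seed, input digests, acceptance rates); rerunning
with the same manifest inputs reproduces the chains bit-for-bit.

## Package layout

* `R/netdata.R` — network/attribute containers, readers, covariate
  transforms, degree and link statistics
* `R/model.R` — linear predictor, likelihood, full-conditional kernels,
  mixture membership
* `R/mcmc-*.R`, `src/sampler.cpp` — initialization, block updates,
  Procrustes alignment, the compiled sampler
* `R/simulate.R` — benchmark generator and presets
* `R/evaluate.R` — TCR/TPR/FPR, ROC/AUC, selection and recovery metrics
* `R/cli.R`, `inst/cli/phlsm.R` — command layer
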