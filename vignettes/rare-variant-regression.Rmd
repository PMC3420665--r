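---
title: "Regularized regression tests for rare-variant association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized regression tests for rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Resequencing a gene in a cohort yields tens to hundreds of variant sites,
most of them rare: carried by a handful of individuals. Single-marker tests
have essentially no power at such frequencies, so rare-variant methods test
the gene as a unit. Burden tests collapse rare alleles into one count and
regress the trait on it; variance-component tests (SKAT) look for excess
phenotypic variance among carriers. Both families answer only "is anything
in this gene associated?".

`rvreg` treats the same problem as high-dimensional regression. With
additive genotype codings $g_{ij} \in \{0,1,2\}$ for individual $i$ at
variant $j$ and a continuous trait $y_i$, the working model is

$$ y_i = \mu + \sum_j \beta_j g_{ij} + \varepsilon_i, $$

and the gene-level question becomes: are any $\beta_j$ nonzero — and if
so, which? Five regularization methods handle the $p \approx n$ (or simply
ill-conditioned, heavily collinear) design:

* **Ridge regression (RR)** — $L_2$ shrinkage. Writing the SVD of the
  column-centered design as $X_c = UDV'$, the fitted response is
  $\hat y = \bar y + \sum_m u_m \frac{d_m^2}{d_m^2+\lambda} u_m' y_c$.
  $\lambda = 0$ is ordinary least squares (pseudoinverse limit under rank
  deficiency); the package exposes the presets $\lambda = 0$ and
  $\lambda = 10$, plus arbitrary values.
* **Principal components regression (PCR)** — regression on the top $k$
  left singular vectors: $\hat y = \bar y + \sum_{m \le k} u_m u_m' y_c$.
* **Partial least squares (PLS)** — orthogonal scores built by the NIPALS
  recursion, first weight vector proportional to $X_c' y_c$, with design
  deflation between components;
  $\hat y = \bar y + \sum_{m\le k} z_m z_m' y_c / z_m' z_m$.
* **LASSO** — $L_1$ penalty over a descending 100-value log-spaced path
  from $\lambda_{\max} = \max_j |x_j' y_c|/n$, solved by coordinate
  descent (glmnet); the path position is chosen by an information
  criterion.
* **Sparse PLS (SPLS)** — per component, direction entries with magnitude
  below $\eta \cdot \max_j |w_j|$ are zeroed; the union of survivors is
  refit by PLS, and $(K, \eta)$ is chosen over a two-way grid by the same
  criteria.

For PCR and PLS the component count is either fixed at one (`Comp1`) or
chosen as the smallest $k$ whose response $R^2$ reaches a fraction
$\theta$ of the full-rank $R^2$ (`Compk`). $\theta$ defaults to 0.80: a
conventional "most of the attainable signal" cut, exposed as a parameter
because no canonical value exists.

Model size for the sparse methods is chosen by minimizing
$\mathrm{IC} = n \log(\mathrm{RSS}/n) + c \cdot \mathrm{df}$ with $c = 2$
(AIC), $\log n$ (BIC) or $(\log\log n)(\log p)$ (GIC). The GIC multiplier
is a standard high-dimensional choice among the family of generalized
criteria; it is configurable because several variants circulate. df is the
number of nonzero coefficients (LASSO) or the active-set size (SPLS).
The criteria trade selection against power in the expected way: with only
a handful of carriers per causal variant, BIC and GIC often select the
empty model (statistic 0), while AIC admits more noise variables but
retains the causal ones — AIC is the more useful default when variant
identification matters.

## Pooled rare-variant predictors

To let the regressions borrow strength the way burden tests do, the design
can be augmented with *pooled counts*: for every threshold $t$ in a
lattice consisting of 5% and every observed MAF below 5%, the column
$C_t(i) = \sum_{j: q_j \le t} g_{ij}$ is appended. Membership uses
$q_j \le t$ so each observed-MAF threshold actually changes the pooled
set. Duplicate pooled columns are collapsed (keeping the largest
threshold's label) and a pooled column identical to a single original
column is dropped — the lattice is otherwise exactly collinear, which
destabilizes nothing in theory but wastes conditioning in practice.
Pooled counts are kept raw (not capped or standardized).

## Inference: permutation with selection inside

Every statistic — the fitted-value correlation $\mathrm{cor}(y, \hat y)$
for RR/PCR/PLS, $-\log_{10}$ of the post-selection F-test p-value for
LASSO/SPLS, and the WE/VT/SKAT comparators — is referred to its
permutation distribution: the phenotype is shuffled against the genotype
rows $B$ times and

$$ p = \frac{1 + \#\{b : s_b \ge s_{\mathrm{obs}}\}}{B + 1}. $$

Crucially, *all* selection steps (the IC minimization over the LASSO path,
the $(K,\eta)$ grid search, the `Compk` rule) are repeated inside every
permutation; otherwise the selection optimism of the observed statistic
has no counterpart in the null draws and the test anti-conserves. The
add-one convention guarantees valid p-values with floor $1/(B+1)$; ties
count as extreme. Genotypes are fixed under phenotype permutation, so the
pooled columns and any SVD of the design are computed once. Missing
genotypes are imputed once, from Hardy–Weinberg probabilities at the
observed MAF, before any permutation. An optional sequential early-stop
(quit once 50 exceedances accumulate) is available but off by default.

The comparators are a continuous-trait adaptation of the Madsen–Browning
weighted sum (absolute correlation between $y$ and
$S_i = \sum_j g_{ij}/\sqrt{n q_j (1-q_j)}$ — the original rank-sum form is
case-control only, and no canonical quantitative version exists, so the
correlation form is this package's documented choice), a
variable-threshold burden scan
$\max_t |C_t' y_c| / \lVert C_t \rVert$ over the same threshold lattice,
and the SKAT quadratic form $Q = r' G W^2 G' r$ with Beta(1, 25) MAF
weights (the published default; assessed by permutation like everything
else, so no mixture-of-chi-square approximation is needed).

## The synthetic cohort

No public genotypes accompany the three Sanger-sequenced genes that
motivated the design (1998 individuals; 98, 28 and 122 polymorphic sites
of which 85, 26 and 99 are rare at MAF < 1%), so `simulate_genotypes()`
emulates their marginal structure: rare target MAFs with density
$\propto 1/x$ on $[1/2n, 0.01)$ — the neutral-spectrum-like shape that
makes very rare variants dominate, as they do in sequence data — common
MAFs uniform on $[0.01, 0.5]$, genotypes Binomial(2, MAF), and per-column
redraws until each variant's realized class (polymorphic; rare vs common)
matches the profile. The generator reproduces marginal frequencies only:
no linkage disequilibrium by default (an AR(1) Gaussian-copula option
exists), no haplotype structure, no site-class annotation. Power
estimates on these synthetic genes therefore speak to frequency-driven
behaviour of the tests, not to LD-driven effects in real data.

Phenotype scenarios mirror a two-set, six-scenario design. Baseline trait:
standard normal ($\mu = 0$, $\sigma = 1$; effects are in SD units, so this
is without loss of generality). A fresh causal draw is made for every
dataset from the variants below the scenario's rarity threshold (1% or
0.1%); percentage specifications convert to counts by round-half-to-even
with a minimum of one, and the bidirectional scenario splits $m$ causal
variants into $\lceil m/2 \rceil$ deleterious and the rest protective. In
set I every causal variant shifts carriers by the same $\delta$ (1.64 or
1 SD; the rare/common scenario adds 4 common causal variants at 0.07 SD).
In set II, $\delta_j = c \cdot w(q_j)$ with default $w(q) = 1/\sqrt{q}$
("effect inversely dependent on MAF"; the exact functional form is a
package choice, pluggable via `weight_fn`) and $c$ solved within each
causal group so the *mean* effect equals the set-I target — an exact
identity, tested to $10^{-12}$. A carrier of several causal variants is
shifted by the *rarest* one carried.

## Numerical choices

* Design columns are mean-centered, never variance-scaled by default:
  unit-variance scaling would multiply a singleton variant's column by
  $\sim \sqrt{n}$, and the ridge presets are calibrated on raw counts. A
  `standardize` flag exists.
* SVD rank uses the usual `max(d) * max(dim) * eps` cutoff; $\lambda = 0$
  ridge on rank-deficient designs takes the pseudoinverse limit.
* The LASSO path floor is $10^{-3}\lambda_{\max}$ when $n > p$, else
  $10^{-2}\lambda_{\max}$; glmnet runs at `thresh = 1e-16` so the KKT
  conditions hold to $10^{-8}$ at the selected point (warm starts keep
  this cheap).
* Zero-variance fitted values give statistic 0; an exact fit (RSS = 0)
  maps the F-test p-value to the smallest positive double and raises a
  degeneracy flag; an empty selected set gives $p = 1$, statistic 0.
* A statistic that errors on a permuted dataset contributes $-\infty$
  (never extreme) with a warning, so one pathological permutation cannot
  invalidate a run.
* Ties in `which.min` over the IC path resolve to the largest penalty
  (most parsimonious model).

A deliberate consequence of using the training correlation as the RR/PCR/
PLS statistic: correlation is scale-invariant, so as $\lambda \to \infty$
the ridge statistic tends to $\mathrm{cor}(y, X X' y_c)$, not to 0, even
though $\hat y \to \bar y$; and the statistic is not monotone in
$\lambda$. This is harmless for permutation inference — observed and null
statistics share the scale — but worth knowing when reading raw
statistics.

## Worked example

```{r example}
library(rvreg)

prof <- genotype_profile(n_individuals = 400, n_variants = 30, n_rare = 25)
dat <- simulate_dataset(prof, scenario_config("I.1"), seed = 42)
dat$G
dat$causal

res <- run_test("LASSO", dat$G, dat$y, pooled = TRUE, criterion = "AIC",
                B = 199, seed = 7)
res
res$selected_variants
```

And a small power comparison (desk scale):

```{r power, eval = FALSE}
estimate_power("I.5", genotype_profile(500, 50, 42),
               methods = c("WE", "SKAT", "RR.lambda0", "LASSO.BIC"),
               S = 100, B = 99, seed = 11)
```

## Problem sizes used in the shipped evaluations

The package's own test-suite evaluations and the acceptance script run at
desk scale, chosen as the smallest sizes at which the comparative findings
are resolvable above Monte-Carlo noise: type-I error on a gene-B-like
profile at $n = 500$ with $S = 400$ null datasets ($S = 150$ for the
sparse methods) and $B = 199$ permutations, with calibration bands taken as
the central 99% binomial interval at the $S$ actually used; power
orderings at $n = 500$, $p = 50$ (42 rare), $S = 60{-}120$, $B = 99$; and
the SPLS grid reduced to $K_{\max} = 5$, $\eta \in \{0.1, 0.3, 0.5,
0.7, 0.9\}$ in the harness runs — a grid that reproduced the full default
grid's power estimates at a third of the cost (the full grid stays the
`rvfit()` default).
Full-scale studies ($S = 1000$, $B = 1000$, $n = 1998$) use the same code
paths through `estimate_power()`; at $S = 1000$ the binomial standard
error of any power estimate is at most
$\sqrt{0.25/1000} \approx 1.6\%$.

## Limitations

* Continuous traits only; no covariate adjustment (the fit statistic is a
  global model-fit summary and would need to isolate the genetic
  contribution first).
* One gene/region at a time; no multi-gene or exome-wide modelling.
* Permutation cost scales linearly in $B$; p-values near genome-wide
  thresholds need $B \sim 10^6$, which is feasible for the SVD-based
  methods (statistics are matrix-vector products after a one-off SVD) but
  expensive for LASSO/SPLS, where every permutation re-runs the full
  selection.
* The WE adaptation to continuous traits is non-canonical (see above);
  its permutation null remains exact regardless.
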