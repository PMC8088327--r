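---
title: "Clustering MR ratio estimates with a null-and-junk mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering MR ratio estimates with a null-and-junk mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioclust)
```

## The model and its assumptions

For each genetic variant $j = 1, \dots, J$ used as an instrument, the ratio
(Wald) estimate of the causal effect of the exposure on the outcome is
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, with delta-method standard
error $\hat\sigma_j$. We model the collection $\{\hat\theta_j\}$ as a finite
mixture with $K + 2$ components:

$$p(\hat\theta_j) \;=\; \pi_0\,\phi(\hat\theta_j \mid 0, \hat\sigma_j^2)
  \;+\; \sum_{k=1}^{K} \pi_k\,\phi(\hat\theta_j \mid \theta_k, \hat\sigma_j^2)
  \;+\; \pi_{K+1}\,T(\hat\theta_j),$$

where $\phi(\cdot \mid m, v)$ is the normal density and $T$ is a
location–scale Student-$t$. Three modelling commitments matter:

1. **Observation-specific variances.** Each variant's component variance is
   its own squared standard error, treated as known. A precise variant close
   to a cluster mean is strong evidence for that cluster; an imprecise one is
   weak evidence for anything. There are no per-cluster variance parameters:
   a cluster is a set of estimates that agree *relative to their own
   uncertainties*, not a region of similar values.
2. **A null cluster fixed at zero.** Variants compatible with no effect are
   absorbed at $\theta_0 = 0$ and cannot drag a substantive cluster toward
   the null or seed one of their own.
3. **A junk cluster.** The $t_4$ component has location $\mu$ equal to the
   sample mean of the ratio estimates and scale
   $\psi = |\hat\theta_{\max} - \hat\theta_{\min}| + 2\hat\sigma_{\max}$ —
   wide enough to cover the whole observed range. It gives isolated outliers
   somewhere to live, so joining a substantive cluster requires beating a
   fixed heavy-tailed alternative. $\mu$, $\psi$ and $\nu$ are computed once
   from the data and never re-estimated.

The substance of the method assumes the input summary statistics are
harmonized to a consistent effect allele, that ratio estimates from valid
instruments sharing a mechanism converge to a common causal parameter
(linearity/homogeneity), and that the reported standard errors are correct —
uncertainty in the standard errors themselves is ignored.

Fitting is by EM. The E-step computes responsibilities
$r_{jk} \propto \pi_k \cdot (\text{component density at } \hat\theta_j)$;
the M-step updates each substantive mean as a responsibility-weighted
inverse-variance-weighted (IVW) average,
$\theta_k \leftarrow \sum_j r_{jk}\hat\theta_j\hat\sigma_j^{-2} /
\sum_j r_{jk}\hat\sigma_j^{-2}$, and each proportion as the mean
responsibility. In the small-$\hat\sigma$ limit the fitted means are exactly
the per-group IVW estimates (this is asserted to $10^{-6}$ in the tests).
The number of substantive clusters is chosen by minimizing
$\mathrm{BIC}(K) = (2K+1)\log J - 2\,\ell$, counting the $K$ free means and
$K+1$ free proportions; the junk parameters are data-determined constants,
not free parameters.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `se_order` | `"first"` | ratio SE formula. First order ($se_Y/|\beta_X|$) is always defined; the second-order form adds exposure-side noise and a correlation term and is opt-in. |
| `rho` | 0 | correlation of the exposure and outcome association estimates; 0 in a two-sample design. If second-order SEs are used with overlapping samples, a sensitivity analysis over `rho` is advisable. |
| `nu` | 4 | junk-component degrees of freedom; heavy-tailed but with finite variance. |
| `delta` | `1e-5` | EM stops when the log-likelihood increment falls below this; small enough that BIC comparisons (order-1 differences) are unaffected. |
| `max_iter` | 500 | iteration cap per start; overlapping-component fits converge slowly but harmlessly. |
| `n_starts` | 25 | random initializations per $K$; EM on these likelihoods has genuine local optima (different starts reach different values), and 25 starts makes the best-of selection stable across seeds. |
| `k_max`, `patience` | `min(J, 10)`, 2 | the scan stops after `patience` consecutive BIC increases — a concrete reading of "stop once BIC is increasing monotonically". Patience 1 would be fooled by a single under-optimized fit. |
| `prob_threshold` | 0.8 | version-B assignment threshold (inclusive: exactly 0.8 assigns). |
| `min_cluster_size` | 4 | version-B minimum reported cluster size. Both thresholds are conventional rather than derived; they trade sensitivity for protection against clusters evidenced by a few variants. |

## The synthetic-data generator

`simulate_summary_data()` emulates GWAS regression coefficients of a
unit-variance trait on a biallelic SNP: per variant,
$MAF \sim U(0.05, 0.5)$, true exposure effect $\mu_{\beta X} \sim N(0,1)$,
sampling variance $v = 1/(N\,MAF(1-MAF))$,
$\hat\beta_X \sim N(\mu_{\beta X}, v)$ and
$\hat\beta_Y \sim N(\theta_j \hat\beta_X, \tau v)$, with *reported* standard
errors $\sqrt{v}$ for both traits. The overdispersion factor $\tau$ is
deliberately excluded from the reported SEs: with $\tau > 1$ every z-score is
inflated by $\sqrt\tau$, emulating unmodeled heterogeneity. Four presets are
provided: 90 null variants with $\tau = 1$ or $2$ (scenarios 1/2), and a
three-cluster composition (effects 0.4/−0.4/0.8 carried by 10/20/40 variants,
plus 10 null and 10 junk variants with $\theta_j \sim N(0,1)$) with
$\tau = 1$ or $2$ (scenarios 3/4).

What the generator does **not** emulate: linkage disequilibrium between
instruments (variants are independent), winner's-curse selection of
instruments, allele-frequency–effect-size coupling, sample overlap between
exposure and outcome GWAS, and binary outcomes. A green simulation test
therefore establishes that the estimator recovers the generative mixture
under idealized two-sample conditions, not that it is robust to those
real-data complications. Because $\mu_{\beta X}$ is standard normal, some
simulated instruments are very weak; their ratio estimates and SEs are
huge, which stress-tests the junk component (it widens $\psi$ dramatically)
— a realistic nuisance that applied analyses usually avoid by selecting
genome-wide-significant instruments.

## Numerical choices

- All densities are evaluated in log space; mixture sums use a per-row
  log-sum-exp. An all-components-underflow row raises an error rather than
  returning `NaN` responsibilities.
- k-means initialization uses ++-style seeding followed by Lloyd iterations,
  unweighted on $\hat\theta$ (initialization deliberately ignores the
  uncertainties; EM immediately reweights). $K = 1$ is special-cased to the
  grand mean, which is the exact single-center Lloyd fixed point.
- Empty-cluster guard: if a substantive cluster's total responsibility falls
  below $10^{-3}$ its mean is held at the previous value for that iteration
  (the IVW update would be 0/0); persistent emptiness is flagged on the fit.
- Convergence is declared when the log-likelihood increment drops below
  `delta`; the returned parameters, responsibilities and log-likelihood all
  refer to the same iteration, so the stored likelihood equals a fresh
  evaluation at the returned parameters.
- Cluster labels are canonicalized by sorting means ascending (responsibility
  columns and proportions permuted to match); argmax assignment breaks ties
  toward the lower column index, i.e. null first.
- All randomness (initialization, multistart, simulation replicates) derives
  sub-seeds from a single master seed, making every result bit-reproducible.
- Version-B dissolution of under-sized clusters is applied once, not
  iterated: dissolving a cluster never re-opens the threshold decision for
  other variants.

## Open design decisions

- **Junk-$t$ parameterization.** "Scale $\psi$" is read as the
  location–scale $t$ scale: density $\psi^{-1} t_\nu((x-\mu)/\psi)$. The
  alternative covariance-like reading ($\sqrt\psi$ as scale) was evaluated
  and changes benchmark behavior only marginally; the plain-scale reading
  matches the parameter's data-units construction from the range.
- **BIC parameter count.** Exactly $2K+1$ free parameters. One could argue
  the junk location/scale should count; they are deterministic functions of
  the data, identical across all $K$, so they shift every BIC equally.
- **Cluster-mean standard errors.** Reported as the responsibility-weighted
  IVW standard error $\sqrt{1/\sum_j r_{jk}\hat\sigma_j^{-2}}$ — the
  uncertainty the M-step estimator itself implies. This is an artifact
  convention: it ignores uncertainty in the responsibilities.
- **Enrichment tail.** The hypergeometric independence test is one-sided
  (upper tail, $P(X \ge \text{observed})$) by default, matching the
  enrichment question "are in-cluster variants over-represented among
  associated variants?"; a two-sided option exists. P-values are raw — with
  thousands of overlapping traits no principled multiplicity correction is
  attempted (an optional Benjamini–Hochberg column is available).
- **Rand-index contribution rules.** True junk variants are excluded from
  the Rand index (methods without a junk concept cannot be penalized for
  them), and under version B unassigned variants are excluded from the pair
  count.

## Known limitations

- **Unmodeled overdispersion produces genuine tail clusters.** When every
  z-score is inflated (the $\tau = 2$ null scenario), groups of 4–7
  moderate-tail variants ($|z| \approx 2$–4) form real likelihood clusters:
  the BIC margin favoring $K \ge 1$ in such datasets is typically 3–25
  units, so this is a property of exact maximum likelihood under the model,
  not an optimization artifact. Conservative (version-B) reporting reduces
  the rate of reported spurious clusters to roughly one dataset in five in
  our 200-replicate benchmark — far better than greedy assignment (about one
  in two), but not negligible. Users who suspect systematic overdispersion
  should treat small reported clusters with particular suspicion.
- The method clusters on a single exposure–outcome pair; it cannot by itself
  distinguish distinct causal pathways from pleiotropy, and cluster
  membership should be validated against external trait associations (the
  `scan_traits()` workflow).
- Standard errors are treated as known; very weak instruments violate the
  normal approximation for the ratio estimate itself (the delta-method SE
  describes the core spread, not the heavy tails).
- The EM likelihood surface is multimodal; 25 starts makes selection stable
  in the benchmarks, but convergence to different optima across starts is
  real and worth checking (`start_log_likelihoods` on the fit).
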