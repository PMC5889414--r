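---
title: "Estimating and judging relative binding free energies with relfep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and judging relative binding free energies with relfep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relfep)
```

## The problem

Alchemical free-energy perturbation (FEP) computes the change in binding
affinity caused by a chemical modification of a ligand. Because the two
end states rarely overlap in phase space, the transformation is split
into a ladder of mixed states $V(\lambda) = (1-\lambda)V_0 + \lambda
V_1$; each state is sampled by molecular dynamics, and the free-energy
differences along the ladder are estimated from the samples. Carrying
the same transformation out with the ligand bound to the protein and
free in solution closes a thermodynamic cycle:
$\Delta\Delta G_\mathrm{bind} = \Delta G_\mathrm{protein} - \Delta
G_\mathrm{water}$.

`relfep` implements everything downstream of the sampling: estimation,
uncertainty, per-window reliability screening, and the statistical
comparison of calculated with experimental affinities. The molecular
dynamics itself — force fields, soft-core potentials, topologies — is out
of scope; the package consumes reduced potentials $u_{kn}$ (energies in
units of $kT$, every sample evaluated in every state) in a plain TSV
format.

All user-facing free energies are in kJ/mol; everything inside the
estimators is dimensionless. The conversion uses $kT = RT$ with
$R = 8.31446\,\mathrm{J/(mol\,K)}$, so the default 300 K gives
$kT = 2.4943$ kJ/mol.

## The MBAR estimator

`mbar()` solves the multistate Bennett acceptance ratio equations

$$ f_i \;=\; -\log \sum_{n=1}^{N} \frac{\exp(-u_{in})}
       {\sum_k N_k \exp(f_k - u_{kn})}, \qquad f_1 = 0, $$

the statistically optimal pooling of all samples from all states. Two
properties pin the solution down and are asserted in the test suite:
adding a constant to row $k$ of $u$ shifts $f_k$ by exactly that
constant, and reversing the state order negates the end-to-end
difference.

Numerical choices:

* **Solver.** Self-consistent iteration, fully log-sum-exp stabilised,
  with a quasi-Newton (BFGS) rescue on the equivalent convex objective
  if the fixed point has not converged after 200 sweeps; relative
  tolerance $10^{-10}$ on $f$, at most $10^4$ sweeps, then an error
  carrying the last residual. The iteration runs in compiled code. A
  fast path precomputes $\exp(-u)$ once with a per-sample shift (taken
  over the sampled states) that cancels exactly between numerator and
  denominator, making each sweep pure multiply–add; whenever an
  intermediate loses finiteness — conceivable only for extreme
  potentials — the solver transparently reruns in the log domain. Both
  kernels agree to machine precision on ordinary inputs and both are
  exercised by the tests.
* **Degenerate inputs.** At least two states must carry samples;
  all entries of $u$ must be finite; identical states yield
  $f = 0$ exactly.
* **Uncertainties.** A stratified bootstrap: samples are redrawn with
  replacement *within* each sampling state, preserving the per-state
  counts $N_k$, and the anchored $f$ vector is re-solved per resample
  (warm-started from the point estimate). The default is 100 resamples.
  Samples are treated as uncorrelated — appropriate after subsampling a
  trajectory beyond its correlation time — and no statistical-
  inefficiency correction is attempted. The bootstrap can equally be
  applied per window; window-wise standard errors combine in quadrature
  ($\mathrm{SE} = \sqrt{\sum_i \mathrm{SE}_i^2}$, `se_quadrature()`),
  the same rule used when combining the two legs of the cycle. Whether
  uncertainty is best bootstrapped end-to-end or per window is genuinely
  open; both are provided, and the end-to-end form is the default
  because it needs no independence assumption between windows.

`bar()` (Bennett's two-state estimator, solved independently as a root
find on the Fermi-function balance) and `exponential_average()` (the
Zwanzig estimator $-\log\langle e^{-w}\rangle$) serve as cross-checks:
at $K = 2$, BAR and MBAR agree to better than $10^{-6}\,kT$ on identical
samples, and on well-overlapping Gaussian work distributions all
estimators agree within combined noise.

## Overlap diagnostics

A window's estimate is only as good as the overlap between the
perturbation-energy distributions of its two states. `assess_windows()`
computes, per adjacent window and in both directions, five measures:

| measure | form | warn when |
|---|---|---|
| $\Omega$ | $\sqrt{2\sigma_A\sigma_B/(\sigma_A^2+\sigma_B^2)}\,e^{-(\mu_A-\mu_B)^2/4(\sigma_A^2+\sigma_B^2)}$ | $\le 0.1$ |
| $K_{AB}$ | $\int 2 p_A p_B/(p_A+p_B)\,dx$ (adaptive quadrature) | $\le 0.1$ |
| $\Pi$ | $\sqrt{2\ln n} - \sigma_w$, reported as $\min(\Pi_f, \Pi_r)$ | $\le 0.4$ |
| $w_\mathrm{max}$ | $\max_n e^{-w_n}/\sum_m e^{-w_m}$ | $\ge 0.5$ |
| $\Delta\Delta G_{EA}$ | forward minus backward exponential-average estimate, kJ/mol | $|\cdot| \ge 4$ |

$\Omega$ and $K_{AB}$ are evaluated under a Gaussian approximation of
the two distributions. The literature defines these measures through
their integrals without a canonical closed form, so the forms above are
adopted as the implemented definitions and validated in the test suite
against dense numerical integration of the defining integrals (to
$10^{-4}$ across a sweep of mean gaps and width ratios) rather than
against any external implementation. The $\Pi > 0.4$ criterion is the
accepted safety threshold; the $w_\mathrm{max}$ threshold of 0.5 is
chosen because a weight of 0.7 is the canonical example of a
single-sample-dominated, still-usable-but-suspect window. All
thresholds are configurable and echoed into the report, and flags are
raised exactly when a threshold is violated.

## Quality measures against experiment

`evaluate_affinities()` compares a rectangular table of calculated
$\Delta\Delta G$ (transformations × method variants) with an
experimental table:

* **Deviation statistics** on $d_i = \mathrm{calc}_i -
  \mathrm{exp}_i$: MAD, MSD (positive = calculations overestimate; the
  sign convention is validated against the benchmark tables), RMSD,
  maximum error. $\mathrm{MAD} \le \mathrm{RMSD} \le \mathrm{Max}$ and
  $|\mathrm{MSD}| \le \mathrm{MAD}$ on every input.
* **Direction-symmetric $R^2$.** The sign of each transformation is an
  arbitrary choice of direction, so the correlation is computed over
  every pair in both directions; the doubled point set has zero means
  and the statistic reduces to $(\sum x_i y_i)^2 / (\sum x_i^2 \sum
  y_i^2)$, invariant under flipping any transformation on both axes.
* **Sign concordance** $\tau_r$: concordant if calculated and
  experimental values share a sign, discordant otherwise, computed only
  over the transformations actually studied. A value that is exactly
  zero on either axis is excluded from both numerator and denominator —
  the unique simple tie rule consistent with all published benchmark
  values (the experimental 0.0 for NHMe→OMe is the only tie in the
  shipped data). $\tau_{r,90}$ additionally requires
  $|\mathrm{value}| \ge 1.645\,\mathrm{SE}$ on *both* axes; a
  measurement with no reported SE is taken at face value and always
  passes (represented as `NA`, never as zero — the distinction
  matters).
* **Uncertainties by parametric simulation.** Every metric is
  recomputed on `n_rep = 1000` synthetic data sets with each value
  resampled from $\mathcal N(\mathrm{value}, \mathrm{SE})$, and the
  *standard deviation* across replicates is reported. (Dividing by
  $\sqrt{n_\mathrm{rep}}$ instead would shrink the figure toward zero
  as replicates are added; the replicate spread is the quantity that
  matches the scale of published uncertainties.) A replicate in which a
  metric is undefined — a $\tau_{r,90}$ with no survivors — is recorded
  as missing, and more than 10% missing is an error rather than a
  silently biased answer.
* **Consensus.** `consensus()` averages the method variants per
  transformation with $\mathrm{SE} = \mathrm{sd}/\sqrt{M}$; because the
  variants differ by deliberate methodological choices (charge
  derivation, perturbed-group size), this SE measures sensitivity to
  the method, complementing the statistical errors.
  `variant_difference_test()` provides the two-sided z-test for
  pairwise variant comparisons; it is exposed but no specific
  significance count is asserted, since such counts are sensitive to
  the rounding of published inputs.

The galectin-3 benchmark (seven transformations, six variants, 42
cells) ships in `inst/extdata/` and the acceptance tests verify that
every published quality row is reproduced from the printed columns —
deviation statistics within ±0.15 kJ/mol (the inputs are rounded to
0.1), $R^2$ within ±0.02, both rank correlations exactly.

## Synthetic data and what the tests do (and do not) show

The generators exist so that every stage can be tested against known
truth without any molecular input:

* `generate_harmonic_leg()` mixes two 1-D harmonic endpoint potentials
  with the same $\lambda$ rule as a real leg. The mixture is again
  harmonic, every state is sampled *exactly* (a Gaussian), and the
  end-to-end free energy is analytic: $\tfrac12\ln(k_1/k_0) + (a_1 -
  a_0)$, independent of the centres. Constant endpoint offsets dial in
  an arbitrary target free energy without changing the overlap
  structure.
* `generate_gaussian_work()` draws the unique Gaussian forward/reverse
  work pair consistent with the Crooks relation (means $\pm\Delta G +
  \sigma^2/2$), so $\langle w_f\rangle + \langle w_r\rangle = \sigma^2$
  and both directions estimate the same free energy.
* `emulate_study()` reproduces the *structure* of the benchmark study:
  seven transformations × six variants, truth defaulting to the
  experimental galectin-3 affinities (realistic magnitudes), a per-cell
  systematic bias (sd 1.5 kJ/mol, drawn once per cell, mirroring the
  observed 1–2 kJ/mol spread between method variants) plus statistical
  noise (sd 0.5 kJ/mol, typical of the published per-cell standard
  errors), 13 $\lambda$ states and 500 samples per state — the number a
  5 ns production run sampled every 10 ps provides. The protein/water
  split of the truth defaults to placing the whole effect in the
  protein leg; the split is configurable and does not affect the
  combined cycle.

Passing these tests demonstrates that the estimators and statistics are
*correct*: exact Boltzmann samples of an exactly solvable model are
recovered within stated uncertainties, and the full
simulate → estimate → evaluate chain returns injected truth within 3 SE
in ≥ 95% of cells. It does **not** demonstrate robustness to what real
trajectories add: autocorrelation, slow conformational degrees of
freedom, force-field error, or non-Gaussian work tails. The overlap
diagnostics exist precisely because real legs can fail in ways the
harmonic fixtures cannot.

Problem sizes in the test suite are chosen to keep the full run in a
few minutes on one core: the estimator-correctness checks use the full
13 × 500-sample geometry with 40 bootstrap resamples over 20 seeds,
while the end-to-end recovery study uses 100 samples per $\lambda$ and
20 bootstrap resamples per leg over 20 regenerations of all 42 cells —
at those sizes the 3-SE criterion is if anything *harder* to meet, since
standard errors are larger and estimated more noisily.

## Reproducibility

Every stochastic routine takes an explicit seed and applies it locally
(the caller's RNG state is untouched). The pipeline derives per-stage,
per-file child seeds from one global seed by a counter-based rule
(`derive_seed()`), so stages can be rerun independently; identical
configuration and seed give byte-identical reports, and every report
embeds its full effective configuration as header lines.

## Known limitations

* No trajectory handling: equilibration detection, autocorrelation
  analysis and statistical-inefficiency subsampling must happen before
  the u_kn matrices are written.
* The Gaussian approximation behind $\Omega$, $K_{AB}$ and $\Pi$ can
  flatter strongly non-Gaussian perturbation-energy distributions; the
  sample-based measures ($w_\mathrm{max}$, $\Delta\Delta G_{EA}$)
  partially compensate.
* $\tau_r$ is computed only over the studied transformations, never
  over the pairwise network they span, and no cycle-closure analysis is
  performed.
* The consensus treats all variants as exchangeable; it has no notion
  of one variant being a priori more trustworthy.
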