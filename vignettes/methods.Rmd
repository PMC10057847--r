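---
title: "Methods: models, estimators and design choices in sensortune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in sensortune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sensortune` engineers protein-based genetic sensors against quantitative
dose-response specifications. This vignette documents the models it
fits, the assumptions behind them, the tunable parameters, and the
design decisions taken where the problem left the design genuinely open.

## The Hill model and its Bayesian estimator

A sensor's dose-response is summarised by the Hill equation
`G(L) = G0 + (Ginf − G0)/(1 + (EC50/L)^n)` with basal output `G0` (MEF),
saturating output `Ginf` (MEF), switching concentration `EC50` (µmol/L)
and steepness `n`. `L = 0` is always handled as the analytic limit `G0`;
the power form is never evaluated at zero ligand (internally the
algebraically identical form `G0 + (Ginf−G0)·L^n/(L^n+EC50^n)` is used,
which is exact at `L = 0`). A variant is *inverted* when `Ginf < G0`.
Non-monotonic ("band-stop") dose-response shapes are outside the model
class and out of scope.

`fit_hill()` assumes multiplicative measurement noise, which is what
bead-calibrated cytometry geometric means show in practice: the log of
each observed geometric mean is normal around the log of the Hill curve
with per-point scale `max(geo_mean_err/geo_mean, 0.02)`. The 2 % floor
prevents a single over-confident point from dominating a 12-point curve.
Priors are weakly informative and deliberately span every phenotype
class seen in large LacI landscapes:

* `log10 G0`, `log10 Ginf`: normal, centred on the data's own low/high
  ends, SD 1.5 decades;
* `log10 EC50`: uniform on [−1, 4] (0.1 to 10⁴ µmol/L);
* `n`: normal(1.5, 1) truncated to (0, 6].

Sampling uses four MCMC chains (JAGS), 500 adaptation + 500 burn-in +
1000 retained iterations per chain, seeded deterministically from the
user's seed. Convergence is declared when every parameter's potential
scale reduction factor is ≤ 1.05; otherwise the fit is returned with
`converged = FALSE` and a warning, never silently. Posterior summaries
follow the landscape-file convention: base-10 logs for the level
parameters and EC50, linear `n`, and they are always recomputed from the
stored draws.

For flat curves the model is intentionally honest about
unidentifiability: `G0` is recovered tightly, `EC50` reverts to its
prior, and `Ginf` is constrained only by the data-centred prior because
a curve that has not begun to switch carries no information about its
ceiling.

Replicate curation uses the 1.25-fold rule: a replicate is dropped when
its `Ginf` estimate is more than 1.25-fold from the consensus. Two
choices were open. First, the consensus: we use the geometric median of
the replicate values and iterate drop-and-recompute to a fixed point,
which makes the filter robust to several outliers and exactly
idempotent (a property the test suite asserts); at least one replicate
is always kept. Second, which `Ginf` enters the rule: fitted values or
raw high-ligand signal. The command-line `fit` pipeline uses the
geometric mean of the readings at the two highest ligand levels as a
cheap, fit-free proxy, which is adequate because the rule only gates
replicates at a coarse 1.25-fold resolution.

## In silico selection

A specification is a set of bands: `EC50` within a fold band of a
target, `Ginf` within a fold band or below a ceiling, `G0` inside an
interval, and optionally a phenotype class (normal/inverted). The two
presets bundle the standard criteria: multi-objective
(1.2-fold EC50, 1.1-fold Ginf, G0 < 2 kMEF) and inverted
(1.5-fold EC50, Ginf < 12.5 kMEF, 19.2 < G0 < 32.5 kMEF, inverted
class).

`success_probability()` is deliberately simple: the fraction of a
variant's posterior draws that satisfy *every* active criterion
jointly. `select_variants()` pre-filters candidates on posterior
medians (cheap), ranks by the joint probability, and truncates at
`top_k` with a `min_prob` floor. Ties break toward fewer mutations,
then lexicographic genotype — simpler constructs first, and the output
is deterministic.

The EC50 systematic-error correction is an unweighted OLS fit of
`ln(measured)` on `ln(dataset)`. Two open choices were resolved as
follows. The correction is applied to *each posterior draw's* EC50, not
only to the median, so that band membership and the reported
probability stay coherent (correcting only the point estimate would let
a variant pass the median filter while its probability was computed on
the uncorrected scale). And the ranking probability includes *all*
criteria of the preset, including the G0 bound; where the G0 criterion
is trivially satisfied this reduces to ranking on EC50/Ginf alone, so
nothing is lost, and the multi-objective semantics stay uniform.

## The latent genotype-phenotype model

Genotypes are one-hot encoded over the mutation vocabulary
(`p` columns; the wild type is the zero vector). The model is a
low-dimensional linear embedding `z = W x` (`K = 3` by default;
configurable) composed with a smooth surface per phenotype. Additivity
of mutation effects in latent space is structural: the embedding of a
multi-mutant is exactly the sum of its mutations' columns of `W`.

Fitting proceeds in three stages:

1. *Linear stage.* Ridge-stabilised multivariate least squares of the
   phenotype matrix on the one-hot encoding; the SVD of the coefficient
   matrix gives up to `min(D, K)` leading latent directions, and
   per-effect standard errors propagate from the OLS coefficient
   covariance (delta method). When `K` exceeds the linear rank, further
   directions are pulled from the residuals of a smooth fit on the
   directions found so far.
2. *Gauss-Newton refinement* (3 damped iterations by default). The
   surfaces are linearised around the current coordinates and the full
   embedding is updated by a ridge-regularised least-squares step with
   step-halving on the joint training loss, re-fitting the surfaces
   after every accepted step. This substantially sharpens the recovered
   latent span relative to the linear initialisation.
3. *Final surfaces.* Latent coordinates are scaled to unit variance,
   dimensions ordered by their knockout contribution to explained
   variance, and tensor-product spline surfaces (thin-plate for
   `K = 1`) fitted by `mgcv` — for large n via `bam(discrete = TRUE)`.
   The surfaces expose a coefficient posterior (`Vp`), which is what
   makes the model's predictions *samplable*.

Phenotypes are modelled on base-10 log scales. `fit_latent_landscape()`
models three phenotypes — `log10 EC50`, `log10 Ginf` and `log10 G0` —
even though engineering targets usually concern the first two: the
basal output gives the linear stage a third independent constraint on
the latent span, which materially improves the recovered embedding
(with only EC50 and Ginf the linear stage has rank 2 and the third
dimension must come entirely from residuals). Independent surfaces per
phenotype are assumed; nothing couples them except the shared
embedding.

Inverted variants are excluded from training by default: in
prescreen-shaped landscapes they are rare and carry strongly inflated
uncertainty, and including their noisy phenotypes degrades the fit.
This mirrors the practical observation that such models fail to learn
the inverted minority class.

Prediction embeds the query genotype, clamps each coordinate to the
training range (spline extrapolation beyond the data is meaningless),
draws `n_draws = 50` coefficient vectors from the surface posterior and
adds residual noise, and summarises mean and SD. `n_draws = 1` is
flagged degenerate (SD 0). The per-mutation significance flag in
`latent_effects_report()` is `|effect| > 2 SE`; `propose_improvement_mutations()`
filters and ranks by signed effect on a chosen dimension — the
forward-engineering step that pairs a latent dimension with a
biophysical hypothesis.

## The MWC allostery model

The biophysical map is the standard thermodynamic induction model of a
two-state allosteric repressor with two ligand-binding sites:
`fold_change(c) = [1 + p_act(c)·(R/N_NS)·e^(−Δε_RA)]^(−1)` with
`p_act(c) = (1+c/K_A)² / [(1+c/K_A)² + e^(−Δε_AI)(1+c/K_I)²]`. The
dose-response is `G(c) = G_max · fold_change(c)`. Downstream code
treats the map from biophysical parameters to Hill parameters as a
black box, so an alternative form can be swapped in.

`R` (repressor copy number) and `N_NS` (nonspecific background sites)
are not identifiable from dose-response shape alone and act as anchors:
defaults (`R = 208`, `N_NS = 4.6e6`, `Δε_RA = −15.3 kT`,
`Δε_AI = 4.5 kT`, `K_A = 139`, `K_I = 0.53` µmol/L) are
literature-like LacI values with `G_max = 31520` MEF calibrated once so
the wild-type anchor sits at the canonical LacI operating point
(basal output ≈ 158 MEF, ceiling ≈ 25 kMEF, EC50 ≈ 95 µmol/L).

`biophys_to_hill()` computes `G0` and `Ginf` in closed form, checks
monotonicity numerically (the MWC form is monotone in `c`, but the
check guards any swapped-in alternative), finds `EC50` by bisection on
`log c` over [10⁻³, 10⁶] µmol/L to relative tolerance 10⁻⁶, and takes
`n` from the log-slope at the midpoint (`dG/dlnL = (Ginf−G0)·n/4` for a
Hill curve). A flat curve (`K_A = K_I`) has no EC50 and raises an
error. In the inverted regime (`K_A < K_I`, destabilised active state)
decreasing `K_A` lowers both EC50 and Ginf — the mechanism the
forward-engineering workflow exploits; the latent-dimension ↔
biophysical-parameter correspondence is exposed as a user-asserted
hypothesis, not a learned mapping.

## What the synthetic generator emulates — and what it does not

The generator exists so that every method is testable without the real
dataset. It emulates, with defaults fixed once:

* library structure: Poisson missense counts, mean 4.4; a shared
  150-mutation vocabulary at distinct positions in a LacI-like core
  domain (the real data's multiple substitutions per position and
  silent mutations are not represented);
* effect structure: per-mutation latent vectors, additive in latent
  space, sparse and heavy-tailed (half the mutations near-neutral with
  SD 0.05, the rest t₃-tailed with scale 0.6, as in deep mutational
  scans); 5 % strongly deleterious (large operator-binding shifts →
  constitutively high basal output) and 3 % inversion-prone (large
  `K_A` decreases plus active-state destabilisation);
* the map from summed latent effects through the MWC model to true Hill
  parameters (dimension 1 → `Δε_AI`, dimension 2 → `−log K_A`,
  dimension 3 → `Δε_RA`), which produces an EC50 span of more than
  three decades, a dense non-inverted mode near the wild type and a
  sparse inverted tail;
* measurement: posterior draws centred on the truth with base widths of
  0.05/0.03/0.06 decades (`log G0`/`log Ginf`/`log EC50`) and 0.08 on
  `n`, inflated as `quality^(−1/2)`;
* the FACS prescreen: logistic retention in `log G0` (midpoint 3 kMEF,
  width 0.5 decades), with surviving high-basal records keeping
  proportionally reduced quality. This reproduces the real dataset's
  rare-and-noisy inverted tail without hard truncation;
* raw curves: the 12-point inducer grid (zero plus an 11-step two-fold
  dilution from 2048 µmol/L) with 5 % lognormal noise per point.

It does **not** emulate barcode counting, sequencing error, replicate
batch structure, epistasis beyond what the latent-additive + nonlinear-map
composition induces, or the real data's joint distribution of parameter
uncertainties (only the quality-inflation schedule above, which is a
free modelling choice). Passing tests on this generator therefore shows
that the estimators recover the structure they assume, at realistic
noise and sparsity — not that the assumptions hold for any particular
real landscape.

In selection benchmarks, "measured" validation values are simulated
from the generator truth with replicate-level geometric SDs of
1.16-fold (EC50) and 1.11-fold (Ginf) — wild-type replicate variability
as the measurement model.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty landscapes select to an
empty result with a warning; contradictory specifications return empty;
fewer than two ligand levels refuse to fit; a flat biophysical curve
refuses a Hill conversion. Probability ties in ranking are broken
deterministically. All ratio metrics use natural logs internally
(`fold_accuracy` is symmetric and scale-invariant); file outputs use
base-10 logs for compatibility with landscape tables.

The benchmark harness (`benchmark_*` functions, used by both the test
suite and `scripts/acceptance.R`) runs at the package's chosen study
sizes: 50 twelve-point curves for parameter-recovery coverage; twenty
10⁴-variant landscapes (three planted in-spec variants each) for the
selection ranking rate, with measured-versus-target accuracy pooled
over the specification grid on three landscapes; 10⁴ training / 1.5·10³
held-out variants for the latent model; a 12-point `K_A` grid for the
inverted mechanism. Seeds propagate from a single user seed, and every
stochastic function is deterministic given its seed.

## Known limitations

* The Hill posterior width depends on the (unknown) real fitting
  configuration; matching any particular pipeline's posterior widths
  exactly is not guaranteed, only calibrated coverage under the model's
  own noise assumptions.
* Near-duplicate genotypes at the DNA level are indistinguishable at
  the protein-code level; callers who need DNA-level de-duplication
  must handle it upstream.
* The latent model does not learn inverted variants (excluded from
  training) and clamps extrapolation; predictions for genotypes far
  outside the training latent range are conservative, not accurate.
* Biophysical parameters are not *fitted* to landscapes here; the MWC
  module maps parameters forward only.
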