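---
title: "Modeling the coral surface-mucus-layer microbiome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the coral surface-mucus-layer microbiome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralsml)
```

## The model

The surface mucus layer (SML) of a coral colony hosts a dense microbial
community whose composition tracks the local thermal environment. `coralsml`
describes that community with a system of coupled logistic differential
equations. Each taxon $i$ (in practice a bacterial or archaeal class) has
abundance $B_i(t)$ and obeys

$$\frac{dB_i}{dt} \;=\; R_i(T(t))\; B_i\,
  \Bigl(1 - \frac{\sum_j B_j}{k}\Bigr)
  \Bigl(1 + \sum_j \eta_{ij} B_j\Bigr),$$

with three ingredients:

* **A Gaussian thermal-performance curve.** The realized growth rate is
  $R_i(T) = r_{\max,i}\,\frac{1}{\sqrt{2\pi\sigma_i^2}}
  e^{-(T-\mu_i)^2/2\sigma_i^2}$, where $\mu_i$ (°C) is the mean ideal growth
  temperature, $\sigma_i$ (°C) its range, and $r_{\max,i}$ (day⁻¹) a
  per-taxon scale. Note a subtlety the interface makes explicit: because the
  curve is a scaled Gaussian *density*, the peak rate attained at $T = \mu$
  is $r_{\max}/(\sigma\sqrt{2\pi})$, not $r_{\max}$ — the curve instead
  *integrates* to $r_{\max}$ over all temperatures. We implement this density
  form as the default because it is the equation as printed in the
  literature this package follows; users who intend $r_{\max}$ as the
  literal peak rate can pass `response = "peak"`, which drops the
  normalization so that $R(\mu) = r_{\max}$. Growth-parameter tables are
  expressed per day.

* **Sinusoidal seasonal forcing.** $T(t) = M + A\sin(\omega t + \theta)$
  with mean $M$ (°C), amplitude $A$ (°C), and $\omega = 2\pi/365$ rad/day
  (one annual cycle). The phase $\theta$ has no published value; our
  convention derives it from the calendar day of the annual minimum
  (`day_of_min = 45`, mid-February, consistent with winter minima in
  subtropical reef systems), and both a raw `theta` and the day convention
  are accepted. With $A = 0$ the profile is constant at $M$ — the "constant
  temperature" scenarios.

* **Community coupling.** All taxa compete identically for a shared
  carrying capacity $k$ (the competition bracket vanishes when total
  abundance reaches $k$), and the interaction bracket modulates each taxon's
  net growth through co-occurrence coefficients $\eta_{ij}$ inferred from
  data (below). The diagonal $\eta_{ii}$ is zeroed by default: a taxon's
  rank self-correlation is trivially 1 and would otherwise inflate its own
  growth. This is configurable (`zero_self_interaction`) because it is
  genuinely unclear whether the original analyses excluded the $j = i$ term.

Defaults where the literature is silent, chosen once: $k = 100$ so
abundances read directly as percent of capacity; initial conditions equal
across taxa and totaling $k/2$ (alternatives: observed proportions scaled to
$k/2$, or a user vector); integration over 3 years to wash out the
transient, sampling at day-of-year 150 (late May, matching the season of the
validation collections).

## Numerical integration

No ODE solver suitable for this model ships with the supported environment,
so the package carries its own adaptive Dormand–Prince RK5(4) pair
(`rtol = 1e-8`, `atol = 1e-10`). Two choices matter:

* Steps never cross a requested output time, so reported states carry full
  solver accuracy with no dense-output interpolation. The single-taxon,
  constant-temperature solution matches the closed-form logistic to better
  than $10^{-6}$ relative error (an acceptance criterion).
* Abundances are non-negative by construction of the model, but floating
  point can produce tiny negative excursions: values in $(-\text{atol}, 0]$
  are clipped to zero on output, while anything below $-\text{atol}$ aborts
  with the failing time (it signals a genuine solver failure, not roundoff).

## Network inference

Interaction coefficients come from co-occurrence analysis of sample × taxon
relative-abundance tables (percent per metagenome): the pairwise Spearman
matrix (average ranks on ties), p-values from the t-approximation on $n-2$
degrees of freedom (the approximation used by the correlation routines this
field commonly cites; an exact permutation p-value is available behind
`p_method = "exact"` for ≤ 8 samples), and edge retention when
$|\rho| \ge 0.7$ **and** $p \le 0.001$. Retained coefficients keep their
sign — negative edges are biologically meaningful exclusions — and all other
entries become 0. Thresholding is idempotent. A taxon constant across
samples has undefined correlations; it is reported missing and can never
form edges.

Centrality summaries follow the conventions of reef-network analyses:
eigenvector centrality on the *absolute* edge weights (a negative weight
would break the Perron–Frobenius guarantee behind the principal
eigenvector), normalized to a maximum of 1; betweenness centrality and
diameter on the *unweighted* graph, betweenness as raw shortest-path counts
(the magnitudes reported for reef networks, up to ~90, indicate unnormalized
counts; a `normalized` flag exists). Nodes with no retained edges stay in
summaries with centrality 0 rather than being dropped silently, and the
component count reports edge-less taxa separately via an attribute instead
of inflating the count.

## Scenario grid

Two network profiles — specific (SN, inferred from one reef zone's samples
alone) and generalized (GN, from all samples pooled) — crossed with three
temperature profiles — zone-specific fluctuating (ST: inner $M=24, A=7$;
outer $M=18, A=5$), generalized fluctuating (GT: $M=21, A=6$, the average of
the two), and constant (CT: $A=0$ at the zone mean) — give six scenarios;
run for both zones, twelve model outputs. All runs share one solver
configuration so that accuracy differences are attributable to the profiles,
not the tolerances.

Validation regresses observed on predicted composition (the axes convention
of model-validation scatter plots; the direction is configurable because the
original is implied rather than stated), after fourth-root transforming both
sides, and tests the joint Wald hypothesis slope = 1, intercept = 0 as a
restricted-versus-full RSS F-test on (2, n−2) degrees of freedom.
Per-parameter t-tests are reported alongside for transparency; no
multiple-testing correction is applied across the twelve regressions.
Observed abundances are renormalized to 100% over the modeled (filtered)
taxon set before comparison, since the model only represents those taxa —
whether the original analysis renormalized is unstated; we renormalize and
say so.

Taxon filtering retains a class when its mean relative abundance reaches 1%
in at least one zone. The comparison is `>=`: a taxon sitting exactly on the
cutoff is kept, a documented boundary choice.

## The synthetic world

The generator exists so the entire pipeline can be exercised without any
sequencing data. It emulates the *statistical shape* of class-level
metagenome tables — six samples per reef zone, ~20 taxa, relative abundances
spanning several orders of magnitude — via a Gaussian copula: latent normal
scores with planted block correlation, pushed through per-taxon log-normal
marginals, then closed to 100% per sample. A copula is the right tool here
because the downstream network method is rank-based: only the rank structure
needs to be controlled, and the copula plants it exactly.

Two honest caveats about what a green test establishes:

* Closure rescales all taxa in a sample by a common factor, so
  *within-sample* ranks are untouched (asserted at generation time), but
  *across samples* the planted rank structure is perturbed by the varying
  denominator. When planted blocks dominate total abundance, closure alone
  can push cross-block correlations past the 0.7 retention threshold — a
  genuine property of compositional data, not a bug. The recovery criterion
  (sensitivity ≥ 0.9, zero cross-block edges at $n = 200$, $|\rho| = 0.95$)
  is therefore stated in the generator's default world: 20 taxa with planted
  blocks a minority of composition.
* The planted latent correlation is $(1-\rho)I + \rho ss^\top$ per block
  (with $s$ the within-block sign pattern), block-diagonal — positive
  semi-definite *by construction*. The infeasibility error in the generator
  is a defensive guard and unreachable through the public interface.

The generator does not emulate read-level noise, taxonomic annotation error,
zero inflation, or any real taxon identity; green recovery tests establish
that the inference machinery works on tables with known structure, not that
it is robust to sequencing artifacts.

All generators require a seed, are bit-reproducible given (spec, seed), and
restore the caller's RNG state.

## Degenerate inputs and tie-breaks

* All-zero community: relative abundances are an explicit error, never NaN.
* Zero-variance predictor in the regression: explicit error.
* Perfect fits: the Wald F is 0 (p = 1) when the fitted line *is* the
  hypothesized line, +∞ (p = 0) when the fit is exact but differs from it;
  the extra sum of squares is floored at 0 against roundoff.
* Disconnected networks: diameter errors with the component sizes named;
  eigenvector centrality is computed on the whole graph (nodes off the
  dominant component score ~0 and are floored to exactly 0 below 1e-10).

## Known limitations

The model inherits the assumptions of its source: identical competition
coefficients for all taxa, a single abiotic driver, correlation treated as
interaction, and validation against a single time point. Growth parameters
come from cultured representatives at class level — a coarse proxy. None of
these are addressed here; the package reproduces the published modeling
approach so that its behavior can be studied, not a new inference method.
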