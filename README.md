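# coralsml

Temperature-forced, network-coupled dynamics of the coral surface mucus
layer (SML) microbiome.

## The problem

The mucus coating a coral colony hosts a microbial community whose
composition shifts with the local thermal environment, and those shifts are
implicated in coral health and disease. `coralsml` is for microbial
ecologists who want to ask, quantitatively: *given per-taxon thermal
preferences and a co-occurrence network inferred from metagenomes, how well
does seasonal temperature alone predict community composition — and does it
matter whether the network and temperature profile are local or generic?*

## The model

Each taxon *i* has abundance *Bᵢ(t)* obeying a coupled logistic system

    dBᵢ/dt = Rᵢ(T(t)) · Bᵢ · (1 − Σⱼ Bⱼ/k) · (1 + Σⱼ ηᵢⱼ Bⱼ)

with a Gaussian thermal-performance curve
*R(T) = r_max · (2πσ²)^(−1/2) · exp(−(T−μ)²/2σ²)*, sinusoidal seasonal
forcing *T(t) = M + A·sin(ωt + θ)* (ω = 2π/365 rad/day), a shared carrying
capacity *k*, and interaction coefficients *ηᵢⱼ* taken from a thresholded
Spearman co-occurrence network (edges kept when |ρ| ≥ 0.7 and p ≤ 0.001,
signs preserved). Six scenarios cross {specific, generalized} networks with
{specific fluctuating, generalized fluctuating, constant} temperature
profiles per reef zone; model output is validated by regressing observed on
predicted composition (fourth-root transformed) with a joint Wald test of
slope 1 / intercept 0.

See `vignettes/coral-sml-model.Rmd` for assumptions, defaults, and design
notes.

## Worked example

Fully synthetic, no downloads: generate two reef-zone tables with a planted
co-occurrence block, infer networks, run the 6 × 2 scenario grid, validate.

```r
library(coralsml)

sp <- function(seed) synth_spec(6, 20,
        blocks = list(list(members = 1:4, rho = 0.9)), seed = seed)
inner <- gen_abundance_table(sp(11)); outer <- gen_abundance_table(sp(22))

keep  <- filter_classes(list(inner = inner, outer = outer))   # >= 1% rule
inner <- abundance_table(unclass(inner)[, keep])
outer <- abundance_table(unclass(outer)[, keep])
growth <- gen_growth_params(length(keep), seed = 3, taxa = keep)

reg <- build_registry(inner, outer)
#> <profile_registry> 16 taxa; networks: inner/outer/generalized; 5 temperature profiles

ns <- network_summary(reg$networks$inner)
#> inner network: 4 nodes, 2 edges, 12 isolated

runs   <- run_scenario_grid(reg, growth)
report <- scenario_report(runs, list(inner = inner, outer = outer))
report[1:3, c("zone", "scenario", "slope", "r_squared", "wald_p")]
#>    zone scenario   slope r_squared  wald_p
#> 1 inner    SN-ST -0.0685   6.3e-03 1.5e-03
#> 2 inner    SN-GT  0.0577   6.7e-03 6.6e-04
#> 3 inner    SN-CT -0.5489   3.0e-01 3.3e-05
```

What the numbers mean: 16 of 20 taxa pass the 1% mean-abundance filter; the
planted 4-taxon block is recovered as 4 connected nodes. The R² column is
the accuracy of each scenario at reproducing the observed composition and
the Wald p tests whether the regression is indistinguishable from the
identity line. Here growth parameters are random and unrelated to the
synthetic "observed" tables, so R² is properly near zero — with real
parameter tables the same report is the basis for deciding whether
temperature or network structure drives predictability.

The CLI wraps the same pipeline
(`system.file("cli", "coralsml", package = "coralsml")`):

```sh
coralsml synth     --out-dir data --seed 4
coralsml scenarios --inner data/inner_abundance.csv \
                   --outer data/outer_abundance.csv \
                   --growth data/growth.csv --out report.csv
coralsml report    --scenarios report.csv
```

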