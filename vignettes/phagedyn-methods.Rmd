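---
title: "phagedyn: methods and design notes"
author: "phagedyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagedyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `phagedyn`, the
choices made where the design was genuinely open, and what the package's
validation does and does not establish. The package addresses a defined
("gnotobiotic") experimental system: mice colonized with a known
ten-member bacterial consortium, perturbed by pairs of species-specific
lytic phages, and tracked longitudinally through 16S amplicon sequencing,
qPCR and untargeted metabolomics.

## 1. The community simulator

### Model

Bacteria follow generalized Lotka-Volterra (gLV) dynamics with
mass-action phage predation. Each species is split into a
phage-susceptible pool $s_i$ and a resistant pool $m_i$
($x_i = s_i + m_i$ cfu/g):

$$\frac{ds_i}{dt} = s_i g_i - \sum_p k_p s_i P_p\,[{\rm target}_p = i]
  - \mu_i s_i (g_i)_+$$
$$\frac{dm_i}{dt} = m_i\!\left(r_i (1 - c_i) + \sum_j a_{ij} x_j\right)
  + \mu_i s_i (g_i)_+$$
$$\frac{dP_p}{dt} = \beta_p k_p s_{{\rm target}(p)} P_p - w_p P_p$$

with $g_i = r_i + \sum_j a_{ij} x_j$. Design choices:

* **gLV + mass-action lysis** is the minimal mechanistic stand-in for
  in-vivo phage–bacteria dynamics. The experimental literature this
  emulates fits no dynamical model; the simulator is a *generator* whose
  job is to produce data with the right qualitative structure and known
  ground truth, not a calibrated model of any mouse.
* **Resistance as a two-compartment split** with growth-coupled mutation
  flux ($\mu_i$ per division, only when the gLV growth term is positive)
  reproduces resistant-subpopulation enrichment after a phage dose
  without modeling genotypes. Resistance carries a fractional growth
  cost $c_i$.
* **Dosing is impulsive**: gavage is effectively instantaneous on the
  day timescale, so doses are state increments at the dose day.

### Default consortium

Ten human gut commensals spanning the four dominant phyla, with 16S gene
copies per genome from the rrnDB (3–10), gavage inocula of 2×10^6 cfu
(*A. muciniphila*, *P. mirabilis*) or 2×10^7 cfu (others), and four lytic
phages — T4 (*E. coli*) and F1 (*C. sporogenes*) at day 16.1, VD13
(*E. faecalis*) and B40-8 (*B. fragilis*) at day 30.1 — each at 2×10^6
pfu. Sampling grids are the study designs: 41 decimal days to 43.1 for
the longitudinal cohort, 6 days to 16.1 for the four 9-member dropout
cohorts, 5 mice each.

The interaction matrix is parameterized around a target equilibrium
$x^*$ (total ≈ 1.1×10^9 cfu/g): $a_{ij} = s_{ij} r^0_i / x^*_j$ with
dimensionless strengths $s_{ij}$, $a_{ii} = -r^0_i/x^*_i$, and
$r = -A x^*$ so $x^*$ is exactly the phage-free equilibrium (self-limiting
diagonals keep it stable). The sign structure of $s$ encodes the
net-influence ground truth used to validate network inference:
*E. coli* promotes *B. fragilis* and represses the low-abundance members;
*C. sporogenes* promotes *P. distasonis* and *P. mirabilis*;
*B. fragilis* represses and *E. faecalis* promotes the same five
low-abundance species (equal and opposite, the nullification structure).

No kinetic parameters for this system are published. Defaults were
chosen once to reproduce the qualitative phenomena a phage-perturbation
study exhibits — knockdowns of roughly one to two orders of magnitude
with coexistence rather than eradication, a durable *E. coli* knockdown
versus a transient *C. sporogenes* one (slow F1 amplification, fast
resistance-driven recovery), a biphasic delayed *P. distasonis* bloom
driven by the durable repressor / transient promoter combination, and
resistant-colony fractions near zero before a VD13-like dose that rise
steeply between two and ten days after it. They are not fits to any
in-vivo trajectory.

### Numerics

Integration uses `deSolve::lsoda` (stiff-capable) with relative
tolerance 1e-8 and absolute tolerance 1e-3 cfu/g; states are clipped at
zero inside the derivative and on output, which prevents
negative-concentration artifacts in the steep post-dose transients.
Doses are deSolve events; dose times are added to the integration grid.
`steadyState()` integrates the phage-free system to a long horizon
(default 2000 d) and declares convergence only if both the relative
drift over the final fifth of the horizon and the largest per-capita
growth rate of a surviving species are below 1e-6; oscillatory systems
(e.g. a neutral predator–prey pair) are reported as non-convergent,
never silently returned. Concentrations below 1 cfu/g at the horizon are
treated as extinct.

## 2. Observation model

Per sample (mouse × day): sequencing reads are multinomial at the
configured depth with probabilities $\propto x_i n_i e_i$ — true
concentration × 16S copies per genome × amplification efficiency
$e_i \in [0,1]$. A read depth of `Inf` emits the infinite-depth
expectation (used for noiseless round-trip validation). The
universal-16S qPCR total is $(\sum_i x_i n_i e_i)\cdot LN(1, cv)$
copies/g, with $LN(1, cv)$ a lognormal factor of mean 1; phage qPCR
assumes one genome per particle — the simplest defensible conversion,
stated nowhere in the source literature. Values below the detection
limit (default 1e3 copies/g) are non-detects. Defaults: read depth
5×10^4 (the order of the study's median), qPCR CV 0.25, stool mass
0.05 g (CV 0.2), template dilution 100-fold.

Amplification bias is real in such assays ("efficiency differs across
species"), so the default consortium gives *P. distasonis* $e = 0.2$
(poorly amplified by universal primers, a documented artifact of the
emulated assay); because the species stays below ~1.5% relative
abundance this barely biases totals, and ratio-based analyses cancel it.
Estimation deliberately does **not** correct amplification bias — the
emulated procedure documents but does not correct it; the simulator can
inject it so its effect is measurable.

Randomness: a single master seed; each mouse's stream is seed +
mouse offset; every stochastic operation requires an explicit seed and
is reproducible.

Metabolites: compounds linked to a producer species have expected level
yield × producer concentration (e.g. a tryptamine-like compound uniquely
produced by *C. sporogenes*, a tyramine-like compound by *E. faecalis*);
unlinked host/background compounds have a constant expectation; all
levels carry lognormal noise (default CV 0.3). The colony resistance
assay draws `n_colonies` Bernoulli trials with the true resistant
fraction $m/(s+m)$; the default 64 colonies implies the 1/64 ≈ 1.6%
limit of sensitivity (the screened number behind that printed limit is
not reported; 64 is the choice that implies it).

## 3. Quantitation

Estimated bacteria per gram stool: $c_i = f_i T / n_i$ with $f_i$ the
relative read fraction and $T$ the qPCR 16S total per gram, itself
obtained by inverting a per-assay standard curve
(Cq = intercept + slope·log10 copies) and applying the explicit
volumetric chain — template dilution, extract/template volume ratio,
stool mass. The elution/template volumes of the emulated protocol are
not printed, so they are explicit parameters defaulting to 1.
Pre-imputation, $\sum_i c_i n_i = T$ exactly (conservation), which the
tests assert.

Non-detect semantics: zero reads or a qPCR non-detect both mean
"non-detected" (the emulated procedure does not distinguish).
Imputation replaces each non-detect with the lowest concentration at
which that species was detected *within one experiment* (one time
series or one dropout cohort — minima are reported per experiment in
the emulated study, so cross-experiment pooling is off by default);
imputation is monotone and idempotent, and a species never detected
anywhere is an explicit error rather than a fabricated value. A cohort's
count table carries no row for its omitted species, so dropout cohorts
impute cleanly.

## 4. Fold changes and aggregation

"Compared to 1 day prior" is resolved as: the latest sample with
day ≤ perturbation day − 0.5. The decimal-day sampling grid has no
sample at exactly −1.0 for every mouse, and this is the closest faithful
reading (for a 16.1-day dose it selects the 15.1-day sample). Cross-mouse
aggregation of ratio quantities is done on log10 values (geometric
means), matching log-scale presentation; arithmetic mode and SD/SEM
spreads are available. Cohort comparisons at a day use the nearest
sample within ±0.5 d (configurable). Whether dropout-versus-full
normalization uses geometric or arithmetic cross-mouse means is not
stated in the emulated analysis; the default is geometric, switchable.

## 5. Network inference

For dropped-out species $i$ and remaining species $j$, the log10 fold
change $\Delta$ of $j$ between the $i$-dropout cohort and the full
consortium at day 16.1 yields edge $i \to j$: promotion if $\Delta < 0$,
repression if $\Delta > 0$, weight $|\Delta|$. Edges measure *net*
(direct + mediated) influence — a dropout is the maximal possible
knockdown, so weights are upper limits on what phage predation of the
source can do. The default `min_weight` of 0.1 log10 suppresses noise
edges; 0 draws every computed edge (the emulated figures draw all of
them; no cutoff is stated there, so it is a free parameter here).

`predictResponse()` formalizes qualitative reasoning on the network as a
capped signed sum: each knocked-down source contributes
−min(weight, knockdown) for promotion and +min(weight, knockdown) for
repression. It is documented as a heuristic and validated only for sign
and nullification behavior (equal opposite influences cancel), not as a
quantitative predictor. Ground truth for validation comes from
`steadyStateInfluence()`: signs of log10 ratios of phage-free dropout
equilibria to the full equilibrium.

## 6. Stability statistics

Bray-Curtis dissimilarity $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on
relative abundances (as the emulated analysis specifies — not on
estimated concentrations), computed through `vegan::vegdist` with an
independent brute-force implementation as the test oracle. Two
longitudinal statistics: all unordered mouse pairs at one time point,
and consecutive samples within one mouse, where "previous time point"
means the previous *available* sample on the irregular grid, not
calendar day − 1. For compositions summing to 1 the denominator is 2
exactly. Bray-Curtis is not a metric; no triangle inequality is assumed
or asserted.

## 7. Metabolome differential analysis

Fold changes are post/pre per mouse against the sample immediately prior
to the perturbation; a compound must be detected in both members of a
pair to contribute (no ratios from non-detects). The significance test
is a two-sided one-sample t-test on log2 fold changes — the emulated
analysis names no test, so this paired default is an explicit choice,
with a Welch two-sample variant for unpaired designs (germfree versus
colonized). Compounds testable in fewer than 2 mice, or with degenerate
constant input, are excluded from the Benjamini-Hochberg family rather
than given fabricated p-values (a compound constant at exactly no change
gets p = 1). BH is `stats::p.adjust`, cross-checked against a
brute-force step-up in the tests. Germfree presence uses the
detected-in-≥4-of-5-samples rule. Heatmap ordering is agglomerative
clustering (Euclidean distance on log2 fold changes, average linkage,
hclust's input-order tie-breaking); log2 is used for heatmap quantities
and log10 for abundance quantities, as in the emulated figures.

## 8. Workflow and I/O

Tables are TSV (not CSV, avoiding locale decimal issues) with documented
schemas; configs and manifests are JSON with a `schema_version` field
and unknown keys rejected. Decimal days are stored as floats with a
0.05-day matching tolerance. `runPipeline()` chains simulate → observe →
write tables → estimate/impute → fold changes → (network) → stability →
metabolome and writes a manifest (config hash excluding the output
directory, seed, package version, per-stage row counts); identical
config + seed gives identical numeric outputs, which the tests verify by
checksum. This package is a library, not a shell tool: the exported
functions, `runPipeline()` and this vignette are its interface.

## 9. Validation scope and problem sizes

The test suite and `scripts/acceptance.R` validate, at the full study
scale (10 species × 5 mice × 41 days, and four 5-mouse dropout cohorts):
the noiseless estimation round trip (relative error ~1e-16, bound
1e-6); Bray-Curtis against its brute-force oracle on 1000 random pairs
(1e-12); influence-sign recovery (exact when noiseless; on edges with
true effect ≥ 0.3 log10, across 20 observation seeds at depth 5×10^4 and
qPCR CV 0.25); nullification (dual-knockdown response far below 25% of
the larger single response); the biphasic delayed bloom; resistant-colony
enrichment in ≥19/20 assay seeds; and metabolome calibration over 100
simulated tables (realized FDR within 0.075 at nominal 0.05, power ≥ 0.9
for a 10-fold producer knockdown).

What passing these does **not** show: the generator shares only
qualitative structure with real gut communities. It has no spatial
structure (mucosa versus lumen), no temperate phage, no horizontal gene
transfer, no host immune feedback, no diet or host variability;
real amplicon data add chimera/denoising artifacts upstream of the count
tables this package takes as given; and real metabolomes are vastly more
coupled than the one-producer linkage emulated here. Results on
synthetic data bound what the estimators can do under their own
assumptions — they are not evidence about any particular mouse
experiment. One printed reference point the package cannot recompute
offline is the deposited untargeted-metabolomics re-analysis
(`analyzeDepositTable()` runs it when a local copy of the deposit is
supplied).
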