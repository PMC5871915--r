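# netprop

Network propagation of somatic mutations for pathway analysis and patient
stratification.

## The problem

In most tumor types only a few genes are mutated in more than 10% of
patients; the majority of altered genes each occur in fewer than 5% of
samples, and driver mutations within one pathway tend to be *mutually
exclusive* — different patients hit different member genes. Selecting
"highly mutated genes" by a frequency threshold and testing pathway overlap
therefore misses pathways whose alteration is dispersed across many
low-frequency genes. `netprop` is for analysts of somatic mutation cohorts
who want pathway-level significance that captures this dispersed signal,
plus a patient-stratification workflow driven by per-patient pathway
profiles and survival comparison.

## Method

Given the symmetric adjacency matrix **W** of an undirected gene
interaction network, with degree matrix **D**, the propagation operator is
the normalized adjacency **S** = **D**^(−1/2) **W** **D**^(−1/2)
(normalized graph Laplacian **L** = **I** − **S**). A non-negative seed
vector f⁽⁰⁾ — gene mutation frequencies for a cohort (λ = 0.5), or a
patient's normalized mutation indicator (λ = 0.1) — is diffused by label
propagation

    f ← λ S f + (1 − λ) f⁽⁰⁾   ⇒   f = (1 − λ)(I − λS)⁻¹ f⁽⁰⁾

A pathway's score is the sum of stationary scores of its member genes, and
its p-value is empirical: the score is compared with those of 10,000
(configurable) random gene sets of the same network-mapped size,
p = (r + 1)/(N + 1) where r counts null scores at least as large. A
no-network baseline (frequency-threshold gene selection + upper-tail
hypergeometric enrichment) is included for comparison. For stratification,
patients are clustered hierarchically on their −log₁₀(p) pathway profiles
and the resulting groups are compared with a log-rank test (pairwise and
pooled), with Kaplan–Meier curves emitted as plain step coordinates.

A synthetic-data module generates planted-partition networks,
module-aligned pathways, cohorts with mutually exclusive planted drivers
(per-gene frequency ≈ 0.03 at the defaults) and exponential survival data,
so the whole pipeline is testable offline.

## Worked example

A single-subgroup cohort of 500 patients in which 60% carry exactly one
driver mutation somewhere in the 20-gene pathway `PW01` (per-gene driver
frequency ≈ 3%, median observed 3.5%), over a 0.3% passenger background:

```r
library(netprop)
cfg <- scenario_config(n_subgroups = 1, n_patients = 500,
                       passenger_rate = 0.003, hazard_per_subgroup = 1,
                       seed = 42)
sc  <- generate_scenario(cfg)
op  <- normalize_adjacency(sc$network)

tab <- score_cohort(sc$cohort, op, sc$pathways, n_null = 500, rng_seed = 3)
head(tab[order(tab$p_empirical), ], 4)
#>  pathway n_genes n_in_network     score p_empirical n_null
#>     PW01      20           20 0.4992759 0.001996008    500
#>     PW11      20           20 0.1776862 0.047904192    500
#>     PW12      20           20 0.1340260 0.295409182    500
#>     PW13      20           20 0.1201796 0.465069860    500
```

The planted driver pathway `PW01` reaches the empirical floor
1/(500 + 1) ≈ 0.002: its summed stationary score exceeded all 500
size-matched random gene sets. The no-network baseline sees almost nothing
— only one gene in the whole cohort clears the 5% threshold:

```r
sel <- select_highly_mutated(sc$cohort, min_freq = 0.05)
length(sel)
#> [1] 1
head(enrich(sel, sc$pathways, sc$cohort$genes), 3)
#>  pathway   N  K n k p_hypergeom
#>     PW01 200 20 1 1         0.1
#>     PW11 200 20 1 1         0.1
#>     PW02 200 20 1 0         1.0
```

A one-gene overlap gives p = 0.1: the dispersed driver pathway is
undetectable without the network.

The full patient-level workflow (per-patient propagation, clustering,
log-rank, KM curves) is available as `run_case_study()` or via the staged
pipeline runners (`run_simulate()`, `run_score()`, `run_enrich()`,
`run_stratify()`, `run_all()`), each of which writes TSV outputs and a JSON
manifest. A command-line dispatcher wrapping the same stages ships at
`inst/cli/netprop.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","netprop.R",package="netprop"))')" \
    simulate --outdir sim --preset mini --seed 1
```

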