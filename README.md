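# treeassoc

Genealogy-based association fine-mapping for phased case/control haplotypes,
with fuzzy p-values against the neutral-coalescent null.

## The problem and the approach

At the position of a disease-predisposing variant, haplotypes carrying the
risk allele descend from the branch on which the mutation arose, so case
haplotypes are more closely related to each other there than control
haplotypes are. The marginal ancestral tree at a genomic **focal point** x is
unobserved, but multi-marker genotype data G around x constrains it.
`treeassoc` samples from (an approximation to) the posterior
f(T<sub>x</sub>, θ, ρ | G) with Markov chain Monte Carlo, where the augmented
state holds the tree topology and node times, the haplotypes at internal
nodes, the scaled mutation rate θ (θ/2 mutation events per ascertained SNP
per unit coalescent time) and the scaled recombination rate ρ (ρ/2 events per
adjacent bp pair per unit coalescent time; one coalescent unit = 2N<sub>e</sub>
generations). Five Metropolis–Hastings kernels update θ, ρ, one
internal-node allele, and the topology (a nearest-neighbour swap and
subtree-prune-regraft), accepted with probability

&nbsp;&nbsp;α = min{1, [f(Ã|G) Q<sub>i</sub>(A|Ã)] / [f(A|G) Q<sub>i</sub>(Ã|A)]}.

Each sampled tree is scored with a **bipartition maximum-correlation
statistic**: every internal branch splits the tips into the branch's
descendants and the rest; over all splits whose two sides each hold at least
5% of the haplotypes, T = max |φ|, the absolute Pearson (phi) correlation
between cluster membership and case status. Because the tree is latent, T is
latent too. Evidence is expressed as a **fuzzy p-value**: with
T<sup>u</sup><sub>1..M</sub> the statistic on M trees drawn from the neutral
coalescent prior, each posterior tree j gets the latent p-value

&nbsp;&nbsp;p<sub>j</sub> = #{i : T<sup>u</sup><sub>i</sub> ≥ T<sup>c</sup><sub>j</sub>} / M,

and the distribution of (p<sub>1</sub>, …, p<sub>N</sub>) over the posterior
sample — summarized by its median, quartiles and 90th percentile — carries
both the strength of association and the genealogical uncertainty. A region
is scanned by repeating this at evenly spaced focal points, each conditioning
on the SNPs within a window (100 kb by default, expanded to the nearest 20
SNPs where markers are sparse).

The package also ships the surrounding machinery: a Kingman coalescent
simulator, a synthetic case/control generator with a planted causal variant
and distance-decaying linkage, single-SNP Fisher exact comparators,
Bonferroni thresholds, a permutation-null diagnostic, Newick/VCF/matrix-text
I/O, and `tidy()`/`glance()`/`autoplot()` methods for every result type.

## Worked example

Simulate a 50-haplotype panel (25 transmitted "cases", 25 untransmitted
"controls", 20 SNPs in 5 kb) with a planted causal variant, then scan four
focal points:

```r
library(treeassoc)

sim <- simulate_case_control(synth_scenario(seed = 42))
sim$data
#> <hap_data> 50 haplotypes x 20 SNPs, 25 cases / 25 controls, span 27-4863 bp
sim$causal_bp
#> [1] 1134

cfg <- region_config(
  n_focal_points = 4, window_bp = 2500, min_snps = 5, prior_m = 2000,
  sampler = sampler_config(n_iterations = 50000, burn_in = 25000, thin = 50),
  seed = 7
)
rr <- run_region(sim$data, cfg)
tidy(rr)
#> # A tibble: 4 × 10
#>   focal_bp n_snps_window  mean_rho mean_theta median_latent_p    q25   q75   q90
#>      <dbl>         <int>     <dbl>      <dbl>           <dbl>  <dbl> <dbl> <dbl>
#> 1     632.            10 0.000699        7.95          0.0445 0.0045 0.064 0.244
#> 2    1840.            14 0.000557        7.78          0.0515 0.0045 0.118 0.244
#> 3    3050.             8 0.000532        6.84          0.244  0.064  0.533 0.914
#> 4    4258.             5 0.0000675       1.85          0.533  0.144  0.616 0.914
```

The focal point nearest the planted variant (632 bp vs causal 1134 bp) has
the smallest median latent p-value (0.0445), and the evidence decays with
distance (0.0515 → 0.244 → 0.533); `mean_rho` hovers near the generating
scaled recombination rate 4e-4. `autoplot(rr)` draws the
−log<sub>10</sub>(median latent p) association curve with the uncorrected
and Bonferroni thresholds, `autoplot(rr, permutation = TRUE)` the
permutation-null companion, and `autoplot(rr$focal[[1]])` the traceplots
(θ, ρ, TMRCA, Robinson–Foulds distance between successive retained trees)
used to judge mixing.

A command-line wrapper with `simulate`, `sample`, `assoc` and `run-region`
subcommands is installed at `inst/cli/treeassoc.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/treeassoc.R", package="treeassoc"))') run-region --data panel.txt --out out/`).

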