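# mitoscan

Tools for mapping and modelling **mitonuclear hybrid incompatibilities**
from local-ancestry data.

In hybrids between recently diverged species, nuclear-encoded and
mitochondrially encoded proteins that must cooperate (for example within
respiratory complex I) can mismatch: individuals homozygous for one
species' nuclear allele on the other species' mitochondrial background die
or fail to develop. `mitoscan` is written for population and evolutionary
geneticists working in such systems — its motivating case is the
*Xiphophorus birchmanni* × *X. malinche* hybrid system, where near-lethal
interactions involve the complex I genes *ndufs5* and *ndufa13* and the
*X. malinche* mitochondria. The package covers the complete analysis arc
on ancestry hard-call matrices (individuals × ancestry-informative sites,
0/1/2 copies of one parent's alleles, plus per-individual mitochondrial
haplotypes):

* **Simulation** — forward-in-time F2 intercrosses and Wright–Fisher
  hybrid swarms under mitonuclear viability selection (Haldane crossover
  model, maternal mitochondrial inheritance, optional migration), plus
  codon alignments with exact branch-specific substitution counts and
  synthetic multi-chain structures.
* **Segregation distortion** — per-site ancestry means with a genome-wide
  99% quantile envelope, the >60% ancestry screening rule, and the exact
  binomial survivor-deficit test.
* **Selection inference** — rejection ABC for the selection coefficient
  *s* and dominance *h* at a focal locus. Fitness of the penalized
  homozygote is 1 − *s*, of the heterozygote 1 − *hs*; the expected
  surviving F2 genotype frequencies are
  ( ¼(1 − *s*), ½(1 − *hs*), ¼ ) / *Z*. The MAP estimate comes from a
  boundary-reflected 2-D KDE over the accepted Uniform(0,1) prior draws.
* **Admixture mapping** — a partial-correlation scan of site ancestry
  against mitochondrial haplotype with genome-wide ancestry regressed out
  (leave-one-chromosome-out), genome-wide significance thresholds at a 10%
  false-positive rate from matched forward-simulated nulls, and peak
  calling.
* **Epistasis** — chi-squared independence and a one-sided permutation
  test for heterozygote depletion among survivors of a second
  incompatibility.
* **Introgression vs. incomplete lineage sorting** — Poisson substitution
  simulations of expected mitochondrial divergence, 250-kb windowed
  ancestry profiles, and a cross-population replicated-depletion
  permutation test.
* **Molecular evolution** — NG86 dN/dS counting with mutational-path
  averaging and Jukes–Cantor correction, two-outgroup parsimony
  polarization of substitutions onto branches, genome-wide percentile
  ranking (dS = 0 reported as "> 99").
* **Structure** — classification of residue–residue contacts between
  substituted sites across replicate structural models (strong: Cα ≤ 10 Å
  in all models; weak: side chain ≤ 12 Å in ≥ 1 model).

## Worked example

Estimate the strength of selection behind an observed F2 genotype deficit.
Among 943 surviving F2 hybrids (all carrying the malinche mitochondria),
28 were homozygous birchmanni at the focal locus, 610 heterozygous and
305 homozygous malinche — about 3% penalized homozygotes versus the
Mendelian 25%:

```r
library(mitoscan)

fit <- abcFit(c(28, 610, 305), nSims = 500000, tolerance = 0.05, seed = 1)
fit
#> ABCPosterior: 399 accepted of 5e+05 simulations (tolerance 0.05 )
#>   MAP: s = 0.910, h = 0.025
#>   95% CI: s = 0.870-0.940, h = 0.002-0.177
```

The posterior mode says the penalized homozygote retains only ~9% of
normal viability (*s* ≈ 0.91), with selection largely recessive. The
closed-form survivor model confirms that these parameters predict the
observed 3%:

```r
round(100 * expectedSurvivingFrequencies(0.91, 0.09), 1)
#> homPenalized          het     homOther
#>          3.1         62.8         34.2
```

An end-to-end demonstration on fully synthetic data — simulate a cross and
two hybrid swarms under a two-locus incompatibility, then run every
analysis stage into a report directory — is one call:

```r
report <- runPipeline(outDir = "demo_run")
```

See the methods vignette (`vignettes/mitoscan-methods.Rmd`) for the models,
assumptions, parameter choices and known limitations.

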