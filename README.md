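# nuptr — characterization of nuclear plastid DNA (NUPT) insertions

Plant nuclear genomes continuously acquire fragments of plastid DNA
(NUPTs). Where they land, how fast they decay, and what they do to the
genes they hit are central questions for genome evolution in
plastid-rich genomes. `nuptr` is an R package plus analysis workflow
that characterizes a genome's NUPT complement from standard inputs — a
nuclear and a plastid genome (FASTA + GFF3), a tabular
nuclear-vs-plastid alignment (BLAST outfmt 6 dialect) defining the
NUPTs, and optionally a tissue TPM matrix and functional-term tables —
and that ships a synthetic-genome generator with planted ground truth so
every layer is testable end to end.

## What it computes

* **Insertion age classes.** A two-component Gaussian mixture
  $x \sim \pi_1\,\mathcal N(\mu_1,\sigma_1^2) + \pi_2\,\mathcal
  N(\mu_2,\sigma_2^2)$ fitted by EM to percent identity; NUPTs are
  assigned to the older episode I (lower mean), the younger episode II,
  or left unclassified when the posterior $\max_j \gamma_j < 0.95$.
* **Feature enrichment.** The genome is partitioned into disjoint
  feature categories (structural gene, TE, repeats, RNA gene classes,
  residual other DNA); observed bp overlap $O_f$ of NUPTs with category
  $f$ is tested against the bp-proportional expectation
  $E_f = T\,S_f/G$ with a Yates-corrected df = 1 chi-squared on the
  cells $(O_f, T{-}O_f)$ vs $(E_f, T{-}E_f)$.
* **Gene impact.** Per-gene NUPT burden split by region (1 kb promoter,
  exons, derived introns, 1 kb terminator), age-class exclusivity
  (I-only / II-only / unclassified-only / mixed, a partition of the
  affected genes), and full-coverage status.
* **RNA origin.** Best-hit compartment calls for tRNA genes (nuclear /
  mitochondrial / plastid), a compartment census with the NUPT-resident
  fraction, and linear, strand-aware donor mapping of NUPT-resident RNA
  genes back to the plastid genome.
* **Expression.** Expressed-gene flags, the Tau tissue-specificity index
  $\tau = \sum_i (1 - x_i/\max x)/(N-1)$, Fisher exact tests on
  expressed fractions, exact/approximate Wilcoxon rank comparisons, and
  Bonferroni-corrected term enrichment.

The methods vignette
(`vignettes/nupt-characterization.Rmd`) documents the models,
parameter defaults, numerical choices, and the generator's scope.

## Worked example

The `analysis/` scripts run the whole study on synthetic data:

```sh
Rscript analysis/01_simulate.R          # inputs + truth -> results/sim/
Rscript analysis/02_run_pipeline.R      # reports        -> results/run/
Rscript analysis/03_score_against_truth.R
```

Stage 1 plants 900 NUPTs (150 old, 750 young) in a 4 x 250 kb nuclear
genome; stage 2 prints the fitted mixture and headline counts:

```
Gaussian mixture on percent identity (k = 2 )
  component 1: mean 82.240, sd 4.358, weight 0.174
  component 2: mean 96.947, sd 1.673, weight 0.826
Age-class counts:
           I           II unclassified
         149          736           15
Structural genes affected by NUPTs: 75
tRNA census: 118 genes, 45.76% NUPT-resident
```

The fitted means (82.2 / 96.9) recover the planted episode identities
(82 / 97), and the 149/736 class split matches the planted 150/750 wave
sizes; the remaining 15 NUPTs sit between the components at posteriors
below 0.95. Stage 3 scores the reports against the truth ledger
(`results/scorecard.tsv`): 99.8% of confidently labeled NUPTs land in
their true episode, every placement-boosted category is flagged
enriched, and the planted functional term is recovered at
$p_{adj} \approx 6\times 10^{-8}$.

Programmatic use mirrors the scripts:

```r
library(nuptr)
bundle <- simulate_bundle(sim_config(seed = 1), "sim")
res <- run_all(run_config(
  bundle$nuclear_fasta, bundle$nuclear_gff3, bundle$plastid_fasta,
  bundle$plastid_gff3, bundle$alignment, bundle$trna_hits,
  bundle$compartment_map, bundle$tpm, bundle$terms, out_dir = "out"))
res$classes$fit            # the mixture
res$enrichment$table       # observed/expected bp per category
res$impact$summary         # gene-region tallies
```

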