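# cftrio

Fetal variant and copy-number inference from maternal plasma cell-free
DNA (cfDNA), with trio support.

Plasma cfDNA in pregnancy is a mixture: a fraction *f* (the fetal
fraction, typically 5–20%) of fragments is fetal/placental, the rest
maternal. `cftrio` provides the statistical core of a targeted
non-invasive prenatal screening analysis:

- **Fetal genotype calling.** At a SNP site with maternal alt copies
  *m* and fetal alt copies *k*, the expected plasma alt-read fraction is
  the mixture *p = (1−f)·m/2 + f·k/2*, error-adjusted to
  *p′ = p(1−ε) + (1−p)ε*; alt counts are Binomial(depth, p′). Posteriors
  over *k* ∈ {0, 1, 2} are computed in log space
  (`call_fetal_genotype()`).
- **Fetal-fraction estimation** from obligate-heterozygote sites
  (mother hom-ref, father hom-alt), *f̂ = 2 · mean(alt fraction)* with
  read-error de-biasing (`estimate_fetal_fraction()`).
- **Fragment-size modeling.** Fragments carrying maternally absent
  alleles are tagged fetal; fetal fragments are shorter (mode ≈ 143 bp
  vs ≈ 166 bp), and the size contrast feeds the CNV caller
  (`tag_fragments()`, `fit_size_distribution()`).
- **CNV calling.** Per-bin depth ratios against reference control bins
  are Gaussian on the log2 scale with event means 1 ± f/2; an optional
  fragment-size channel adds the expected short-fragment shift.
  Contiguous segments are scored by maximum likelihood and called above
  a log-likelihood-ratio threshold (`call_cnvs()`).
- **Trio pipeline.** Artifact filters (allele-fraction band
  0.20 < AF ≤ 0.80, ENCODE-style BED blacklist, depth ≥ 100×) followed
  by inheritance classification: paternal-inherited, de novo,
  maternal-or-shared (`run_artifact_pipeline()`).
- **Concordance statistics.** Plasma-vs-child callset overlap per
  inheritance category, coverage refiltering of missed variants, and
  r² analyses (`overlap_report()`, `overlap_correlations()`), with a
  bundled 36-family published cohort as worked example
  (`cohort_samples()`, `cohort_concordance()`).
- **Synthetic cohort simulator.** Seeded, deterministic generation of
  trio genotypes, plasma counts, fragments, bins, controls and injected
  CNVs so the whole pipeline runs at desk scale (`simulate_cohort()`).

## Worked example

```r
library(cftrio)

co <- simulate_cohort(sim_config(seed = 1,
  cnv_events = data.frame(chrom = "chr1", start = 2e6, end = 2.8e6,
                          state = "fetal_dup")))

ff <- estimate_fetal_fraction(co$sites, error_rate = 0.01)
ff
#> Fetal fraction estimate: 0.0972 (n = 83 informative sites, se = 0.0041)

calls <- call_fetal_genotype(co$sites, ff$f)
mean(calls$ml_call == co$genotypes$child)
#> [1] 0.8355

nb <- normalize_bins(co$bins, co$reference)
call_cnvs(nb, ff$f, co$reference)
#>   chrom   start     end copy_state   log_lr n_bins     f_used
#> 1  chr1 2000000 2800000  fetal_dup 25.41291      8 0.09723183
```

The simulated truth was *f* = 0.10 with an 800 kb heterozygous fetal
duplication at chr1:2,000,000–2,800,000. The estimator recovers the
fetal fraction to within its standard error; at depth 200 a plasma
genotype is correct at about 84% of sites (heterozygous vs homozygous
fetal states differ by only *f*/2 ≈ 0.05 in expected allele fraction,
so depth is the limiting factor); the sub-megabase duplication is
recovered exactly, with a log-likelihood ratio of 25.4 against the
diploid model.

Cohort worked examples from the bundled published tables:

```r
str(summarize_cohort())
#> List of 7
#>  $ n_samples        : int 36
#>  $ n_plp_snv_samples: int 18
#>  $ n_deletions      : int 2
#>  $ n_duplications   : int 2
#>  $ ff_min           : int 5
#>  $ ff_max           : int 20
#>  $ mean_ga_weeks    : num 12.1
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "cftrio.R", package = "cftrio")` with subcommands
`simulate`, `genotype`, `cnv-call`, `trio-filter` and `concordance`.

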