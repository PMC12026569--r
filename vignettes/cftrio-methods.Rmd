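---
title: "Models and methods behind cftrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cftrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrio)
```

## The problem

During pregnancy, maternal plasma carries a mixture of cell-free DNA
(cfDNA) fragments: mostly maternal, with a minority fraction $f$ (the
*fetal fraction*, typically 5–20%) of placental/fetal origin. Targeted
deep sequencing of plasma can in principle reveal the fetal genotype at
single-nucleotide resolution and detect fetal copy-number variants
(CNVs), but every observation is diluted by the maternal background.
`cftrio` implements the statistical machinery for this setting: fetal
genotype inference and fetal-fraction estimation from plasma allele
counts, fragment-size-aware CNV calling on targeted bins, artifact
filtering and inheritance classification of trio gDNA callsets, and
concordance analysis between plasma callsets and the child's confirmed
genotype.

## The binomial mixture model for plasma allele counts

At a biallelic SNP site with maternal alt-allele copy number
$m \in \{0,1,2\}$ and fetal copy number $k \in \{0,1,2\}$, the expected
alt-read fraction in plasma is the linear mixture

$$p = (1-f)\,\frac{m}{2} + f\,\frac{k}{2},$$

adjusted for a symmetric per-read miscall probability $\varepsilon$ as
$p' = p(1-\varepsilon) + (1-p)\varepsilon$. The observed alt count at
depth $d$ is modeled as $\mathrm{Binomial}(d, p')$. For fixed $m$ and
$f>0$ the mean is strictly increasing in $k$, which makes the fetal
genotype identifiable; at $f=0$ the three fetal states are
indistinguishable and the posterior collapses to the prior.

Posteriors over $k$ are computed in log space with max-subtraction
normalization, so sites with depth up to $10^5$ do not underflow. The
maximum-likelihood call breaks exact ties toward the smallest $k$ — a
deliberate, conservative convention (prefer fewer alt copies when the
data cannot distinguish) that is documented and tested. The default
prior is uniform over $k$; a Mendelian prior computed from both parental
genotypes (`mendelian_prior()`) can be supplied when the trio is
available. Plain binomial noise is used rather than beta-binomial;
overdispersion in real panels is acknowledged as a limitation below.

Defaults: $\varepsilon = 0.01$, uniform prior. The error rate matters
mainly near $p' \approx 0$ or $1$, where it keeps log-likelihoods
finite and absorbs stray reads at homozygous sites.

## Fetal-fraction estimation

At sites where the mother is homozygous reference and the father is
homozygous alt, the fetus is an obligate heterozygote and the expected
plasma alt fraction is $f/2$; the package estimates
$\hat f = 2\,\overline{\mathrm{af}}$ over those sites, with a
delta-method standard error. Two refinements were design decisions:

* **Heterozygous fathers.** If sites with paternal copy number 1 were
  pooled naively, the fetus inherits the paternal alt allele only half
  the time and $2\,\overline{\mathrm{af}}$ would be biased low by
  roughly a factor of two. The default therefore restricts to
  father-homozygous sites (`min_paternal_copies = 2`); setting
  `min_paternal_copies = 1` includes het-father sites through the
  transmission-corrected estimator
  $\hat f = 4\,\overline{\mathrm{af}} / \bar p$.
* **Read-error de-biasing.** Sequencing errors add $\approx \varepsilon$
  to the mean alt fraction at these near-zero-signal sites, inflating
  $\hat f$ by $\approx 2\varepsilon$. When an error rate is supplied the
  estimator inverts $p' = p(1-2\varepsilon)+\varepsilon$ first. At the
  simulator's default $\varepsilon=0.01$ this correction is the
  difference between meeting and missing a bias target of 0.005.

An externally measured fetal fraction (as screening assays provide) can
be passed to any downstream function instead; the internal estimate is
the default for synthetic runs.

## Fragment-size model

Fetal cfDNA fragments are characteristically shorter than maternal ones
(modes near 143 bp vs 166 bp). Fragments covering a site where the
mother is homozygous can be tagged: a read carrying the allele absent
from the maternal genotype is fetal up to sequencing error
(`tag_fragments()`). Size distributions are normalized histograms on
fixed global edges (50–400 bp, 5 bp bins) so that samples are directly
comparable; kernel estimates were rejected to keep the distributions
exactly re-normalizable and deterministic.

Two uses are implemented: hard selection of fetal-tagged fragments (the
default pathway), and a continuous per-fragment fetal posterior by
length, $\Pr(\text{fetal}\mid \ell) = f d_F(\ell) / (f d_F(\ell) +
(1-f) d_M(\ell))$ (`fetal_probability_by_size()`), for pipelines that
prefer weighting over selection. Where both densities vanish the prior
$f$ is returned.

## CNV calling on targeted bins

Per-bin fragment counts are normalized by a double-median ratio against
presumed-diploid reference controls:
$r_i = (c_i/\tilde c)\,/\,(\rho_i/\tilde\rho)$, so a diploid sample has
median ratio 1 by construction. A heterozygous *fetal* event only
rescales the fetal share of fragments, so the expected ratio is
$1 - f/2$ for a fetal deletion and $1 + f/2$ for a duplication — at
$f = 0.10$ a 5% depth shift, which is why bin-level noise must be small
and why the fetal fraction enters the likelihood explicitly.

The likelihood is Gaussian on $\log_2 r_i$ with standard deviation
`ratio_sigma` estimated from the controls, summed over the bins of a
candidate segment. A second, optional evidence channel uses the per-bin
short-fragment fraction: an event changes the fetal share of fragments
from $f$ to $w = f(c/2)/((1-f)+fc/2)$, shifting the expected short
fraction by $(w-f)(p^{short}_F - p^{short}_M)$. The channel is centered
on the *control baseline* `short_mean` rather than on an absolute
mixture mean: absolute short-fragment probabilities estimated from
tagged fragments are biased (fetal fragments carrying the maternal
allele are inevitably tagged maternal), and anchoring on the baseline
makes that bias cancel at diploid so it cannot manufacture false
events; only the fetal–maternal contrast, which survives contamination
in direction, drives sensitivity. The two channels are combined
additively in log space with weight 1.

Segmentation scans every contiguous run of `min_bins` (3) to
`max_span_bins` (25) bins per chromosome, computes the log-likelihood
ratio of the best non-diploid state against diploid via cumulative
sums, keeps candidates above `log_lr_threshold` (10), and resolves
overlaps greedily by descending ratio. The procedure is exhaustive
within its span limit, deterministic, and O(states × bins × span).
Ratios are floored at `ratio_floor` ($10^{-6}$) before logs; bins with
zero reference count are masked rather than dropped so coordinates stay
aligned; |log2 ratio| beyond 0.5 is flagged as a gross deviation
(maternal-origin CNVs shift ratios by ±0.5 and are outside the
three-state fetal space by design). At $f=0$ the caller warns and
returns no calls.

## Trio artifact filtering and inheritance classification

Child/fetal gDNA callsets pass three artifact filters, in order: an
allele-fraction band that keeps $0.20 < \mathrm{AF} \le 0.80$ (both
tails are artifact-enriched; the literal band also removes true
homozygous calls, so a documented `exempt_hom_alt` switch can retain
proband hom-alt genotypes), a BED blacklist filter (BED intervals are
0-based half-open, so `[100, 200)` covers 1-based positions 101..200 —
the conversion is boundary-tested with sentinels), and a depth filter
keeping $\ge 100\times$. The filters are pure row predicates, hence
idempotent and order-commutative; the fixed order only determines
first-rule attribution in the provenance report.

Surviving proband variants are classified against the parents:
*paternal-inherited* (absent from the mother, present in the father),
*de novo* (absent from both), *maternal-or-shared* (present in the
mother), or *unclassifiable* (required genotype missing, or proband
carries no alt). "Present" means called genotype copies $\ge 1$;
low-level parental read evidence is deliberately not consulted.

## Concordance statistics

Plasma and truth callsets are matched on `chrom:pos:ref:alt` keys. For
one sample and inheritance category the denominator is the truth-side
total; `pct_common` is rounded half-up to an integer (the convention
that reproduces the most published table cells; the bundled table is
internally inconsistent between rounding conventions in 6 of 72 cells,
which the tests surface rather than mask). The coverage refilter
drops missed truth variants whose plasma coverage is at or below the
threshold (default 5 reads) from the denominator — the only reading
under which refiltering can only raise the percentage, which is proved
as a monotonicity property in the tests. Squared Pearson correlations
of the overlap percentage against missed-variant coverage and against
fetal fraction are computed pooled and per category, since the pooling
convention of the source figures is ambiguous.

## The synthetic cohort simulator

The generator is first-class, tested code and defines the study
conditions for every recovery test:

* Trio genotypes: per-site alt frequencies uniform on 0.05–0.95,
  parents drawn from Hardy–Weinberg, child by uniform Mendelian
  transmission, de novo injection at $10^{-3}$ per site (a fixture
  convenience, not a biological rate).
* Plasma counts: depth Poisson(200), alt counts binomial at the mixture
  expectation — the generative twin of the inference model.
* Fragments: Gaussian lengths (fetal mode 143 bp, maternal 166 bp, sd
  20 — conventional cfDNA values), fragment origin fetal with
  probability $f$, rescaled inside CNV events; 2500 fragments per
  100 kb bin by default, giving Poisson log2-ratio noise near 0.03 as
  in a deeply sequenced targeted panel; 20 diploid controls.
* Default $f = 0.10$, mid-range of the 5–20% observed in screening
  cohorts; recovery tests sweep $\{0.05, 0.10, 0.20\}$.

Everything is reproducible from one integer seed, including emitted
files (byte-identical re-runs). Problem sizes used by the test suite
and the acceptance script — 2000 sites, 50 bins, 10–100 seeds per
operating characteristic — are the package's chosen desk-scale study
conditions.

What the simulator does **not** emulate bounds what passing tests can
show about real data: no GC or mappability bias (a hook exists in
normalization but no correction is applied), no overdispersion beyond
binomial/Poisson noise, no placental mosaicism (the fetal fraction is a
single global constant), no alignment or trimming artifacts (fragment
lengths are exact interval lengths), and maternal-origin CNVs appear
only as the gross-deviation guard, not as a modeled state.

## Known limitations

* The three-state copy space (fetal del / diploid / dup) does not
  estimate absolute integer copy number, nor deconvolve placental
  mosaicism.
* The AF band literally removes true homozygous child variants unless
  the exemption switch is used; both behaviors are tested.
* Binomial counts understate real-panel variance; an overdispersed
  extension would widen genotype posteriors at high depth.
* The published concordance table that ships with the package is
  treated as ground truth for worked examples even where its own
  printed percentages are internally inconsistent; the package reports
  what it computes.

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 1))
ff <- estimate_fetal_fraction(co$sites, error_rate = 0.01)
calls <- call_fetal_genotype(co$sites, ff$f)
nb <- normalize_bins(co$bins, co$reference)
cnvs <- call_cnvs(nb, ff$f, co$reference)
```
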