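---
title: "Auditing SNP-based evidence for graft-mobile mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing SNP-based evidence for graft-mobile mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftnoise)
```

## The inference problem

In a heterograft (two genotypes joined at a graft junction), an RNA-seq
read from the sampled tissue that carries the partner genotype's SNP
allele is the elementary datum for mRNA transport. The same datum is
produced by base-calling error (~0.1–1% per base on short-read
platforms), reverse-transcription error, mismapping between paralogues
or incomplete assemblies, pseudo-heterozygous loci, and contamination.
A homograft — the same genotype on both sides — generates all of those
*except* transport, and is therefore the experiment's own null.

`graftnoise` treats mobility claims as a model-comparison problem
against that null rather than a thresholding problem. This vignette
records the models, the tunable parameters, the design decisions taken
where the design was genuinely open, and what the synthetic-data
calibration does and does not demonstrate.

## The noise model

Let `q` be the probability that a sequenced base at a SNP position
reports the foreign allele by error. With uniform misincorporation a
per-base error rate `e` gives `q = e/3`, since only one of the three
wrong nucleotides matches the foreign allele. A transcript with `N`
reads over its SNPs reaches a read-count criterion "at least `m`
foreign reads" by chance with probability

> P(k >= m | N, q) = 1 − P(k < m | N, q),

the cumulative binomial tail (`binomial_tail()`). For criteria that
demand a read covering two SNPs, both bases on the read must err, so the
per-read probability is `q^2` and `N` counts multi-SNP reads
(`criterion_fp_probability()`). Summing the tail over a transcript
catalogue gives the expected number of false mobile calls
(`expected_false_positives()`); the tail grows with `N`, which is the
read-depth dependency that makes absolute read-count criteria
incomparable across libraries. Strict thresholds are normalised at
construction (`>3` becomes `>=4`), so no downstream code ever branches
on strictness.

The homograft background rate is estimated by pooling foreign and total
counts over all sites (`estimate_background()`); the conjugate
`Beta(a + n, b + N − n)` posterior keeps the depth-dependent uncertainty
explicit. Pooling is the default because it matches how a single
dataset-level rate is used; a per-gene stratified mode exists because a
handful of pseudo-heterozygous loci can dominate a pooled rate — in the
worked example in the README a 0.3% base error plus 2% pseudo-het genes
yields a pooled background of 0.82%, eight times the error-only value.

## The Bayes-factor comparison

For one transcript with pooled heterograft counts `(n_het, N_het)` and
homograft counts `(n_hom, N_hom)`, two hypotheses are compared:

* **Noise**: one shared rate `q ~ Beta(a, b)` generated both samples.
  The marginal likelihood is the closed-form integral of the two
  binomials against the prior.
* **Foreign component**: each sample has its own rate; the marginal is
  the product of two beta-binomial marginals
  (`log_betabinom_marginal()`).

`bayes_factor()` returns `log10(m_foreign / m_noise)`; transcripts above
the threshold (default 1, "strong" on Jeffreys' scale) are mobile
candidates. Decisions taken here, each genuinely open:

* **Prior** `Beta(1, 1)` on every rate: flat, conjugate, and dominated
  by the data at RNA-seq depths. Doubling both pseudo-counts moves
  classifications on the standard simulation by under 2% of genes.
* **Base-10 logarithm, threshold 1** — the conventional "strong
  evidence" reading; the base is a display choice, the threshold a
  configuration field.
* **Unconstrained second rate** rather than a one-sided
  `q_het > q_hom` prior: this keeps the closed form, is symmetric under
  label exchange, and is conservative for the transport direction (a
  heterograft rate *below* the homograft's also earns a positive BF, but
  such genes are not transport candidates and can be screened by sign of
  the rate difference). A consequence worth knowing: the BF is
  *minimised* where `n_het/N_het = n_hom/N_hom` and rises on both sides,
  so it is monotone in `n_het` only above the matched point. The test
  suite asserts exactly that shape.
* **Pooling across a gene's SNPs** sums counts; `per_snp = TRUE`
  computes one BF per site and takes the gene maximum, because a single
  pseudo-SNP can dominate a pooled count.
* Genes with zero depth in both samples get `log10 BF = 0` and a
  zero-evidence flag rather than an error: absence of data is absence of
  evidence.

## Read-level consistency

A read genuinely transcribed from one genotype carries that genotype's
allele at every SNP it covers. `classify_read()` maps a multi-SNP read
to all-local / all-foreign / inconsistent, with a separate
`contains_other` category (taking precedence) for reads showing a
nucleotide that is neither allele: a third nucleotide is unambiguous
sequencing error, and folding such reads into "inconsistent" would
dilute the local-versus-foreign contrast. Under pure noise the
all-foreign fraction of k-SNP reads scales as `(e/3)^k`, which the
suite verifies at `k = 2` against the generator.

## SNP versus neighbour distributions

At SNP positions the statistic is `n/N`: foreign-allele reads over the
total, where `N` by default counts only reads matching either graft
allele (`total_definition = "local_plus_foreign"`); counting all four
nucleotides is a configuration switch, because pileups report everything
while the ratio of interest divides by informative reads only. At
neighbouring non-SNP positions (all positions within
`neighbour_window = 5` bp of a SNP, deduplicated) the noise statistic is
`m/M`: the second most frequent nucleotide over the sum of the top two.
Ties for second place are broken in fixed A<C<G<T order — the tied
*counts* are equal, so the value is unaffected.

`compare_distributions()` runs an exact two-sample Kolmogorov–Smirnov
test (asymptotic with a message when the combined sample exceeds
`exact_max`), a one-sided KS test of "SNP values stochastically larger"
— the direction genuine transport must push — plus Welch t and Wilcoxon
as secondary tests. Tests run on the raw value collections, not on
100-bin histograms: binning a KS statistic discards information, so the
histogram view is confined to `plot_fraction_histogram()`. This is a
deliberate divergence from binned-histogram practice.

Two caveats the calibration exposed, both relevant to real data:

* With uniform miscalls, `m` at a neighbour is the *maximum* of three
  error counts while `n` at a SNP is a single one, so `m/M`
  stochastically dominates `n/N` under the null. Two-sided rejections in
  that direction are not evidence for transport; the audit's verdict
  therefore leans on the one-sided test.
* Neighbour positions inherit their gene's expression level, so `n/N`
  and `m/M` values cluster by gene and are not independent samples —
  two-sample p-values are then miscalibrated. The null calibration in
  the test suite removes both effects (flat expression profile, and the
  concentrated error-bias mode in which every miscall lands on the
  transition partner, making the two statistics identically
  distributed); on real data the tests should be read as descriptive,
  not as exact p-values.

## Contamination and pseudo-heterozygosity

`contamination_regression()` fits ordinary least squares of the foreign
count at each SNP in the sampled tissue on the read depth at the same
SNP in the source tissue. A significant positive slope means a constant
proportion of the source transcriptome appears as foreign reads. The
package reports this as *contamination suspected*, never as established:
non-selective transport of the whole transcriptome is observationally
equivalent, and the report says so. The intercept is reported but not
constrained to zero; a through-origin slope is given alongside as the
proportional-model estimate. Because the regressor is itself a noisy
count, the slope is attenuated (errors in variables) — the attenuation
factor is roughly the between-site variance over itself plus the
counting noise, and the suite demonstrates it directly by regressing on
noisy versus latent depths. Recovery of the generator's contamination
constant is therefore assessed at moderate expression spread
(`expression_log_sd = 0.75`, `depth_dispersion = 0.02`, mean depth
~1000, where the bias is a few percent); at wide spreads with dispersed
depths the attenuation can exceed 20%, which is a property of OLS on
counts, not of the implementation.

`flag_pseudohet()` screens homograft sites with depth at least
`min_depth` whose alternative-allele fraction falls in
`fraction_band = [0.15, 0.85]` *and* whose binomial tail under the
background rate is below `1e-6`. The band is a package decision — wide
enough for copy-number ratios (1:2 through 2:1 and beyond) while
excluding both noise-scale fractions and fixed differences; the tail
condition prevents flagging when the background itself is high. A gene
is pseudo-heterozygous if any site is flagged;
`intersect_mobile_list()` crosses the flags with a published mobile
catalogue. In `run_audit()` the pseudo-het stage runs *before* the
contamination regression and its genes are excluded from the pairs:
pseudo-het loci carry large foreign counts unrelated to source
expression and would otherwise swamp the fit.

## The synthetic generator

`simulate_experiment()` produces a homograft and a heterograft pair
(root and shoot each) over a shared SNP map, with per-gene truth labels.
Mechanisms, applied per site and sample:

* depth `N ~ NegBin(mu = gene tissue expression, size = 1/dispersion)`,
  the expression itself log-normal per gene and tissue — the depth
  distribution is a modelling choice (no canonical form exists for it),
  picked to reproduce RNA-seq's depth spread and the read-depth
  dependency of false calls;
* foreign count `n ~ Binomial(N, e/3 + (1 − e/3 − e)·phi)`, where `phi`
  is 0 for noise genes, the mobile level for mobile genes (heterografts
  only), `c·src/(loc + c·src)` for contaminated genes, and the
  pseudo-het level in **both** graft types for pseudo-het genes;
  miscalls landing on the remaining nucleotides populate the "other"
  counts;
* neighbour positions receive pure error at the same depth
  distribution;
* multi-SNP reads draw the molecule origin once per read, then per-base
  errors independently — so transport makes whole reads foreign while
  error makes single bases foreign.

Transport and contamination are deliberately the *same* arithmetic with
different provenance labels, because count data cannot distinguish
them; only the truth table keeps them apart, which is what makes power
studies possible. When `contamination_c > 0`, every gene that is
neither mobile nor pseudo-heterozygous receives the contamination
mechanism — contamination is transcriptome-wide by nature, so it is not
rationed by a separate fraction parameter. Miscalls are uniform over
the three non-template nucleotides by default (`q = e/3`); the
`concentrated` mode sends every miscall to the transition partner
(and makes SNP alleles transitions), emulating reverse-transcription
bias and providing the exact-null regime used for calibration.

Reproducibility: a single `rng_seed` drives everything through derived
per-stage substreams (`seed + k·10007 mod 2^31 − 1` for stage `k`), so
equal seeds give identical datasets and byte-identical fixture files
from `write_fixture()`.

Defaults are chosen to emulate a bulk graft RNA-seq experiment at desk
scale: 0.3% base error (mid-range for short-read RNA-seq), log-normal
expression around 100 reads per site with unit log-sd, negative-binomial
dispersion 0.1, three SNPs per gene. What the generator does **not**
emulate: alignment and mapping artefacts (mismapping enters only through
the pseudo-het abstraction), positional error profiles along reads,
library-preparation batch effects, UMI structure, and genome-assembly
incompleteness. Passing calibration here shows the statistics behave as
designed under their own assumptions — not that those assumptions hold
for any particular real dataset.

## Numerical choices and degenerate inputs

* `binomial_tail()` delegates to the regularised incomplete-beta tail
  (`pbinom(..., lower.tail = FALSE)`), verified against exhaustive
  term-by-term enumeration to 12 significant digits; `m = 0` returns 1
  and `m = N + 1` returns 0 exactly.
* Beta-binomial marginals run entirely in log-gamma space and stay
  finite to `N = 1e7`; the suite checks them against adaptive quadrature
  restricted to the posterior's `[1e-13, 1 − 1e-13]` quantile interval
  (which keeps prior endpoint singularities out of the integrand) to 8
  significant digits.
* Zero-depth sites are retained and flagged, never silently dropped;
  zero-depth samples raise errors where a rate is undefined.
* The exact KS computation is used while the combined sample size
  permits it, with an explicit message when falling back to the
  asymptotic distribution.
* Percentages are formatted at two significant figures by default and
  two decimals on request, matching the two reporting styles in common
  use; all underlying fractions are kept at full precision.

## Problem sizes in the shipped tests

The calibration suite runs a 2,000-gene pure-noise experiment for the
false-call model, 600 genes for Bayes-factor power (about 100 truly
mobile genes at pooled depth over 1,000), 700 genes / over 2,000 SNP
pairs for contamination recovery, 300 genes for pseudo-het sensitivity,
and 200 seeded replicates of a 60-gene null for p-value uniformity —
sizes at which every binomial tolerance in the suite is comfortably
resolvable while the whole suite stays quick on one CPU.

## Known limitations

* The audit assumes bi-allelic SNPs; multi-allelic records are skipped,
  counted and reported, not decomposed.
* Strand is ignored: counts are used exactly as the upstream pileup
  reports them.
* The Bayes factor's unconstrained alternative is two-sided in the rate
  difference; a truncated one-sided variant would be slightly more
  powerful for transport but loses the closed form.
* The distribution tests' p-values assume independent values; gene-level
  depth clustering on real data violates that (see above).
* The contamination slope inherits OLS attenuation on noisy regressors;
  treat it as a lower bound on the proportion.
* Nothing here validates transport mechanistically — the package can
  only say whether the sequencing data *require* a foreign component, or
  are explained without one.
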