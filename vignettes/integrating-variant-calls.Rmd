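---
title: "Integrating SNP call sets with a latent class model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating SNP call sets with a latent class model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varlca)
```

## The model and its assumptions

`varlca` treats the integration of SNP call sets as a latent class problem.
Every assayable position (of `T` total) carries an unobserved binary label:
true variant, with background probability $\theta$, or non-variant. Each of
the $r$ evidence sources — a variant caller's VCF, or a database export such
as dbSNP treated identically — is a binary rater characterised by a
false-negative rate $\beta_i$ and a false-positive rate $\alpha_i$.
Conditional on the latent label, sources call independently. The observable
data reduce to the counts $n_k$ of the $2^r$ agreement patterns
$x = (x_1, \dots, x_r)$, $x_i \in \{0, 1\}$, a multinomial with cell
probabilities

$$p_k = \theta \prod_i \beta_i^{1-x_i} (1-\beta_i)^{x_i}
      + (1-\theta) \prod_i \alpha_i^{x_i} (1-\alpha_i)^{1-x_i}.$$

Bayes' rule on the two classes gives each pattern a posterior probability of
being a true variant (`pattern_posterior()`); every union site inherits the
posterior of its pattern. There is deliberately no per-site covariate — two
sites called by the same combination of sources are exchangeable under this
model, whatever their QUAL fields say. Input quality scores are carried to
the output as provenance only.

Three assumptions matter:

1. **Conditional independence of sources.** Real callers share aligners,
   reference bias and coverage blind spots, so their errors correlate; the
   model will overstate the evidence of patterns that correlated sources
   jointly favour. Modelling inter-source error correlation is out of scope
   here (a residual-correlation penalty is the natural extension).
2. **A single error profile per source.** Error rates do not vary with
   depth, region class or allele frequency.
3. **A known assayable total `T`.** The likelihood needs the count of
   positions called by nobody, which no VCF contains. `T` is therefore a
   required input (`total_positions`), and the single most consequential
   parameter a user sets: the all-zero cell `T − |union|` anchors
   $\theta$ and, through it, the scale of all $\alpha_i$. Set it to the
   callable-target size — an exome capture footprint, the confidently
   callable genome — not to a number vastly larger than the region actually
   assayed. The default (3e9, human whole-genome scale) is a fallback, and
   every report prints the `T` and all-zero count actually used. In
   practice the *ranking* of patterns by posterior is fairly insensitive to
   moderate changes in `T`; the absolute posteriors are not.

## Estimation

All parameters carry conjugate $\mathrm{Beta}(1, 2)$ priors — proper,
mildly favouring small rates, and adding one pseudo-miss and two pseudo-hits
of regularisation, which keeps every estimate strictly inside $(0,1)$ even
for degenerate tables.

`fit_lca_gibbs()` implements the exact conjugate scheme directly (no
external MCMC engine): each sweep (1) splits each $n_k$ into latent
true/false counts with a binomial draw at the current pattern membership
probability, (2) draws $\theta$ from its Beta full conditional, and
(3) draws each $\alpha_i, \beta_i$ from theirs. Defaults: 120,000
iterations, 20,000 burn-in, thinning 10 — roughly 10,000 retained draws,
whose Monte-Carlo error is far below the reporting precision for tables of
this size (the sampler scales with $2^r$, not `T`, so the defaults are cheap
even at genome scale). Point estimates are posterior means of retained
draws; central 95% percentile intervals and an autocorrelation-based
effective sample size are reported per parameter.

Two numerical choices guard the sampler:

* **Initialisation** is moment-style: $\theta_0 = |union|/T$,
  $\alpha_i^0 = (\text{sites unique to } i)/T$,
  $\beta_i^0 = 1 - (\text{sites in } i)/|union|$, clipped to
  $[10^{-6}, 1-10^{-6}]$. This starts on the intended side of the mode.
* **Label switching.** The two-class model is invariant under swapping the
  classes ($\theta \to 1-\theta$, $\alpha \leftrightarrow 1-\beta$). We
  impose the constraint that the true class is the better-detected one
  (mean of $1-\beta_i$ at least mean of $\alpha_i$) and relabel violating
  draws; the relabel count is reported and should be zero on identifiable
  data. With a single source the constraint cannot bite and the model is not
  identifiable — `fit_lca_gibbs()` refuses `r = 1`.

`fit_lca_em()` maximises the same multinomial likelihood by EM from the same
start; its observed-data log-likelihood is non-decreasing by construction
and it converges in a few hundred iterations on typical tables. It serves as
a fast fit and as an independent check: on well-identified tables the Gibbs
posterior means and the EM maximum agree to a few percent (the prior
contributes only three pseudo-counts), and the test suite asserts this
agreement on a four-caller table with 200,000 positions.

A statistical note on interval checks: with tables this informative the 95%
intervals are tight (a few percent relative), and a single simulated
realisation's empirical frequencies sit ~2 posterior standard deviations
from the generating values for some parameter fairly often — joint coverage
of nine 95% intervals at one realisation is only $\approx 0.95^9 \approx
0.63$. Tests of estimator correctness therefore assert point recovery and
4-sd bounds per realisation, and near-nominal *pooled* interval coverage
across a parameter grid, rather than all-intervals-cover at a single seed.

## Posterior filtering

`integrate_calls()` filters the union at a posterior cutoff, default 0.8;
0.9 buys extra specificity at a small sensitivity cost. The comparison is
inclusive (`posterior >= cutoff`, with a $10^{-9}$ guard), so cutoff 0
returns exactly the union, and cutoff 1.0 returns the sites whose posterior
rounds to 1 within $10^{-9}$ — with strictly interior parameters usually the
empty set, approaching the all-caller intersection. Since call sets at
increasing cutoffs are nested, the call count and the sensitivity against
any truth set are non-increasing in the cutoff, exactly; the empirical
precision is non-decreasing *in expectation* only, so evaluation code should
expect tie-level violations within binomial noise.

Posterior evaluation is done in log space and mapped back through a stable
logistic; the test suite checks agreement with naive arithmetic to
$10^{-12}$ relative across random parameter draws, including rates at
$10^{-6}$. Probabilities serialised in reports are clipped to
$[10^{-15}, 1-10^{-15}]$ so logged values stay finite. Parameters exactly on
the boundary $\{0, 1\}$ are rejected rather than silently clipped — the
fitters never produce them.

## Site matching and VCF handling

* **Keying.** Sources are matched on the full `(chrom, pos, ref, alt)` key
  by default: two callers asserting different ALT alleles at one position
  are not corroborating each other. `match_by = "position"` relaxes to
  `(chrom, pos)` for compatibility with position-level agreement
  tabulations; there the first asserting source's alleles are carried.
* **FILTER.** All records are ingested regardless of FILTER by default
  (comparing a filtered and an unfiltered view of the same caller is a
  legitimate use); `pass_only` restricts to `PASS`/`.`.
* **Multiallelic records** split into one key per ALT allele — each ALT is
  a separate assertion. Non-SNP alleles (indels, MNPs, symbolic) are
  skipped with a per-source tally.
* **Chromosome names** are never normalised. When inputs plainly disagree
  ("chr1" vs "1", or disjoint vocabularies) a loud warning lists each
  source's chromosome vocabulary, because silently matching nothing is the
  worst failure mode.
* Coordinates are VCF-native 1-based throughout; BED input for region
  stratification is converted explicitly from its 0-based half-open
  convention at the single point of use (`in_regions()`).

## The synthetic generator

`simulate_call_sets()` draws data from exactly the generative process the
model assumes: independent Bernoulli truth at rate $\theta$ per position on
one artificial contig, then independent per-source calls at rates
$1-\beta_i$ (true positions) and $\alpha_i$ (false positions). Alleles are
assigned per position so that transitions outnumber transversions 2:1 among
true variants and 1:2 among false positives — the canonical values for real
human SNPs and for uniform-random artefacts — which makes the Ti/Tv
specificity proxy meaningful on simulated data. All sources calling a
position report the same allele, so allele- and position-matching coincide
on simulated data by construction.

What the generator does **not** emulate: correlated errors between sources,
depth- or context-dependent error rates, clustered variants, multiallelic
sites, genotype calls. Passing tests on simulated data therefore validate
the estimation and filtering machinery under the model's own assumptions;
they do not validate the conditional-independence assumption against real
callers.

The evaluation problem sizes are chosen to keep the whole suite inside a
coffee break while leaving binomial noise well below the tolerances being
asserted: the workhorse ensemble uses four sources over 200,000 positions at
$\theta = 0.01$ (about 2,000 true variants and 5,500 union sites), the
recovery grid uses 100,000 positions per cell, and full-length (120,000
iteration) chains are reserved for the acceptance checks while unit tests
use 6,000–24,000 iteration chains, which already mix thoroughly for these
conjugate conditionals.

## Degenerate inputs and edge cases

* Empty VCFs parse to empty sources (warning, not error); an empty union
  puts all `T` positions in the all-zero cell, and the fit falls back to
  the prior with appropriately wide intervals.
* `total_positions` smaller than the union is a hard error that prints both
  numbers.
* All sources agreeing everywhere drives all $\alpha_i, \beta_i$ toward the
  prior floor — agreement is evidence of quality under this model, which is
  precisely its blind spot for correlated callers (see above).
* Ti/Tv with zero transversions reports an undefined ratio with counts
  intact rather than infinity.
* Reports contain no timestamps; identical configuration and seed produce
  byte-identical artifacts, and per-chain seeds are derived
  deterministically from the master seed.

## Somatic calls and databases

Combining somatic call sets from tumor/normal pairs is the same problem
with different inputs: pass the somatic callers' VCFs (and optionally a
COSMIC export) as sources. The model treats database sources identically to
callers — a database is simply a rater with its own error profile; the
`kind = database` label exists for reporting. For somatic work the
database-overlap specificity proxy (`fraction_in_database()`) replaces the
Ti/Tv proxy as the headline metric.

## Known limitations

SNPs only; site-level inference (genotypes are provenance, not data); no
inter-source error correlation; no per-site covariates; pattern tables are
dense, so $r \le 24$ sources. For very small `T` or a single source the
model is unidentifiable and the package says so rather than returning
plausible-looking numbers.
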