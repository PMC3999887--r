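# varlca

Unsupervised integration of SNP call sets by Bayesian latent class analysis.

## The problem

Variant callers disagree. Run GATK, FreeBayes, SAMtools and friends on the
same alignments and large fractions of the SNPs appear in only one output;
most callers expose only qualitative filters (`PASS`, `LowQual`), so there is
no principled way to trade sensitivity against specificity when merging
their outputs. Ad hoc fixes — take the union, the intersection, a majority
vote — either maximize sensitivity, or specificity, or neither, and none
yields a quantitative confidence per site. Supervised combiners need a
gold-standard truth set, which most projects (and most organisms) do not
have.

`varlca` is for anyone with two or more SNP call sets in VCF form — caller
outputs, or database exports such as dbSNP/COSMIC — who wants one integrated
call set with a posterior probability attached to every site, estimated from
nothing but the agreement structure of the inputs.

## The model

Each of the `T` assayable positions belongs to an unobserved class: true
variant, with probability θ, or non-variant. Each evidence source `i`
(of `r`) is a binary rater with a false-negative rate β<sub>i</sub>
(misses a true variant) and a false-positive rate α<sub>i</sub> (calls a
non-variant), conditionally independent across sources given the class.
The observed data are the counts n<sub>k</sub> of the 2<sup>r</sup>
agreement patterns x = (x₁, …, x_r) over all positions — the all-zero
pattern's count is `T` minus the union size, which is why `T` is a required
input. All parameters carry conjugate Beta(1, 2) priors and are estimated by
a Gibbs sampler (120,000 iterations, 20,000 burn-in by default); an EM
maximum-likelihood fitter for the same multinomial mixture is included as a
fast alternative and cross-check.

The posterior probability that a site with pattern x is a true variant is
closed-form Bayes:

    P(true | x) = θ ∏ᵢ βᵢ^(1-xᵢ) (1-βᵢ)^xᵢ
                  ─────────────────────────────────────────────────────────
                  θ ∏ᵢ βᵢ^(1-xᵢ) (1-βᵢ)^xᵢ + (1-θ) ∏ᵢ αᵢ^xᵢ (1-αᵢ)^(1-xᵢ)

Sites with posterior ≥ cutoff (default 0.8; 0.9 for higher specificity) are
written to the integrated VCF with `PPROB` and `SRCS` INFO tags.

## Worked example

Simulate three callers of known, unequal quality and recover everything:

```r
library(varlca)

sim <- simulate_call_sets(
  r = 3, theta = 0.02,
  alpha = c(0.005, 0.02, 0.001),   # false-positive rates
  beta  = c(0.10, 0.30, 0.20),     # false-negative rates
  total_positions = 50000, seed = 7
)

counts <- pattern_counts(sim$sites, total_positions = 50000)
counts
#>   pattern     n
#> 1 000     47758
#> 2 001        71
#> 3 010       966
#> 4 011        60
#> 5 100       309
#> 6 101       206
#> 7 110       123
#> 8 111       507

fit <- fit_lca_gibbs(counts, seed = 7)
fit
#> Latent class fit (Gibbs), 3 sources, T = 50,000
#>   retained draws: 10000  relabel corrections: 0
#>   parameter source      mean       sd    lower   upper   ess
#> 1 theta     <NA>    0.0197   0.000700 0.0183   0.0211  10000
#> 2 alpha1    caller1 0.00545  0.000390 0.00471  0.00623 10000
#> 3 alpha2    caller2 0.0196   0.000627 0.0184   0.0208  10000
#> 4 alpha3    caller3 0.000995 0.000195 0.000624 0.00139 10000
#> 5 beta1     caller1 0.106    0.0131   0.0819   0.133   10000
#> 6 beta2     caller2 0.289    0.0169   0.257    0.323   10000
#> 7 beta3     caller3 0.189    0.0159   0.158    0.221   10000
```

Every generating value is recovered (compare `mean` to the simulation
parameters above; `lower`/`upper` are central 95% credible bounds). The
per-pattern posteriors show how corroboration works — one caller is rarely
enough, any two usually are, and which two matters:

```r
posterior_table(fit)
#>   pattern n_sources posterior
#> 1 000             0  0.000119
#> 2 001             1  0.339          # the precise caller3 alone
#> 3 010             1  0.0144         # the noisy caller2 alone
#> 4 011             2  0.984
#> 5 100             1  0.155
#> 6 101             2  0.999
#> 7 110             2  0.958
#> 8 111             3  1.000

calls <- integrate_calls(sim$sites, fit, cutoff = 0.8)
nrow(calls)                              # 896 integrated calls
sensitivity_vs_truth(calls, sim$truth)   # 91.7 % of true variants recovered
titv_ratio(calls)$ratio                  # 2.12 — near the true-SNP value 2
write_integrated_vcf(calls, "integrated.vcf", fit = fit, cutoff = 0.8)
```

The same pipeline runs in one call (`run_integration()`) or from the shell:

```sh
exec/varlca run --vcf gatk=gatk.vcf --vcf fb=freebayes.vcf --db dbsnp=dbsnp.vcf \
  --total-positions 3e9 --cutoff 0.8 --seed 1 --out-vcf integrated.vcf
```

`total_positions` is the assayable-region size (exome footprint, callable
genome, …). It supplies the unobservable "called by nobody" cell of the
agreement table; always set it to your target size rather than trusting the
whole-genome default.

## Limitations

SNPs only (no indels/MNPs/SVs); site-level, not genotype-level; sources are
assumed conditionally independent given the truth — callers sharing error
modes (same aligner, same low-coverage blind spots) violate this and inflate
posteriors for patterns they jointly favor. See the methods vignette
(`vignettes/integrating-variant-calls.Rmd`) for the full model discussion.
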