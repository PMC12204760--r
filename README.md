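# RNAfrac

Estimating nucleo-cytosolic RNA localization from matched whole-cell,
nuclear and cytosolic RNA-seq.

## The problem

Fractionated RNA-seq measures *relative* transcript abundances (FPKM)
within each compartment, but the sequencing depth of each library is
unrelated to how much RNA the compartment held, so nuclear and cytosolic
FPKMs cannot be compared directly. With a matched whole-cell library the
ambiguity disappears: molecule conservation plus the proportional read
model imply, for every transcript i,

    FPKM_w(i) = (1 - beta) * FPKM_n(i) + beta * FPKM_c(i)

where beta is the fraction of total cellular RNA volume (nucleotides)
residing in the cytosol. RNAfrac estimates beta by Bayesian robust
regression with Student-t errors,

    FPKM_w(i) = (1 - beta) FPKM_n(i) + beta FPKM_c(i) + e_i,
    e_i ~ t(nu, 0, sigma),
    beta ~ Beta(2, 2),  nu ~ Gamma(2, 0.1),  sigma ~ Exp(1 / sd(FPKM_w)),

sampled with an in-package No-U-Turn sampler (4 chains x 6000 draws, 2000
warmup; MAP point estimate from a boundary-reflected kernel density of the
posterior draws). From beta, the localization index of transcript i — the
estimated proportion of its molecules in the cytosol — is

    LI(i) = beta * FPKM_c(i) / ((1 - beta) * FPKM_n(i) + beta * FPKM_c(i)).

The package also provides a box-constrained least-squares baseline,
preprocessing filters (CPM >= 1, mitochondrial removal, replicate
concordance, beta > 0.95 sample exclusion), a fractionated-transcriptome
simulator with known ground-truth beta, localization classification and
cross-sample consistency statistics, and hypergeometric enrichment tests
linking localization to splicing efficiency.

## Worked example

Two genes of equal length; in this cell type gene A has 40 nuclear / 60
cytosolic molecules and gene B has 20 / 180, so 80% of the RNA volume is
cytosolic (beta = 0.8). Sequencing each fraction to 1000 expected reads:

```r
library(RNAfrac)
lens <- c(1000, 1000)
fn <- fpkm_from_reads(expected_reads(c(A = 40, B = 20),  lens, 1000), lens, 1000)
fc <- fpkm_from_reads(expected_reads(c(A = 60, B = 180), lens, 1000), lens, 1000)

round(naive_li(fn, fc), 2)
#>    A    B
#> 0.27 0.69
localization_index(fn, fc, beta = 0.8)
#>   A   B
#> 0.6 0.9
```

The naive FPKM ratio (0.27) wrongly calls gene A preferentially nuclear;
the localization index with the correct beta recovers the true cytosolic
proportions (0.6 and 0.9) exactly.

A full simulate-then-estimate round trip:

```r
sim  <- simulate_fraction_dataset(sim_config(target_beta = 0.6, seed = 1))
fqs  <- filter_by_cpm(sim$fqs)
fpkm <- fraction_matrix(fqs, "fpkm")
post <- estimate_beta_bayes(fpkm[, "whole_cell"], fpkm[, "nuclear"],
                            fpkm[, "cytosolic"], beta_model_config(seed = 1))
post
#> BetaPosterior (4849 transcripts)
#>   MAP: 0.5988  mean: 0.5988  95% CI: [0.5931, 0.6046]
#>   R-hat(beta): 1.0016  ESS(beta): 2423  divergences: 0
```

(The simulated dataset's realized beta is 0.5996.)

## Command line

```sh
Rscript inst/cli/rnafrac.R simulate --beta 0.7 --seed 1 --out simdir
Rscript inst/cli/rnafrac.R estimate-beta --whole W.tsv --nuclear N.tsv \
    --cytosolic C.tsv --method bayes --seed 1 --out beta.json
Rscript inst/cli/rnafrac.R li --quant-set Q.tsv --beta 0.8 --out li.tsv
Rscript inst/cli/rnafrac.R run --config pipeline.cfg --out results/
```

Exit codes: 0 success, 2 input/format error, 3 model/diagnostic failure
(with `--strict`).

## Documentation

The methods vignette
(`vignettes/estimating-rna-localization.Rmd`) describes the model and its
assumptions, the simulator's stated world and what it deliberately omits,
numerical choices (MAP extraction, calibration bisection, degenerate
inputs) and known limitations.
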