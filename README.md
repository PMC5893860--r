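# rarecov

Abundance-weighted average coverage and sequence diversity of shotgun
metagenomes, estimated from read redundancy — no reference database needed.

## What it does, and for whom

For anyone running culture-independent sequencing studies (environmental,
host-associated or clinical), the first question about a metagenome is how
much of the community's DNA the sequencing actually captured. `rarecov`
answers it from the data alone:

1. **Redundancy**: for a random subset of query reads, count how many other
   reads each query is redundant with — either by exact occurrence of the
   query's 5′ *k*-mer (or its reverse complement) anywhere in the dataset
   (default, runtime ∝ dataset size), or by ungapped alignment at ≥ 95%
   identity over ≥ 50% of the query (the classical, slower definition).
   Sequencing errors in query *k*-mers are corrected using the Phred
   qualities: the expected number of erroneous *k*-mers,
   *E* = Σᵢ [1 − Πⱼ (1 − eᵢⱼ)], is removed from the zero-match tally.
2. **Rarefaction** (Turing–Good): at subsample fraction *p* a query with *m*
   matches is covered with probability 1 − (1−p)^m, giving a closed-form
   coverage-vs-effort curve over a logarithmic effort series.
3. **Model**: the curve is fitted to the gamma-CDF sigmoid
   *Ĉ* = γ[α, β ln(*LR* + 1)]/Γ(α), which yields the headline coverage at the
   actual sequencing effort, the projected effort for any target coverage
   (*LR*\* = exp(*Q*γ(t; α, β)) − 1), and the sequence-diversity index
   **Nd = (α − 1)/β** in natural-log bp — the log-effort position of the
   curve's inflection. Soil communities sit around Nd 22–24, open ocean
   20.5–21.8, animal hosts 18–20.

A seeded synthetic-community simulator with a closed-form Poisson coverage
oracle, and the OTU-side diversity estimators used to benchmark Nd (Shannon
H′, maximum-likelihood and Dirichlet-pseudocount; Turing–Good coverage of
OTU profiles), are part of the package, so every estimator is testable
offline.

## Worked example

```r
library(rarecov)

# a 10-genome community with lognormal abundances, sequenced to ~80% coverage
cm  <- make_community(10, c(20000, 50000), abundance_sigma = 1, seed = 4)
sim <- simulate_reads(cm, reads_for_coverage(cm, 0.8, 101), 101, seed = 5)

fit <- rarecov(sim$reads, q_target = 5000, seed = 6)   # or a FASTQ/FASTA path
summary(fit)
#> Gamma-CDF coverage model summary
#>   alpha = 48.2328, beta = 4.07536, SSE = 0.00253, points = 21, converged = TRUE
#>   coverage at actual effort (5.071e+05 bp): 0.7837 (raw final point 0.7584)
#>   Nd = 11.5899 ln-bp
#>   LR95: 2.599e+06 bp
#>   LR99: 1.039e+07 bp

expected_poisson_coverage(cm, length(sim$reads), 101)  # simulator ground truth
#> [1] 0.7999965
```

The fitted estimate (0.784) tracks the analytic truth (0.800); the package
estimated, from the reads alone, that ~78% of this community's DNA was
sequenced, that a 5× larger run (~2.6 Mbp) would reach 95% coverage, and that
the community has sequence diversity Nd ≈ 11.6 (a toy community — far below
any real environment). `plot(fit)` draws the rarefied points with the fitted
projection; `write_npo()`/`read_npo()` serialise curves to a self-contained
TSV that can be refitted later without the reads.

A thin command-line wrapper with `run`, `fit`, `simulate` and `otu`
subcommands is installed at `inst/scripts/rarecov-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/rarecov-cli.R", package="rarecov"))')" \
    run -i reads.fastq.gz -o sample1 --seed 1
```

It prints a single-line JSON summary
(`{"coverage":..., "Nd":..., "LR95":..., ...}`) on stdout and writes the
curve to `sample1.npo`.

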