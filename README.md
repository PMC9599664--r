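# sparsetrack

Sparse microbial source tracking with explicit unknown-source estimation.

## The problem

Given a **sink** microbiome sample (an OTU/ASV count vector) and a large panel
of candidate **source** samples, source tracking asks what fraction of the
sink's reads each source contributed. With modern repositories the candidate
panel can hold hundreds of samples of which only a handful truly contribute;
dense mixture estimators smear small positive weights across the many
non-contributing ("nuisance") sources and underestimate the part of the sink
that no observed source explains.

`sparsetrack` models the sink as a multinomial draw from a convex combination
of M candidate sources plus one aggregate **unknown** source:

    x  ~ Multinomial(C, β),   β_j = Σ_{i=1}^{M+1} α_i γ_ij
    Y_i ~ Multinomial(C_i, γ_i)            (observed candidate counts)
    α_1..M ~ Exp(λ) · 1{Σ_{i≤M} α_i ≤ 1}   (sparsity prior on known sources)

where α is the mixing-proportion vector (Σ α_i = 1, entry M+1 is the unknown)
and γ_i is source i's latent relative-abundance profile. Inference proceeds in
two stages:

1. **Screening** — an L1-penalized, simplex-constrained least-squares problem

       α̂ = argmin ‖Γᵀα − x/C‖² + λ‖α‖₁   s.t.  α ≥ 0, Σα ≤ 1

   over the observed profiles Γ selects the plausible contributors and the
   nonnegative residual initializes the unknown source's profile.
2. **Penalized EM** — for each λ on a grid, expectation-maximization refines
   (α, γ) under the exponential prior; the fit with the highest model
   likelihood is returned. The α update is solved exactly by 1-D dual root
   finding on the simplex; the objective ascends monotonically.

The package also ships the benchmark apparatus: a multinomial community
simulator (fixed-depth subsampling, Pareto-distributed sparse mixing vectors,
an appended unknown proportion of up to 90%, shuffled-abundance nuisance
sources) and the three evaluation metrics (MSE over known sources, absolute
error of the unknown, and the false positive rate — the total mass
misattributed to truly non-contributing sources).

## Worked example

```r
library(sparsetrack)

cfg <- simulation_config(n_taxa = 300, n_candidates = 15, n_contributing = 4,
                         unknown_prop = 0.3, n_sinks = 1, seed = 42)
ds  <- build_dataset(cfg)
fit <- track_sink(ds$problems[["Sink01"]])
fit
#> em_state: lambda = 0.01, 12 iterations (converged), loglik = -630107.760, unknown = 0.269
#> selected: Source01=0.004, Source02=0.005, ..., Source13=0.135, Source14=0.462, Unknown=0.269

round(ds$true_alpha[1, ds$true_alpha[1, ] > 0], 3)
#> Source05 Source10 Source13 Source14  Unknown
#>    0.057    0.032    0.142    0.469    0.300

evaluation_report(ds$true_alpha[1, ], fit$alpha)
#>           mse ae_unknown        fpr
#>  0.0004260057 0.03107965 0.03472029
```

The fit recovers the four true contributors (0.064/0.035/0.135/0.462 against
0.057/0.032/0.142/0.469), estimates the unknown fraction at 26.9% against a
true 30%, and leaves only ~3.5% total mass on the eleven nuisance sources.

File-based workflows use `track_files()` / `evaluate_files()`, or the
command-line wrapper:

```sh
Rscript inst/cli/sparsetrack.R simulate --out data --n-candidates 50 --n-sinks 30 --seed 1
Rscript inst/cli/sparsetrack.R track --counts data/counts.tsv --metadata data/metadata.tsv --out results
Rscript inst/cli/sparsetrack.R evaluate --estimates results/Sink01.tsv --truth data/truth.tsv --sink-id Sink01
```

Input formats: tab-delimited taxon-by-sample count tables (integer counts;
first header cell `TaxonID`, or `SampleID` with `--orientation samples_rows`)
and a metadata TSV with columns `SampleID`, `Env`, `SourceSink`
(Source/Sink, case-insensitive) and an optional `id` pairing column.

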