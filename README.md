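# phdeconv

Macrophages sense tissue acidification: dropping the environment from
pH 7.4 to pH 6.5 reshapes the LPS-driven inflammatory transcriptional
program gene by gene, and histidine-enriched disordered regions (as in
BRD4) can act as intracellular pH sensors by gaining positive charge when
pH falls. `phdeconv` provides a tested R implementation of the two
computational analyses behind this biology, for computational biologists
working with four-condition (±LPS × pH 7.4/6.5) expression data or
proteome-wide sequence screens:

1. **Expression-component deconvolution.** Per gene, the five pairwise
   condition contrasts stack into the linear model

   `Y = X β + ε`,  `β = (LPS, pH, INT)`

   where `Y` holds log2 fold changes (pseudocount 2) over replicate
   sets, `X` replicates the 5×3 contrast-loading matrix per set (10 rows
   and `df = 7` with two sets), and OLS solves exactly. Each component
   is tested against a *shifted null* — true magnitude ≤ 1.5-fold —
   via a one-sided t statistic `t = (β ∓ log2 1.5)/se` on `n − p`
   degrees of freedom, and genes are classified (|β| ≥ 2-fold,
   p < 0.05, R² > 0.8) into regulatory-logic groups and merged
   categories: pH-insensitive, pH-antagonistic, pH-synergistic, pH-only.

2. **pH-sensor screen.** Per protein, the histidine indicator is
   smoothed with a truncated unit-peak Gaussian (FWHM 5 residues,
   σ = 2.12, 20-residue span) giving a ΔCharge profile in histidine
   equivalents; peaks strictly above 1 are extended ±50 residues, gated
   on per-side disorder scores (> 0.3, either side suffices), and ranked
   by a proline/glutamine enrichment score. Residue arithmetic for
   condensate IDRs (longest H run, H→A mutants, net charge,
   composition enrichment, Henderson–Hasselbalch protonation) is exposed
   directly.

A synthetic-data module (`simulate_expression()`, `simulate_proteome()`,
`synthetic_brd4()`) plants known components and motifs so every stage is
validated against ground truth, offline.

## Worked example

```r
library(phdeconv)

sim <- simulate_expression(n_genes = 2000, seed = 1)   # planted truth
res <- run_deconvolution(sim$matrix, normalize = FALSE, prefilter = FALSE)
table(res$category)
#>           other pH_antagonistic  pH_insensitive         pH_only  pH_synergistic
#>               4             375             390             193             204
#>      unassigned
#>             834
mean(res$category == sim$truth$category)
#> [1] 0.988
```

At the default noise (sd 0.25 log2 units) 98.8% of the 2000 genes land in
their planted category; the `unassigned` block is mostly the 40% planted
null genes. One antagonistic gene's row shows the fitted components —
LPS activation (+2.1 log2) opposed by a negative interaction (−1.6),
with shifted-null p-values and the per-gene fit R²:

```r
res[8, c("beta_LPS", "beta_pH", "beta_INT", "p_LPS", "p_INT", "r2", "category")]
#>   beta_LPS  beta_pH  beta_INT    p_LPS     p_INT    r2        category
#> 8     2.12   -0.227     -1.58  2.4e-09   2.5e-07 0.997 pH_antagonistic
```

Screening the packaged synthetic BRD4-like stand-in (a code-built
1400-residue protein carrying the published sequence features — not the
real BRD4 sequence) finds both planted HPQ regions:

```r
b <- synthetic_brd4()
prot <- data.frame(accession = b$accession, description = b$description,
                   sequence = b$sequence)
sidecar <- data.frame(protein_id = b$accession, position = 1:1400,
                      score = b$disorder)
screen_proteome(prot, disorder = sidecar)
#>   accession peak_pos delta_charge start  end disordered pq_score net_charge
#> 1   SYNBRD4      723         4.44   673  773       TRUE     5.20          0
#> 2   SYNBRD4     1006         1.07   956 1056       TRUE     5.09          0
#> 3   SYNBRD4     1031         1.00   981 1081       TRUE     5.09          0
#> 4   SYNBRD4     1058         1.00  1008 1108       TRUE     5.09          0
```

The 6-histidine run at 721–726 peaks at 4.44 histidine equivalents; the
dispersed 9-histidine region around 1001–1080 yields weaker peaks just
above the strict ΔCharge > 1 threshold. All regions are disordered,
PQ-rich and carry zero net charge, the screen's candidate signature.

A three-subcommand CLI (`simulate`, `deconvolve`, `screen`) wraps the
same pipeline with JSON run summaries:

```sh
Rscript inst/scripts/phdeconv-cli.R simulate --type expression --n 5000 \
    --seed 1 --out sim/
Rscript inst/scripts/phdeconv-cli.R deconvolve --counts sim/counts.tsv \
    --design sim/design.tsv --no-normalize --out decon/
```

## Documentation

The methods vignette
(`vignettes/expression-deconvolution-and-ph-sensor-screen.Rmd`) explains
the model, the shifted-null test, every tunable with its default and
rationale, the synthetic-data assumptions, and known limitations.
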