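# uprflow

Transcriptome and growth-kinetics analysis for studies of the fungal
**unfolded protein response (UPR)**, built around the classic constitutive-UPR
experiment: a strain carrying a constitutively active (intron-less) allele of
the bZIP transcription factor HacA is compared against the wild type on
expression microarrays at several timepoints of a glucose batch culture.

The package is aimed at computational biologists who want a tested, fully
reproducible version of that analysis chain — or any microarray study with
the same shape — without assembling it from a dozen scripts:

1. **Probe summarization** — normal+exponential background correction
   (optional), quantile normalization across arrays, and Tukey median-polish
   summarization of perfect-match probes to probeset-level log2 expression.
2. **Differential expression** — empirical-Bayes moderated *t*-statistics.
   Per gene, the one-way fit gives group means and a pooled residual
   variance s²_g on d = n_arrays − n_conditions degrees of freedom. Log
   variances are shrunk toward a scaled inverse-χ² prior (d₀, s₀²), fitted by
   method of moments on z = ln s²_g via
   trigamma(d₀/2) = var(z) − trigamma(d/2), and each contrast is tested with

       t̃_g = (x̄_A − x̄_B) / √( s̃²_g (1/n_A + 1/n_B) ),
       s̃²_g = (d₀ s₀² + d s²_g) / (d₀ + d),

   on d₀ + d degrees of freedom, with Benjamini–Hochberg FDR control at
   q < 0.005 and no fold-change filter. Linear fold changes use the signed
   convention (−2ˣ for 2ˣ-fold down-regulation).
3. **Set consistency** — Venn partitions of up/down sets across timepoints
   and the genes consistently regulated at every timepoint.
4. **UPRE motif enrichment** — 400 bp upstream windows, both-strand scanning
   for the degenerate HacA-binding consensus 5'-CAN(G/A)NTGT/GCCT-3'
   (IUPAC `CANRNTGKCCT`), and a one-sided Fisher exact test of
   over-representation among up-regulated genes.
5. **GO over-representation** — true-path propagation of annotations up the
   GO DAG, per-term one-sided Fisher tests, BH FDR at q < 0.05, and a
   transitive-reduction network of the enriched terms.
6. **Growth kinetics** — the specific growth rate μ as the OLS slope of
   ln(biomass) vs time (cumulative alkali addition works as a proxy after
   offset correction), detection of the exponential→linear phase shift by a
   continuous piecewise fit over a breakpoint grid, and the biomass yield on
   substrate Y_xs = ΔX/(−ΔS).

Every input the pipeline consumes can also be *generated* with known ground
truth (planted differential expression, planted promoter motifs, a planted
enriched GO term, two-phase culture curves), so each stage is testable
end-to-end against the truth that produced its input.

## Worked example

```r
library(uprflow)

design <- default_design()                       # 3 replicates x {WT, CA1, CA2, CA3}
sim  <- generate_probe_data(design, n_genes = 300, de_fraction = 0.1, seed = 1)
expr <- summarize_expression(sim$probes)         # quantile norm + median polish
res  <- de_analysis(expr, design)                # moderated t, BH q < 0.005
print(res)
#> Moderated-t differential expression (q < 0.005 )
#> prior: d0 = 44.01451  s0^2 = 0.04208576
#>   contrast up down total
#> 1   CA1-WT 15   15    30
#> 2   CA2-WT 15   15    30
#> 3   CA3-WT 15   15    30

cs <- consistent_de_sets(res$tables)             # regulated at all timepoints
prom <- generate_promoters(n_genes = 300, planted_genes = cs$up_all$members,
                           seed = 2)
enr <- motif_enrichment(prom$promoters, cs$up_all)
#> UPRE-positive in set: 15 of 15; one-sided p = 1.06e-22

cult <- generate_culture(noise_cv = 0.03, seed = 3)
growth_kinetics(cult$culture)
#> growth_fit: exponential-then-linear
#>   mu = 0.2205 1/h (se 0.0009, R^2 0.9997)
#>   t_break = 21.00 h, linear rate = 0.3515 g_DW/kg/h
#>   Y_xs = 0.5641 g/g
```

The 300-gene simulation plants 30 differentially expressed genes (log2
effect ±2 in all three CA conditions); the moderated-t stage recovers the 15
up- and 15 down-regulated genes at q < 0.005 with no false calls. The
culture fit recovers the generating kinetics (μ = 0.22 h⁻¹, shift at 21 h)
from 3%-noise observations.

The enrichment statistic applied to a published UPRE contingency table — 47
motif-positive genes among 598 up-regulated promoters against 457 among
13156 remaining genes — gives

```r
fisher_exact_one_sided(47, 551, 457, 12699)
#> p = 6.44e-07, odds ratio = 2.37
```

A thin command-line wrapper with subcommands (`demo`, `run`, `summarize`,
`de`, `venn`, `upre-scan`, `go-enrich`, `kinetics`) is installed at
`exec/uprflow.R`; `Rscript <path>/uprflow.R demo --out demo_run --seed 42`
runs the all-synthetic end-to-end demonstration and writes a checksummed
manifest.

## Documentation

The methods vignette (`vignettes/upr-pipeline.Rmd`) describes the
statistical models, the synthetic-data generators and their calibration,
numerical choices, and known limitations.
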