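# crustassembly

Quantitative inference chain for soil (and biocrust) microbiome surveys,
linking four analyses that are usually run separately:

1. **Eco-enzymatic stoichiometry** — from seven hydrolase activities
   (AG, BG, XS, CB for carbon, NAG, LAP for nitrogen, AP for phosphorus),
   the log-ratio indices `ln(BG)/ln(LAP+NAG)`, `ln(BG)/ln(AP)`,
   `ln(LAP+NAG)/ln(AP)`, and the allocation vector
   `x = (BG+CB)/(BG+CB+AP)`, `y = (BG+CB)/(BG+CB+NAG+LAP)`,
   `length = sqrt(x² + y²)`, `angle = atan(y/x)`; vector length indexes
   relative C limitation, angles < 45° indicate N limitation and > 45°
   P limitation, with the quadrant scatter as a second classifier.
2. **Community structure** — abundant (> 1% mean relative abundance) /
   rare (< 0.1%) taxon partitioning, copiotroph:oligotroph ratios, Shannon
   diversity, Bray–Curtis PCoA and PERMANOVA.
3. **Community assembly** — abundance- or incidence-based βMNTD, βNTI
   against a taxa-shuffle null over the regional phylogeny, Raup–Crick with
   Bray–Curtis, and the five-process partition (heterogeneous / homogeneous
   selection at |βNTI| > 2; dispersal limitation / homogenizing dispersal at
   |RC| > 0.95; undominated otherwise), plus Mantel tests against soil
   variables.
4. **Co-occurrence networks** — Pearson correlations of log counts,
   a random-matrix-theory threshold (smallest cutoff whose eigenvalue
   spacing distribution becomes Poisson), topology and module composition,
   and per-sample network-complexity z-scores regressed on enzyme ratios.

A synthetic-data module generates phylogenies, communities under five named
assembly regimes, soil metadata and enzyme activities with recorded ground
truth, so the whole chain is testable end to end without any downloads. See
`vignettes/methods.Rmd` for the models, parameter defaults and their
rationale.

## Worked example

```r
library(crustassembly)

# a 20-sample community assembled under dispersal limitation, with
# phosphorus-limited enzyme profiles
bundle <- simulate_bundle(regime_spec("dispersal_limitation", seed = 11),
                          limitation = "P")

enzyme_limitation(bundle$enzymes) |>
  dplyr::count(vector_call)
#> # A tibble: 1 × 2
#>   vector_call     n
#>   <chr>       <int>
#> 1 P_limited      20

pairs <- assembly_pairs(bundle$table, bundle$tree, n_null = 199, seed = 11)
assembly_fractions(pairs) |> dplyr::filter(n > 0)
#> # A tibble: 5 × 4
#>   group process                    n fraction
#>   <chr> <fct>                  <int>    <dbl>
#> 1 all   homogeneous_selection      3   0.0160
#> 2 all   dispersal_limitation     117   0.622
#> 3 all   homogenizing_dispersal    28   0.149
#> 4 all   undominated               40   0.213
#> 5 all   undefined                  2  NA
```

The modal process (`dispersal_limitation`, 62% of defined pairs) matches the
generating regime; the vector-angle classifier calls every sample
P-limited, matching the enzyme scenario. Each result type has `tidy()` /
`glance()` methods and a `plot_*()`/`autoplot()` companion
(`plot_enzyme_vectors()`, `autoplot()` on PCoA results, `plot_bnti()`,
`plot_assembly_fractions()`).

`run_pipeline(crust_config(...))` chains every stage from on-disk TSV/Newick
inputs (or a simulation spec) and writes per-stage TSVs plus a JSON
summary; `inst/cli/crust-assembly.R` is a thin command-line wrapper around
it.

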