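# dropscreen

Design, simulate and analyse droplet-based in vitro two-hybrid peptide
screens.

In a drop-based two-hybrid screen, a degenerate peptide library (for
example an NNK-randomised triad grafted onto a fixed scaffold) is
encapsulated in picolitre water-in-oil drops together with a coupled
transcription/translation system and a fluorogenic protein–protein
interaction readout. Template loading is Poisson: at a mean occupancy of
λ templates per drop, a fraction e<sup>−λ</sup> of drops is empty,
λe<sup>−λ</sup> carry exactly one template, and the rest carry two or
more. Drops whose fluorescence exceeds a fold-over-background threshold
are sorted, their cargo is amplified by RT-PCR, and deep sequencing of
the bright, dark and unsorted (input) pools identifies binders by
fold-enrichment of each variant's read frequency.

`dropscreen` provides the full loop as composable, tidyverse-style pieces:

- **Library design** — degenerate codon expansion (sense or antisense),
  variant enumeration with genotype multiplicities, template assembly,
  FASTA/TSV export (`library_design()`, `enumerate_library()`,
  `expected_variant_frequency()`).
- **Screen model** — Poisson occupancy, binder-hit expectations, drop
  volumes, encapsulation and fluorescence simulation, threshold sorting
  (`poisson_occupancy()`, `expected_binder_drops()`, `screen_config()`,
  `simulate_encapsulation()`, `sort_drops()`).
- **Readout simulation** — RT-PCR amplification with per-genotype
  log-normal bias, amplicon read simulation with substitution errors and
  degraded 3' qualities, FASTQ I/O (`amplify_pool()`,
  `simulate_reads()`, `write_fastq()`).
- **Sequence analysis** — adapter/quality trimming (running-sum
  algorithm), anchored codon extraction, frequency tables, fold
  enrichment with bootstrap confidence intervals (`trim_reads()`,
  `extract_codons()`, `tabulate_codons()`, `enrichment()`).
- **Planning and pipeline** — screen-design calculator and a
  deterministic end-to-end pipeline (`plan_screen()`, `run_pipeline()`),
  plus a thin command-line wrapper in `inst/scripts/dropscreen.R`.

All tabular results are tibbles; enrichment tables support
`tidy()`/`glance()` and `autoplot()`.

## Worked example

An NNK×NNK×NNK triad on a 12-residue scaffold encodes 20³ = 8000
peptides across 31³ stop-free genotypes:

```r
library(dropscreen)

design <- library_design()       # NNK triad at scaffold positions 3, 7, 10
enumerate_library(design)
#> # A tibble: 8,000 × 4
#>    peptide full_peptide n_genotypes expected_freq
#>    <chr>   <chr>              <int>         <dbl>
#>  1 AAA     TSAAEYANLASP           8      0.000269
#>  2 AAC     TSAAEYANLCSP           4      0.000134
#>  3 AAD     TSAAEYANLDSP           4      0.000134
#>  # … with 7,997 more rows
```

Plan the screen: one-fold coverage of 8000 members at λ = 0.1 needs
80,000 drops (10 drops per molecule screened; 0.45% doublets), and a
3-million-drop screen is expected to contain about 38 binder-bearing
drops:

```r
plan_screen(8000, lam = 0.1)
#> # A tibble: 1 × 6
#>   n_library   lam target_coverage drops_required doublet_fraction
#>       <dbl> <dbl>           <dbl>          <dbl>            <dbl>
#> 1      8000   0.1               1          80000          0.00452

expected_binder_drops(n_drops = 3e6, lam = 0.1, n_library = 8000)
#> # A tibble: 1 × 6
#>   n_drops   lam n_library expected rounded drops_per_hit
#>     <dbl> <dbl>     <dbl>    <dbl>   <dbl>         <dbl>
#> 1 3000000   0.1      8000     37.5      38         80000
```

Simulate a full screen of one million drops with one high-affinity
member (the FWL triad) and a 1.3-fold brightness threshold, then rank
variants by bright/input fold-enrichment:

```r
cfg <- screen_config(design = design, n_drops = 1e6, lam = 0.1,
                     threshold = 1.3, binders = "FWL", seed = 20160304)
run <- run_pipeline(cfg)
run
#> <screen_run> 1000000 drops at lam = 0.1 (seed 20160304)
#>   bright drops: 17 (fraction 1.72e-05; occupied-drop fraction predicted 0.0952)
#>   top enriched peptide: FWL (9415-fold)

head(tidy(run$enrichment), 5)
#> # A tibble: 5 × 7
#>   peptide freq_bright freq_dark freq_input   fold  rank flag
#>   <chr>         <dbl>     <dbl>      <dbl>  <dbl> <int> <chr>
#> 1 FWL         0.950   0.0000633  0.000101  9415.      1 ok
#> 2 FCL         0.00351 0.0000633  0.0000126  279.      2 ok
#> 3 VVC         0.0140  0.000190   0.0000631  222.      3 ok
#> 4 FWQ         0.00100 0.0000633  0.0000126   79.6     4 ok
#> 5 LWL         0.00464 0.0000633  0.0000757   61.4     5 ok
```

A bootstrap confidence interval on the designated binder's bright/input
ratio confirms the enrichment is significant:

```r
bright <- run$frequency_tables$bright
input  <- run$frequency_tables$input
enrichment_significance(
  count_focal = bright$per_peptide$count[bright$per_peptide$peptide == "FWL"],
  n_focal     = bright$n_reads_used,
  count_ref   = input$per_peptide$count[input$per_peptide$peptide == "FWL"],
  n_ref       = input$n_reads_used, seed = 1)
#> # A tibble: 1 × 5
#>   estimate lower  upper enriched undefined
#>      <dbl> <dbl>  <dbl> <lgl>    <lgl>
#> 1    9415. 5379. 25120. TRUE     FALSE
```

`plot_fluorescence()`, `plot_position_frequencies()` and
`autoplot()` on an enrichment table give the standard diagnostic plots.

## Further reading

The methods vignette (`vignettes/drop-screen-methods.Rmd`) documents the
generative model, its parameters and defaults, the numerical choices
(truncated fluorescence noise, running-sum trimming tie-breaks, shared
per-genotype amplification bias) and the model's known limitations.
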