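# createscan

Design, quantification and statistics for **pathway-scale deep scanning
mutagenesis** with trackable CRISPR editing cassettes.

Classical deep mutational scanning saturates one protein; extending it to a
whole metabolic pathway means designing thousands of single-residue edits
across many genes, delivering them with cassettes that couple a
genome-targeting gRNA to a homology-directed-repair template, and reading
each mutant's fate through the cassette itself, which doubles as a
sequencing barcode. Because genome editing at library scale is inefficient
(a few percent of cells), unedited "escaper" cells carry barcodes too, and
the statistics must separate real fitness signal from that noise.
`createscan` implements the full computational stack for experiments of
this shape, plus a ground-truth simulator to validate every stage.

## What it computes

* **Cassette design** — mutagenesis sites from a structure (all residues
  with a heavy atom within 6 Å of declared binding atoms), full codon
  saturation with preferred *E. coli* K-12 codons (20 designs per site,
  one synonymous, no stops), and 230-nt cassettes: 18-nt subpool primer,
  12-nt variant primer, 118-nt homology arm carrying the codon edit and a
  synonymous PAM-disrupting substitution, 35-nt promoter, 3-nt linker,
  20-nt spacer, 24-nt scaffold head.
* **Barcode quantification** — two-tier identity matching of merged
  amplicon reads: candidate hits at ≥ 95% identity over ≥ 150 aligned
  columns; counted only when the alignment spans the full cassette at
  identity > 99%.
* **Enrichment statistics** — per replicate *i*,
  `W_i = log2[(post_count/post_total) / (pre_count/pre_total)]` with
  post-selection zeros floored at 0.5 and pre-selection counts < 10 masked
  per replicate; replicates combine as the count-weighted average
  `W_avg = Σ C_i·W_i / Σ C_i`. Significance is called against the
  synonymous designs' score distribution: enriched iff
  `W_avg ≥ μ + 2σ` (depletion symmetric), with a seeded 20,000-resample
  bootstrap CI on `μ` and per-mutant condition-level p-values.
* **Genomic validation** — expected-variant databases per sequenced
  window, 100%-identity read matching, `fraction covered = 100·observed/w`
  and editing efficiency `Eff = (edit_reads/total_reads)/(w/16300)`.
* **Simulation** — a deterministic selection model (edited fraction ε
  grows as `(1+s)^g`, escapers as `(1+s_esc)^g`) with multinomial
  sequencing noise, presets for a paper-like dominant-winner regime and a
  neutral calibration regime, and closed-form true enrichments.

## Worked example

Simulate a small selection in which one transport gene's missense designs
carry a fitness advantage against an otherwise neutral 800-design library
(editing efficiency 10%, mildly beneficial escapers), then score it:

```r
library(createscan)

cfg <- sim_config("neutral", seed = 1,
                  epsilon = 0.1, generations = 8,
                  fitness = list(default = 0, by_gene = c(tra01 = 0.6)),
                  escaper_fitness = 0.1)
lib    <- simulate_library(cfg, cassettes = FALSE)
state  <- simulate_selection(cfg, lib$designs)
sim    <- simulate_reads(state, cfg)
scores <- score_library(sim$counts, sim$samples, lib$designs, seed = 1)

scores
#> scan_scores: 800 designs, 1 condition(s)
#>   selection: 800 scored, 204 enriched, 19 depleted
scores$null_models$selection
#> synonymous null: mu = -0.5666, sigma = 0.1397 (n = 40)
#> bootstrap 95% CI for mu: [-0.6101, -0.5251] (B = 20000, seed = 1)

res <- scores$results
head(res[order(-res$W_avg), c("design_id", "gene_id", "W_avg", "significant", "p_value")], 5)
#> # A tibble: 5 × 5
#>   design_id  gene_id W_avg significant  p_value
#>   <chr>      <chr>   <dbl> <lgl>          <dbl>
#> 1 tra01_A13K tra01    1.34 TRUE        1.17e-42
#> 2 tra01_A6S  tra01    1.33 TRUE        2.91e-42
#> 3 tra01_A6P  tra01    1.28 TRUE        2.70e-40
#> 4 tra01_N10P tra01    1.27 TRUE        7.75e-40
#> 5 tra01_Q5M  tra01    1.25 TRUE        4.28e-39

summarize_hits(scores, lib$genes[, c("gene_id", "category")])$by_category[,
  c("category", "n_scored", "n_enriched", "mean_score")]
#> # A tibble: 4 × 4
#>   category     n_scored n_enriched mean_score
#>   <chr>           <int>      <int>      <dbl>
#> 1 biosynthesis      200          5     -0.580
#> 2 degradation       200          4     -0.601
#> 3 regulation        200          5     -0.567
#> 4 transport         200        190      0.957
```

The transport gene's designs dominate the enriched set; every other
design's score is dragged negative because frequencies must sum to one —
the synonymous null absorbs exactly that compositional shift (its mean is
−0.57, not 0), which is why significance is called relative to `μ + 2σ`
rather than to zero. The handful of enriched designs in the neutral
categories (~2.5% of them) is the expected one-sided false-positive rate
of a 2σ threshold.

The design side works the same way from real inputs: `read_structure()` +
`select_shell_residues()` + `sites_from_cds()` give sites,
`saturate_sites()` the manifest, and `design_cassettes()` the 230-mers,
written out with `write_cassette_fasta()` / `write_manifest()`.

## Package layout

| file | contents |
|---|---|
| `R/design_shell.R`, `R/design_saturate.R`, `R/design_cassette.R` | site selection, codon saturation, cassette assembly |
| `R/quant.R` | read matching and count matrices |
| `R/enrich.R` | scores, weighted averages, null model, significance |
| `R/validate.R` | window variant databases, coverage, editing efficiency |
| `R/simulate.R` | configuration, library/selection/read simulation |
| `R/io.R`, `R/codon_usage.R` | CSV/FASTA interfaces, codon usage table |
| `vignettes/deep-scanning-pipeline.Rmd` | models, assumptions, parameter choices |
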