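---
title: "Pathway-scale deep scanning mutagenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-scale deep scanning mutagenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(createscan)
```

## The experiment this package models

Deep scanning mutagenesis maps genotype to phenotype by constructing
(nearly) every single amino-acid substitution in a region of interest and
reading out each variant's fitness under selection. `createscan`
implements the computational stack for the *pathway-scale* version of this
idea, in which trackable CRISPR editing cassettes couple a genome edit to
a plasmid-borne barcode:

1. **Design.** Mutagenesis sites are the residues within a distance shell
   (default 6 Å, heavy atoms, inclusive) of declared binding atoms in a
   protein structure. Each site is saturated with 20 designs — one per
   amino acid, encoded by that amino acid's most frequent codon in the
   *E. coli* K-12 genome — and each design becomes a 230-nt cassette:
   18-nt subpool primer + 12-nt variant primer + 118-nt homology arm
   (carrying the codon edit and a synonymous PAM-disrupting substitution)
   + 35-nt constitutive promoter + 3-nt linker + 20-nt gRNA spacer +
   24-nt scaffold head.
2. **Quantification.** After selection, merged amplicon reads of the
   plasmid cassettes are matched back to the design database; counts
   before and after selection measure each design's fate.
3. **Statistics.** Per-replicate log2 frequency-ratio scores are combined
   across biological replicates by a count-weighted average and compared
   against a null distribution built from the library's synonymous
   designs.
4. **Genomic validation.** Deep-sequenced amplicon windows over the
   targeted loci verify that edits actually reached the genome, yielding
   per-window coverage and an editing-efficiency estimate.
5. **Simulation.** A seeded generative model produces libraries, selection
   dynamics and read sets with known ground truth, so every stage above is
   testable end to end.

## Cassette design

`select_shell_residues()` keeps every protein residue with at least one
heavy atom within the shell radius (inclusive boundary) of any declared
binding atom. Hydrogens are excluded because their positions are
unreliable in crystal structures; hetero groups are never returned as
sites. The implementation is vectorised but is verified in the test suite
against a literal all-pairs distance loop.

`saturate_site()` emits exactly 20 designs per site and never a stop
codon. The design encoding the wild-type residue is the site's
*synonymous design* — the internal control that later anchors the null
distribution — and must be distinguishable from wild type, so when the
preferred codon *is* the wild-type codon the second most frequent codon is
substituted. Methionine and tryptophan have a single codon; a site whose
wild-type residue is M or W cannot carry an observable synonymous design
and is rejected with an error rather than silently under-controlled (the
simulator never places sites there).

The gRNA spacer is the 20-mer whose NGG PAM lies nearest the edited codon
on either strand (ties: `+` strand first, then smaller coordinate), with
PAM candidates restricted to the homology arm so the anti-re-cutting edit
stays on the repair template. `design_pam_kill()` prefers a synonymous
single-nucleotide change that destroys the NGG itself and falls back to
any synonymous change in the 10-nt seed adjacent to the PAM, nearest
first. The homology arm splits 58 nt left flank / 3-nt codon / 57 nt
right flank around the edit; the arm plus the fixed parts always total
230 nt, and assembly is invertible — reverting the codon edit and the PAM
kill reproduces the reference window exactly, which the tests exercise.

```{r}
site <- list(gene_id = "lysC", residue_index = 7, wt_aa = "T", wt_codon = "ACT")
saturate_site(site)[1:5, c("design_id", "target_aa", "target_codon", "is_synonymous")]
```

## Read matching: two tiers, one identity definition

Identity is matching columns divided by alignment columns; gap columns
count against identity. A read is aligned end-to-end while the cassette's
ends are free (a *fitting* alignment, linear gap penalty). This keeps the
two matching tiers meaningful:

* **candidate tier** — at least 95% identity over at least 150 aligned
  columns, at most 40 candidates retained, sorted by identity (ties to
  the lexicographically smallest design id);
* **counting tier** — the best hit increments its design's count only
  when the alignment spans the entire cassette and identity is *strictly*
  above 99% (so 2 substitutions over 230 columns count, 3 do not, and a
  truncated read can be a reported hit without ever being counted).

The production path delegates the alignment to
`Biostrings::pairwiseAlignment()` after an exact-equality fast path; the
test suite carries an independent quadratic dynamic-programming oracle
with the same scoring and requires byte-identical best-hit assignments on
mutated reads.

## Enrichment statistics

For design *d* in replicate *i*, with pre- and post-selection counts
\(c^{pre}_{di}, c^{post}_{di}\) and sample totals \(T^{pre}_i, T^{post}_i\)
(total matched reads of the sample),

\[ W_{di} = \log_2 \frac{c^{post}_{di} / T^{post}_i}{c^{pre}_{di} / T^{pre}_i}, \]

with post-selection zeros floored at 0.5 before the frequency step.
Designs with a pre-selection count below 10 are masked *in that replicate
only* (a count of exactly 10 passes). Replicates combine as the
count-weighted average

\[ W_{avg,d} = \frac{\sum_i C_{di} W_{di}}{\sum_i C_{di}}, \]

where the weight \(C_{di}\) is the replicate's pre-selection count by
default — it measures evidence available in both phases — with `"post"`
and `"pre+post"` available as configuration switches. A design passing
the filter in a single replicate gets that replicate's score (the formula
with \(N = 1\)).

The null is fit to the weighted scores of the synonymous designs: mean
\(\mu\), standard deviation \(\sigma\), and a bootstrap 95% confidence
interval for \(\mu\) from 20,000 resamples with replacement (seeded). A
design is *enriched* when \(W_{avg} \ge \mu + 2\sigma\) (inclusive), with
the symmetric depleted call reported separately; the p-value is the
one-sided upper normal tail at the score. When \(\sigma = 0\)
(degenerate null) the calls reduce to strict comparisons against
\(\mu\). Per-mutant condition-level p-values use a normal fit to all
scored designs in the condition by default; an empirical variant with
add-one smoothing \((\#\{x > w\} + 1)/(n + 1)\) is available, chosen so
the maximum observed score gets \(1/(n+1)\). No multiple-testing
correction is applied to the genome-wide map by default;
`p.adjust`-style correction can be layered on the returned tibble by the
caller.

## Genomic validation

`enumerate_expected()` builds, per sequenced window, the wild-type
sequence plus one full-window sequence per design whose codon edit and
PAM kill both fall inside the window; reads are matched at 100% identity
only (`match_window_reads()`), with wrong-length reads skipped under a
warning. A design counts as *observed* with a single exact-match read —
no read floor is applied. Coverage and efficiency follow

\[ \mathrm{covered} = 100 \cdot \frac{\mathrm{observed}}{w}, \qquad
   \mathrm{Eff} = \frac{\mathrm{edit\ reads} / \mathrm{total\ reads}}{w / L}, \]

with \(w\) the window's designed edits and \(L\) the library size
(default 16,300). Percentages are reported to one decimal to match how
such tables are conventionally printed.

## The selection simulator

`sim_config()` declares the generative model:

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.03 | probability a transformed cell is actually edited |
| `fitness` | all 0 | selection coefficient *s* per generation, by design/gene/category |
| `escaper_fitness` | 0 (0.2 in `paper_like`) | *s* of unedited barcode-carrying cells |
| `escaper_fitness_sd` | 0 | per-design, per-replicate jitter of escaper fitness |
| `generations` | 10 | generations of selective growth |
| `depth_pre`, `depth_post` | 2e5 (1e5 in `neutral`) | reads per sample |
| `error_rate` | 0 | per-base substitution rate at sequencing |
| `n_replicates` | 2 | biological replicates |

Each design's cell pool splits into an edited fraction (`epsilon`,
growing as \((1+s_d)^g\)) and an *escaper* fraction growing as
\((1+s_{esc})^g\). Selection is deterministic exponential growth on
expected abundances; stochasticity enters only at sequencing, as
multinomial draws at the configured depth with independent per-base
substitution errors. This keeps the ground truth closed-form
(`true_enrichment()`), which is what makes parameter-recovery tests
meaningful; a birth–death process is deliberately out of scope. Escaper
fitness may jitter across designs and replicates
(`escaper_fitness_sd`), modelling heterogeneous adaptive backgrounds —
this is what makes barcode scores decouple from genotype as `epsilon`
shrinks, the false-positive regime the test suite probes.

Two presets pin the regimes the package is tested in. `paper_like`
mirrors the studied pathway's shape: 19 genes (12 biosynthesis, 2
degradation, 3 transport, 2 regulation), 815 sites, 16,300 designs,
`epsilon = 0.03`, one high-fitness transport gene (`tra01`, *s* = 1 on
its missense designs) whose edited cells exceed 95% of the selected
edited population after 10 generations, and mildly beneficial escapers.
`neutral` is the calibration regime: 4 genes (one per category), 40
sites, 800 designs, every coefficient 0, depth 1e5, 2 replicates.

What the simulator emulates: the library-scale design census,
low editing efficiency with escapers, replicate structure,
dominant-winner takeover, synonymous scores centred at 0 under
neutrality. What it does not: cell-to-cell growth stochasticity, clonal
interference, oligo synthesis errors, chimeric reads, indel sequencing
errors, and condition (dose) series — so passing tests demonstrate the
pipeline's statistical behaviour under the declared model, not fidelity
to any particular wet-lab data set.

```{r, eval = FALSE}
cfg <- sim_config("neutral", seed = 1)
lib <- simulate_library(cfg)
state <- simulate_selection(cfg, lib$designs)
sim <- simulate_reads(state, cfg)
scores <- score_library(sim$counts, sim$samples, lib$designs, seed = 1)
summarize_hits(scores, lib$genes[, c("gene_id", "category")])$by_category
```

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive at every interface; internal
  arithmetic uses offsets where convenient.
* Shell membership, the count filter, and the \(\mu + 2\sigma\) call are
  all *inclusive* at their boundaries; the 99% counting identity is
  *exclusive*. These readings are pinned by tests.
* PAM-candidate and PAM-kill tie-breaks are fully deterministic (strand,
  then coordinate; PAM positions before seed positions; alternative
  bases in alphabetical order), so cassette design is reproducible.
* The bootstrap is chunked to bound memory at large synonymous counts
  and is reproducible from its seed; all simulator stages derive
  sub-seeds from `config$seed`, and two runs with the same seed are
  byte-identical.
* Degenerate cases error loudly rather than guess: empty binding sets,
  unpaired samples, empty samples, an all-identical synonymous null with
  \(\sigma = 0\) (handled, with 0/1 p-values), windows larger than the
  library, lethal coefficients \(1 + s \le 0\).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on simulated data
at sizes chosen to exercise every code path while staying quick on a
single CPU: the full 815-site/16,300-design roster for design-census and
dominance checks (without cassette assembly, which is exercised on
80-cassette libraries); 200 neutral runs at depth 1e5 for null
calibration; 50 seeds for recovery of an imposed 4-log2 enrichment; 200
mutated reads against the dynamic-programming oracle; and 20 seeds for
editing-efficiency recovery. These sizes are the package's own choices
and are stated here so they can be scaled up by users with more patience.

## Known limitations

* The spacer-selection heuristic (nearest PAM, deterministic
  tie-breaks) is a stated, reproducible rule — real gRNA pickers weigh
  activity and off-target scores that are out of scope here.
* Identity as defined here (terminal read columns always counted) can
  differ from other aligners' percent-identity conventions; counts on
  borderline reads may differ accordingly.
* The normal condition-density p-value is a convenience; score
  distributions under strong selection are heavy-tailed, and the
  empirical variant is the safer choice there.
* Paired-read merging, demultiplexing and quality trimming are upstream
  of this package: it consumes merged reads.
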