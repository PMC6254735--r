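#' Simulation configuration
#'
#' Declares every generative parameter of a synthetic deep-scanning
#' selection experiment. All randomness downstream flows from `seed`.
#'
#' Presets:
#' \describe{
#'   \item{`paper_like`}{19 genes / 815 sites (16,300 designs) across the
#'     four pathway categories, editing efficiency 3%, one dominant
#'     loss-of-function transport gene (`tra01`, s = 1 per generation on
#'     its missense designs), mildly beneficial escapers, 2 replicates,
#'     2e5 reads per sample.}
#'   \item{`neutral`}{4 genes / 40 sites (800 designs), all selection
#'     coefficients 0, no escaper advantage, 2 replicates, 1e5 reads per
#'     sample. Used for null-calibration studies.}
#' }
#'
#' @param preset `"custom"`, `"paper_like"` or `"neutral"`.
#' @param ... Overrides of the preset fields: `genes` (tibble with
#'   `gene_id`, `category`, `n_sites`), `epsilon` (per-cell editing
#'   probability), `fitness` (list with `default`, and optional named
#'   vectors `by_category`, `by_gene`, `by_design`; gene/category rules
#'   apply to missense designs only, `by_design` to any design),
#'   `escaper_fitness` (mean selection coefficient of unedited
#'   barcode-carrying cells), `escaper_fitness_sd` (per-design,
#'   per-replicate jitter of escaper fitness), `generations`, `depth_pre`,
#'   `depth_post`, `depth_genomic`, `error_rate` (per-base substitution
#'   probability at sequencing), `n_replicates`, `seed`.
#' @return A `sim_config` object (list).
#' @export
#' @examples
#' sim_config("neutral", seed = 7)
sim_config <- function(preset = c("custom", "paper_like", "neutral"), ...) {
  preset <- match.arg(preset)
  base <- list(
    genes = default_genes(preset),
    epsilon = 0.03,
    fitness = list(default = 0),
    escaper_fitness = 0,
    escaper_fitness_sd = 0,
    generations = 10,
    depth_pre = 2e5,
    depth_post = 2e5,
    depth_genomic = 1e5,
    error_rate = 0,
    n_replicates = 2L,
    seed = 1L
  )
  if (preset == "paper_like") {
    base$fitness <- list(default = 0, by_gene = c(tra01 = 1))
    base$escaper_fitness <- 0.2
  }
  if (preset == "neutral") {
    base$depth_pre <- 1e5
    base$depth_post <- 1e5
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg <- base
  cfg[names(over)] <- over   # whole-field replacement, no recursive merge

  cfg$genes <- as_tibble(cfg$genes)
  stopifnot(all(c("gene_id", "category", "n_sites") %in% names(cfg$genes)),
            cfg$epsilon >= 0, cfg$epsilon <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$generations > 0, cfg$n_replicates >= 1,
            cfg$depth_pre >= 0, cfg$depth_post >= 0)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  structure(cfg, class = "sim_config")
}

## gene rosters for the shipped presets; mirrors the studied pathway's
## shape: 12 biosynthesis, 2 degradation, 3 transport, 2 regulation genes
## and 815 sites in the full-scale roster
default_genes <- function(preset) {
  if (preset == "paper_like") {
    tibble(
      gene_id = c(sprintf("bio%02d", 1:12), "deg01", "deg02",
                  "tra01", "tra02", "tra03", "reg01", "reg02"),
      category = c(rep("biosynthesis", 12), rep("degradation", 2),
                   rep("transport", 3), rep("regulation", 2)),
      n_sites = c(rep(45L, 12), 40L, 40L, 25L, 30L, 30L, 55L, 55L)
    )
  } else {
    tibble(
      gene_id = c("bio01", "deg01", "tra01", "reg01"),
      category = c("biosynthesis", "degradation", "transport", "regulation"),
      n_sites = rep(10L, 4)
    )
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d sites, epsilon = %g, g = %g, %d replicate(s), seed = %d\n",
              nrow(x$genes), sum(x$genes$n_sites), x$epsilon, x$generations,
              x$n_replicates, x$seed))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose top-level keys are [sim_config()] fields
#'   (an optional `preset` key selects the base preset; `genes` may be a
#'   list of records).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "custom"
  y$preset <- NULL
  if (!is.null(y$genes)) y$genes <- dplyr::bind_rows(y$genes)
  if (!is.null(y$fitness)) {
    y$fitness <- lapply(y$fitness, function(v) if (is.list(v)) unlist(v) else v)
  }
  do.call(sim_config, c(list(preset = preset), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## flank carried on each side of a synthetic CDS; leaves room for homology
## arms and protospacers at terminal sites
SIM_FLANK <- 100L

## random CDS with sites at residues 5..(4 + n_sites); site codons avoid
## Met/Trp so every site admits a synonymous fallback design
simulate_gene <- function(gene_id, n_sites) {
  usage <- ecoli_codon_usage()
  sense <- usage[usage$aa != "*", ]
  site_pool <- sense[!sense$aa %in% c("M", "W"), ]
  n_res <- n_sites + 14L
  codons <- sample(sense$codon, n_res, replace = TRUE, prob = sense$per_1000)
  codons[1L] <- "ATG"
  site_res <- seq(5L, 4L + n_sites)
  codons[site_res] <- sample(site_pool$codon, n_sites, replace = TRUE,
                             prob = site_pool$per_1000)
  cds <- paste(codons, collapse = "")
  flank <- function() paste(sample(c("A", "C", "G", "T"), SIM_FLANK, replace = TRUE),
                            collapse = "")
  context <- paste0(flank(), cds, flank())
  list(gene_id = gene_id, cds = cds, context = context,
       cds_start = SIM_FLANK + 1L, cds_end = SIM_FLANK + nchar(cds),
       site_residues = site_res)
}

#' Simulate a saturation library
#'
#' Generates synthetic genes (random coding sequences with realistic codon
#' usage embedded in random genomic context), selects the configured number
#' of sites per gene, saturates each site with the 20 preferred-codon
#' designs, and (optionally) assembles the 230-nt cassettes. Fully
#' deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param cassettes Assemble cassettes (default `TRUE`; skip for
#'   statistics-only studies).
#' @return A `scan_library` object: list with `genes` (tibble incl.
#'   `context`, `cds_start`, `cds_end`, `category`), `sites`, `designs`
#'   and `cassettes` (or `NULL`).
#' @export
simulate_library <- function(config, cassettes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- list(); sites <- list(); cass <- list()
  for (i in seq_len(nrow(config$genes))) {
    g <- simulate_gene(config$genes$gene_id[i], config$genes$n_sites[i])
    gene_sites <- tibble(gene_id = g$gene_id, chain = "A",
                         residue_index = g$site_residues)
    gene_sites <- sites_from_cds(gene_sites, g$cds)
    genes[[i]] <- tibble(gene_id = g$gene_id,
                         category = config$genes$category[i],
                         context = g$context, cds = g$cds,
                         cds_start = g$cds_start, cds_end = g$cds_end)
    sites[[i]] <- gene_sites
  }
  genes <- dplyr::bind_rows(genes)
  sites <- dplyr::bind_rows(sites)
  designs <- saturate_sites(sites)
  cass_tbl <- NULL
  if (cassettes) {
    subpool <- make_primers(1L, 18L, seed = config$seed + 101L)
    variant <- make_primers(nrow(designs), 12L, seed = config$seed + 102L)
    cass_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
      sel <- designs$gene_id == genes$gene_id[i]
      design_cassettes(designs[sel, ], genes$context[i],
                       genes$cds_start[i], genes$cds_end[i],
                       subpool_primer = subpool,
                       variant_primers = variant[sel])
    }))
  }
  structure(list(genes = genes, sites = sites, designs = designs,
                 cassettes = cass_tbl),
            class = "scan_library")
}

#' @export
print.scan_library <- function(x, ...) {
  cat(sprintf("scan_library: %d genes, %d sites, %d designs%s\n",
              nrow(x$genes), nrow(x$sites), nrow(x$designs),
              if (is.null(x$cassettes)) " (no cassettes)" else ""))
  invisible(x)
}

## per-design selection coefficients from the config's fitness rules
resolve_fitness <- function(config, designs) {
  s <- rep(config$fitness$default %||% 0, nrow(designs))
  missense <- !designs$is_synonymous
  bc <- config$fitness$by_category
  if (!is.null(bc)) {
    cat_of <- setNames(config$genes$category, config$genes$gene_id)
    for (categ in names(bc)) {
      s[missense & cat_of[designs$gene_id] == categ] <- bc[[categ]]
    }
  }
  bg <- config$fitness$by_gene
  if (!is.null(bg)) {
    for (g in names(bg)) s[missense & designs$gene_id == g] <- bg[[g]]
  }
  bd <- config$fitness$by_design
  if (!is.null(bd)) {
    idx <- match(names(bd), designs$design_id)
    if (anyNA(idx)) stop("fitness assigned to unknown design(s)")
    s[idx] <- unname(bd)
  }
  s
}

#' Simulate selection on the library
#'
#' Deterministic exponential growth on expected abundances: every design
#' starts at equal abundance; a fraction `epsilon` of its cells is edited
#' (growing as `(1 + s_design)^g`) and the remainder are escapers -
#' unedited cells that keep the barcode plasmid and grow as
#' `(1 + s_escaper)^g`. Escaper fitness can jitter per design and
#' replicate (`escaper_fitness_sd`), modelling heterogeneous adaptive
#' backgrounds. Stochasticity enters only at sequencing
#' ([simulate_reads()]).
#'
#' @param config A [sim_config()].
#' @param designs Design tibble from [simulate_library()].
#' @param seed Seed (default derived from `config$seed`).
#' @return A `true_state` object: per-design pre abundances and
#'   edited/escaper decomposition, per-replicate post abundances, and the
#'   selection coefficients used.
#' @export
simulate_selection <- function(config, designs, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  D <- nrow(designs)
  R <- config$n_replicates
  s <- resolve_fitness(config, designs)
  if (any(1 + s <= 0)) stop("lethal coefficient out of range")
  g <- config$generations
  eps <- config$epsilon

  s_esc <- matrix(config$escaper_fitness, nrow = D, ncol = R)
  if (config$escaper_fitness_sd > 0) {
    s_esc <- s_esc + matrix(rnorm(D * R, 0, config$escaper_fitness_sd), D, R)
    s_esc <- pmax(s_esc, -0.95)   # keep growth factors positive
  }

  init <- rep(1 / D, D)
  edited_pre <- eps * init
  escaper_pre <- (1 - eps) * init
  edited_post <- edited_pre * (1 + s)^g                     # recycled per column
  edited_post <- matrix(edited_post, D, R)
  escaper_post <- escaper_pre * (1 + s_esc)^g
  tot <- colSums(edited_post + escaper_post)
  edited_post <- sweep(edited_post, 2L, tot, "/")
  escaper_post <- sweep(escaper_post, 2L, tot, "/")
  abund_post <- edited_post + escaper_post
  colnames(abund_post) <- colnames(edited_post) <- colnames(escaper_post) <-
    colnames(s_esc) <- paste0("rep", seq_len(R))

  structure(list(design_id = designs$design_id,
                 abund_pre = init, edited_pre = edited_pre,
                 escaper_pre = escaper_pre,
                 abund_post = abund_post, edited_post = edited_post,
                 escaper_post = escaper_post,
                 s = s, s_escaper = s_esc, generations = g, epsilon = eps),
            class = "true_state")
}

#' @export
print.true_state <- function(x, ...) {
  cat(sprintf("true_state: %d designs, %d replicate(s), epsilon = %g, g = %g\n",
              length(x$design_id), ncol(x$abund_post), x$epsilon, x$generations))
  invisible(x)
}

#' Expected (noise-free) enrichment of every design
#'
#' Closed-form log2 ratio of post- to pre-selection frequency under the
#' deterministic selection model; the quantity [score_library()] estimates
#' from sequencing counts.
#'
#' @param state A `true_state` from [simulate_selection()].
#' @return A list with `per_replicate` (designs x replicates matrix) and
#'   `combined` (mean across replicates, the expectation of the weighted
#'   average under equal expected pre counts).
#' @export
true_enrichment <- function(state) {
  W <- log2(sweep(state$abund_post, 1L, state$abund_pre, "/"))
  rownames(W) <- state$design_id
  list(per_replicate = W, combined = rowMeans(W))
}

## substitution-only sequencing errors
mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  width <- nchar(reads)
  k <- rbinom(length(reads), width, error_rate)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(width[i], k[i])
    for (p in pos) {
      ref <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, ref), 1L)
    }
  }
  reads
}

#' Draw sequencing reads / counts from the selection state
#'
#' Read counts per sample are multinomial draws from the pre- (or post-)
#' selection abundances at the configured depth, independently per
#' replicate. When `sequences = TRUE`, cassette amplicon reads are
#' materialised from the cassette sequences with independent per-base
#' substitution errors at `config$error_rate`.
#'
#' @param state A `true_state`.
#' @param config The [sim_config()] used to generate it.
#' @param library A `scan_library` (required when `sequences = TRUE`).
#' @param sequences Materialise read sequences (default `FALSE`: counts
#'   only).
#' @param seed Seed (default derived from `config$seed`).
#' @return A list with `counts` (the true [count_matrix()]), `samples`
#'   (sample sheet tibble) and, when requested, `reads` (named list of
#'   character vectors per sample).
#' @export
simulate_reads <- function(state, config, library = NULL, sequences = FALSE,
                           seed = config$seed + 2L) {
  stopifnot(inherits(state, "true_state"), inherits(config, "sim_config"))
  set.seed(seed)
  D <- length(state$design_id)
  R <- ncol(state$abund_post)
  sample_ids <- c(paste0("pre_rep", seq_len(R)), paste0("post_rep", seq_len(R)))
  counts <- matrix(0L, nrow = D, ncol = 2L * R,
                   dimnames = list(state$design_id, sample_ids))
  for (r in seq_len(R)) {
    counts[, r] <- rmultinom(1L, config$depth_pre, state$abund_pre)
    counts[, R + r] <- rmultinom(1L, config$depth_post, state$abund_post[, r])
  }
  cm <- count_matrix(counts)
  samples <- tibble(
    sample_id = sample_ids,
    condition = "selection",
    replicate = rep(seq_len(R), 2L),
    phase = rep(c("pre", "post"), each = R)
  )
  out <- list(counts = cm, samples = samples)
  if (sequences) {
    if (is.null(library) || is.null(library$cassettes)) {
      stop("sequences require a scan_library with cassettes")
    }
    seqs <- setNames(library$cassettes$full_seq, library$cassettes$design_id)
    seqs <- seqs[state$design_id]
    out$reads <- lapply(setNames(sample_ids, sample_ids), function(sid) {
      mutate_reads(rep(unname(seqs), counts[, sid]), config$error_rate)
    })
  }
  out
}

#' Window coordinates covering every designed edit of each gene
#'
#' Builds one genomic amplicon window per gene, spanning all codon edits
#' and PAM-kill positions with a small margin, as a reconstruction of the
#' targeted-locus amplicons used for edit verification.
#'
#' @param library A `scan_library` with cassettes.
#' @param margin Extra nt on each side (default 5).
#' @return Named list of [genomic_window()] objects, one per gene.
#' @export
design_windows <- function(library, margin = 5L) {
  stopifnot(inherits(library, "scan_library"), !is.null(library$cassettes))
  out <- list()
  for (i in seq_len(nrow(library$genes))) {
    gid <- library$genes$gene_id[i]
    cc <- library$cassettes[library$cassettes$gene_id == gid, ]
    start <- min(cc$codon_start, cc$pam_kill_pos) - margin
    end <- max(cc$codon_start + 2L, cc$pam_kill_pos) + margin
    start <- max(1L, start)
    end <- min(nchar(library$genes$context[i]), end)
    out[[gid]] <- genomic_window(gid, start, end,
                                 substring(library$genes$context[i], start, end))
  }
  out
}

#' Draw genomic-window amplicon counts
#'
#' Samples reads for one verification window from the cell population
#' implied by the selection state: each design edited in the window
#' contributes its edited abundance, and everything else (unedited
#' escapers and cells edited at other loci) contributes wild-type reads.
#'
#' @param state A `true_state`.
#' @param config The [sim_config()].
#' @param library A `scan_library` with cassettes.
#' @param window A [genomic_window()] for one of the library's genes.
#' @param phase `"pre"` or `"post"`.
#' @param replicate Replicate index (used for `phase = "post"`).
#' @param depth Reads to draw (default `config$depth_genomic`).
#' @param seed Seed (default derived from `config$seed`).
#' @return A [match_window_reads()]-shaped list: named `counts` over the
#'   variant database (incl. `WT`), `total_reads`, plus the database as
#'   `db` and `w`, the number of designed edits in the window.
#' @export
simulate_window_counts <- function(state, config, library, window,
                                   phase = c("pre", "post"), replicate = 1L,
                                   depth = config$depth_genomic,
                                   seed = config$seed + 3L) {
  phase <- match.arg(phase)
  set.seed(seed)
  db <- enumerate_expected(window, library$cassettes, library$designs)
  vids <- setdiff(names(db), "WT")
  idx <- match(vids, state$design_id)
  edited <- if (phase == "pre") state$edited_pre[idx] else state$edited_post[idx, replicate]
  p <- c(max(0, 1 - sum(edited)), edited)
  cnt <- as.integer(rmultinom(1L, depth, p))
  list(counts = setNames(cnt, c("WT", vids)), total_reads = sum(cnt),
       skipped = 0L, db = db, w = length(vids))
}

#' Run a full synthetic experiment
#'
#' Convenience wrapper: [simulate_library()] then [simulate_selection()]
#' then [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @param cassettes,sequences Passed through to the stages.
#' @return A list with `library`, `state`, `counts`, `samples` and
#'   optionally `reads`.
#' @export
simulate_experiment <- function(config, cassettes = TRUE, sequences = FALSE) {
  library <- simulate_library(config, cassettes = cassettes)
  state <- simulate_selection(config, library$designs)
  reads <- simulate_reads(state, config, library = library, sequences = sequences)
  c(list(library = library, state = state), reads)
}
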