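#' Define a genomic amplicon window
#'
#' A window is the trimmed region (primer sites excluded) of one targeted
#' locus that is deep-sequenced to verify editing.
#'
#' @param gene_id Gene identifier.
#' @param start,end 1-based inclusive positions within the genomic context.
#' @param wt_seq Wild-type sequence of the window (`end - start + 1` nt).
#' @return A `genomic_window` object (list).
#' @export
genomic_window <- function(gene_id, start, end, wt_seq) {
  stopifnot(end >= start, nchar(wt_seq) == end - start + 1L)
  structure(list(gene_id = gene_id, start = as.integer(start),
                 end = as.integer(end), wt_seq = toupper(wt_seq)),
            class = "genomic_window")
}

#' Enumerate expected edited sequences for a window
#'
#' Builds the variant database used for 100%-identity matching of genomic
#' amplicon reads: the wild-type window plus, for every design whose codon
#' edit and PAM-kill substitution both fall inside the window, the window
#' with those substitutions applied. Ordering is deterministic (wild type
#' first, then by `design_id`).
#'
#' @param window A `genomic_window`.
#' @param cassettes Cassette tibble for the window's gene (needs
#'   `design_id`, `codon_start`, `pam_kill_pos`, `pam_kill_alt` and the
#'   designed codon via `homology_arm`); see [design_cassettes()].
#' @param designs Design manifest supplying `target_codon` per design.
#' @return Named character vector of full-window sequences; the wild type
#'   is named `"WT"`.
#' @export
enumerate_expected <- function(window, cassettes, designs) {
  stopifnot(inherits(window, "genomic_window"))
  cassettes <- as_tibble(cassettes)
  designs <- as_tibble(designs)
  cassettes <- cassettes[cassettes$gene_id == window$gene_id, ]
  cassettes <- dplyr::left_join(
    cassettes, designs[, c("design_id", "target_codon")], by = "design_id"
  )
  inside <- cassettes$codon_start >= window$start &
    (cassettes$codon_start + 2L) <= window$end &
    cassettes$pam_kill_pos >= window$start &
    cassettes$pam_kill_pos <= window$end
  cassettes <- cassettes[inside, ]
  cassettes <- cassettes[order(cassettes$design_id), ]

  db <- setNames(character(nrow(cassettes)), cassettes$design_id)
  for (i in seq_len(nrow(cassettes))) {
    s <- window$wt_seq
    c0 <- cassettes$codon_start[i] - window$start + 1L
    s <- str_sub_replace(s, c0, c0 + 2L, cassettes$target_codon[i])
    k <- cassettes$pam_kill_pos[i] - window$start + 1L
    s <- str_sub_replace(s, k, k, cassettes$pam_kill_alt[i])
    db[i] <- s
  }
  if (any(db == window$wt_seq)) stop("ambiguous variant database: variant equals wild type")
  db <- c(WT = window$wt_seq, db)
  if (anyDuplicated(db)) stop("ambiguous variant database: two designs yield identical sequences")
  db
}

#' Count exact matches of window reads against the variant database
#'
#' A read increments a variant's count only when it equals the full-length
#' window sequence exactly (100% identity); all other reads contribute to
#' the total only. Reads whose length differs from the window length are
#' skipped with a warning.
#'
#' @param reads Character vector of merged, primer-trimmed reads.
#' @param db Variant database from [enumerate_expected()].
#' @return A list with `counts` (named integer vector over the database),
#'   `total_reads` (reads of the correct length) and `skipped`.
#' @export
match_window_reads <- function(reads, db) {
  stopifnot(length(db) >= 1L, !is.null(names(db)))
  wlen <- nchar(db[[1L]])
  ok <- nchar(reads) == wlen
  if (any(!ok)) {
    warning(sum(!ok), " read(s) skipped: length differs from the window length")
  }
  reads <- reads[ok]
  idx <- match(reads, unname(db))
  tab <- table(factor(names(db)[idx], levels = names(db)))
  list(counts = setNames(as.integer(tab), names(db)),
       total_reads = length(reads), skipped = sum(!ok))
}

#' Fraction of designed edits observed
#'
#' Percent of a window's designed edits seen at least once in genomic
#' amplicon sequencing: `100 * edits_observed / w`.
#'
#' @param edits_observed Number of distinct designs observed.
#' @param w Total designed edits in the window.
#' @param digits Decimal places for reporting (default 1).
#' @return Percent, rounded to `digits`.
#' @export
#' @examples
#' fraction_covered(59, 260)  # 22.7
fraction_covered <- function(edits_observed, w, digits = 1) {
  if (any(w <= 0)) stop("w must be positive")
  stopifnot(all(edits_observed >= 0), all(edits_observed <= w))
  round(100 * edits_observed / w, digits)
}

#' Estimated genomic editing efficiency
#'
#' Estimates the fraction of cells edited at a locus from amplicon reads,
#' normalising the edited-read fraction by the locus's share of the design
#' library: `Eff = (edit_reads / total_reads) / (w / library_size)`,
#' expressed as percent.
#'
#' @param edit_reads Reads matching any edited variant.
#' @param total_reads All window reads.
#' @param w Designed edits in the window.
#' @param library_size Total library size (default 16300).
#' @param digits Decimal places for reporting (default 1).
#' @return Percent.
#' @export
editing_efficiency <- function(edit_reads, total_reads, w,
                               library_size = 16300L, digits = 1) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(w <= 0)) stop("w must be positive")
  if (any(w > library_size)) stop("window larger than library")
  round(100 * (edit_reads / total_reads) / (w / library_size), digits)
}

#' Tabulate edit verification across windows and samples
#'
#' Produces the verification table (one row per window and sample):
#' designed edits, edits observed, fraction covered, and estimated editing
#' efficiency.
#'
#' @param window_counts Named list: per sample, a list of
#'   [match_window_reads()] results named by gene.
#' @param w_by_gene Named integer vector: designed edits per window.
#' @param library_size Total library size.
#' @return A tibble with columns `gene_id`, `sample_id`, `designed`,
#'   `observed`, `edit_reads`, `total_reads`, `fraction_covered`, `eff`.
#' @export
validation_table <- function(window_counts, w_by_gene, library_size = 16300L) {
  rows <- list()
  for (sample_id in names(window_counts)) {
    for (gene_id in names(window_counts[[sample_id]])) {
      m <- window_counts[[sample_id]][[gene_id]]
      edited <- m$counts[setdiff(names(m$counts), "WT")]
      w <- w_by_gene[[gene_id]]
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = gene_id, sample_id = sample_id,
        designed = as.integer(w),
        observed = sum(edited > 0),
        edit_reads = sum(edited),
        total_reads = m$total_reads,
        fraction_covered = fraction_covered(sum(edited > 0), w),
        eff = editing_efficiency(sum(edited), m$total_reads, w, library_size)
      )
    }
  }
  dplyr::bind_rows(rows)
}
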