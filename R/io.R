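#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `condition`, `replicate`,
#'   `phase` (`pre`/`post`) and optionally `reads_path`.
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "condition", "replicate", "phase")
  if (!all(need %in% names(s))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  s$replicate <- as.integer(s$replicate)
  pair_samples(s)   # validates pairing and uniqueness
  s
}

#' Write / read the design manifest
#'
#' The manifest records one row per design: identity, site, codons and the
#' synonymous flag, plus spacer and PAM-kill details when cassettes are
#' supplied.
#'
#' @param designs Design tibble from [saturate_sites()].
#' @param path CSV path.
#' @param cassettes Optional cassette tibble from [design_cassettes()].
#' @return The written tibble, invisibly.
#' @export
write_manifest <- function(designs, path, cassettes = NULL) {
  out <- as_tibble(designs)
  if (!is.null(cassettes)) {
    out <- dplyr::left_join(
      out,
      cassettes[, c("design_id", "spacer", "spacer_strand",
                    "pam_kill_pos", "pam_kill_ref", "pam_kill_alt")],
      by = "design_id"
    )
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("design_id", "gene_id", "is_synonymous") %in% names(m))) {
    stop("manifest must have design_id, gene_id and is_synonymous columns")
  }
  m$is_synonymous <- as.logical(m$is_synonymous)
  m
}

#' Write cassettes as FASTA
#'
#' One record per cassette; the header is the design id.
#'
#' @param cassettes Cassette tibble from [design_cassettes()].
#' @param path Output FASTA path.
#' @export
write_cassette_fasta <- function(cassettes, path) {
  x <- Biostrings::DNAStringSet(setNames(cassettes$full_seq, cassettes$design_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a cassette database from FASTA
#'
#' @param path Cassette FASTA (headers = design ids).
#' @return Named character vector usable as the `db` of [count_matches()].
#' @export
read_cassette_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read counts written by [write_counts()]
#'
#' @param counts_path Counts CSV (first column `design_id`).
#' @param summary_path Optional per-sample summary CSV supplying
#'   `total_reads`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, summary_path = NULL) {
  df <- read.csv(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  total <- NULL
  if (!is.null(summary_path)) {
    s <- read.csv(summary_path, stringsAsFactors = FALSE)
    total <- setNames(s$total_reads, s$sample_id)[colnames(m)]
  }
  count_matrix(m, total_reads = total)
}
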