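#' Read merged amplicon reads
#'
#' Loads merged reads from FASTA or FASTQ (qualities are ignored; the
#' matching rules are identity-based).
#'
#' @param path File path; format is taken from the extension
#'   (`.fastq`/`.fq` = FASTQ, anything else FASTA).
#' @return A character vector of read sequences.
#' @export
read_merged_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

## alignment scoring shared by the matcher and the test oracle: +1 match,
## -1 mismatch, -2 per gap column, linear gaps; read end-to-end, cassette
## ends free ("fitting" alignment)
ALN_MATCH <- 1
ALN_MISMATCH <- -1
ALN_GAP <- 2

align_read_to_db <- function(read, db_seqs) {
  subj <- Biostrings::DNAString(read)
  pat <- Biostrings::DNAStringSet(db_seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = ALN_MATCH, mismatch = ALN_MISMATCH)
  ## pattern = cassettes (locally aligned), subject = read (globally aligned)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = subj, type = "local-global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = ALN_GAP
  )
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  prange <- methods::slot(Biostrings::pattern(aln), "range")
  tibble(
    identity = ifelse(cols > 0, matches / cols, 0),
    length = cols,
    full = BiocGenerics::start(prange) == 1L &
      BiocGenerics::end(prange) == nchar(db_seqs)
  )
}

#' Match one read against the cassette database
#'
#' Aligns a merged read to every cassette (read end-to-end, cassette ends
#' free), keeps cassettes aligning with at least `min_identity` identity
#' over at least `min_length` aligned columns, retains at most `max_hits`
#' candidates sorted by identity (ties broken by lexicographic
#' `design_id`), and returns the best hit. Identity is matching columns
#' divided by alignment columns; gap columns count against identity.
#'
#' @param read Merged read sequence (character scalar).
#' @param db Named character vector of cassette sequences; names are
#'   design ids.
#' @param min_identity Candidate identity threshold (default 0.95).
#' @param min_length Minimal alignment length in columns (default 150).
#' @param max_hits Maximum number of candidate hits retained (default 40).
#' @return A one-row tibble with `design_id`, `identity`, `length` and
#'   `full` (whether the alignment spans the whole cassette), or a zero-row
#'   tibble when there is no hit.
#' @export
match_read <- function(read, db, min_identity = 0.95, min_length = 150L,
                       max_hits = 40L) {
  stopifnot(length(db) > 0L, !is.null(names(db)), nchar(read) >= 1L)
  ## exact-equality fast path
  ex <- which(db == read)
  if (length(ex)) {
    id <- sort(names(db)[ex])[1L]
    return(tibble(design_id = id, identity = 1, length = nchar(read), full = TRUE))
  }
  hits <- align_read_to_db(read, unname(db))
  hits$design_id <- names(db)
  hits <- hits[hits$identity >= min_identity & hits$length >= min_length, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(design_id = character(), identity = numeric(),
                  length = integer(), full = logical()))
  }
  hits <- hits[order(-hits$identity, hits$design_id), , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  hits[1L, c("design_id", "identity", "length", "full")]
}

#' Count cassette matches in a read set
#'
#' Applies the two-tier matching rule: candidate hits need >= 95% identity
#' over >= 150 aligned bases, but a read only increments its best hit's
#' count when the alignment spans the full cassette with identity strictly
#' greater than `count_identity` (99%). All reads contribute to
#' `total_reads`; only counted reads contribute to `matched_reads`.
#'
#' @param reads Character vector of merged reads.
#' @param db Named character vector of cassette sequences.
#' @inheritParams match_read
#' @param count_identity Strict identity threshold for counting
#'   (default 0.99, exclusive).
#' @return A list with `counts` (named integer vector over all designs in
#'   `db`), `total_reads` and `matched_reads`.
#' @export
count_matches <- function(reads, db, min_identity = 0.95, min_length = 150L,
                          max_hits = 40L, count_identity = 0.99) {
  stopifnot(length(db) > 0L, !is.null(names(db)))
  counts <- setNames(integer(length(db)), names(db))
  if (length(reads) == 0L) {
    return(list(counts = counts, total_reads = 0L, matched_reads = 0L))
  }
  ## exact matches resolve in bulk; ties on identical cassettes go to the
  ## lexicographically smallest design_id
  ord <- order(names(db))
  idx <- match(reads, unname(db)[ord])
  exact_id <- names(db)[ord][idx]
  tab <- table(exact_id[!is.na(idx)])
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)

  for (read in reads[is.na(idx)]) {
    hit <- match_read(read, db, min_identity, min_length, max_hits)
    if (nrow(hit) == 1L && hit$full && hit$identity > count_identity) {
      counts[hit$design_id] <- counts[hit$design_id] + 1L
    }
  }
  list(counts = counts, total_reads = length(reads),
       matched_reads = sum(counts))
}

#' Build a count matrix across samples
#'
#' Runs [count_matches()] per sample and assembles the design-by-sample
#' count matrix together with per-sample totals.
#'
#' @param reads_by_sample Named list of read vectors, one per sample.
#' @param db Named character vector of cassette sequences.
#' @param ... Passed to [count_matches()].
#' @return A `count_matrix` object: list with integer matrix `counts`
#'   (designs x samples), `total_reads` and `matched_reads` (named per
#'   sample).
#' @export
quantify_samples <- function(reads_by_sample, db, ...) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  cols <- lapply(reads_by_sample, count_matches, db = db, ...)
  counts <- vapply(cols, function(x) x$counts, integer(length(db)))
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(cols))
  dimnames(counts) <- list(names(db), names(reads_by_sample))
  count_matrix(counts,
               total_reads = vapply(cols, function(x) as.integer(x$total_reads), integer(1)))
}

#' Construct a count matrix
#'
#' @param counts Integer matrix, designs in rows, samples in columns (both
#'   dimnames required).
#' @param total_reads Named integer vector of all reads entering matching
#'   per sample; defaults to the column sums (every read matched).
#' @return A `count_matrix` object with elements `counts`, `total_reads`
#'   and `matched_reads` (`matched_reads` is always the column sums).
#' @export
count_matrix <- function(counts, total_reads = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have design ids as rownames and sample ids as colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  matched <- colSums(counts)
  if (is.null(total_reads)) total_reads <- matched
  total_reads <- setNames(as.integer(total_reads), colnames(counts))
  if (any(matched > total_reads)) stop("matched_reads exceeds total_reads")
  structure(list(counts = counts, total_reads = total_reads,
                 matched_reads = setNames(as.integer(matched), colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "designs x", ncol(x$counts), "samples\n")
  cat("matched/total reads per sample:\n")
  print(rbind(matched = x$matched_reads, total = x$total_reads))
  invisible(x)
}

#' Write counts and per-sample summary
#'
#' @param x A `count_matrix`.
#' @param counts_path CSV path for the design-by-sample counts.
#' @param summary_path Optional CSV path for the per-sample summary
#'   (total reads, matched reads, match rate).
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, counts_path, summary_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(design_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.csv(df, counts_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- data.frame(sample_id = names(x$total_reads),
                    total_reads = x$total_reads,
                    matched_reads = x$matched_reads,
                    match_rate = ifelse(x$total_reads > 0,
                                        x$matched_reads / x$total_reads, NA_real_))
    write.csv(s, summary_path, row.names = FALSE)
  }
  invisible(x)
}
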