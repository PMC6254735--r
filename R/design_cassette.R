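#' Fixed cassette parts
#'
#' The invariant components of an editing cassette: the constitutive
#' promoter J23119 (35 nt) driving gRNA expression, the 3-nt spacing
#' sequence between promoter and spacer, and the first 24 nt of the
#' canonical *S. pyogenes* gRNA scaffold.
#'
#' @return A named list with elements `promoter`, `linker`, `scaffold5`.
#' @export
cassette_parts <- function() {
  list(
    promoter  = "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC",
    linker    = "ATC",
    scaffold5 = "GTTTTAGAGCTAGAAATAGCAAGT"
  )
}

## component lengths of the 230-nt cassette, in assembly order
CASSETTE_LENGTHS <- c(subpool_primer = 18L, variant_primer = 12L,
                      homology_arm = 118L, promoter = 35L, linker = 3L,
                      spacer = 20L, scaffold5 = 24L)

## homology-arm split around the edited codon: 58 nt left, codon, 57 nt right
ARM_LEFT <- 58L
ARM_RIGHT <- 57L

## distance between two closed intervals (0 when they touch or overlap)
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2, s2 - e1))
}

## all NGG PAMs on either strand whose PAM bases fall inside [win_start,
## win_end] and whose 20-nt protospacer lies within the context sequence.
## Ordered by distance to the codon interval, '+' strand first, then
## position (the deterministic tie-break).
find_pam_candidates <- function(context, win_start, win_end, codon_start) {
  n <- nchar(context)
  win_start <- max(1L, win_start)
  win_end <- min(n, win_end)
  codon_end <- codon_start + 2L

  cand <- list()
  ## + strand: PAM = N G G at [p, p+2], protospacer = [p-20, p-1]
  gg <- gregexpr("(?=GG)", context, perl = TRUE)[[1]]
  gg <- gg[gg > 0]
  p <- gg - 1L
  p <- p[p >= win_start & (p + 2L) <= win_end & (p - 20L) >= 1L]
  if (length(p)) {
    cand[["+"]] <- tibble(
      strand = "+", pam_start = p, pam_end = p + 2L,
      spacer = substring(context, p - 20L, p - 1L),
      distance = interval_distance(p, p + 2L, codon_start, codon_end)
    )
  }
  ## - strand: plus-strand CCN at [q, q+2] (PAM read on minus strand),
  ## protospacer = revcomp of [q+3, q+22]
  cc <- gregexpr("(?=CC)", context, perl = TRUE)[[1]]
  cc <- cc[cc > 0]
  q <- cc
  q <- q[q >= win_start & (q + 2L) <= win_end & (q + 22L) <= n]
  if (length(q)) {
    cand[["-"]] <- tibble(
      strand = "-", pam_start = q, pam_end = q + 2L,
      spacer = revcomp(substring(context, q + 3L, q + 22L)),
      distance = interval_distance(q, q + 2L, codon_start, codon_end)
    )
  }
  out <- dplyr::bind_rows(cand)
  if (nrow(out) == 0L) return(out)
  out[order(out$distance, out$strand != "+", out$pam_start), ]
}

#' Pick the gRNA spacer nearest a designed edit
#'
#' Scans both strands of a genomic context for NGG PAMs inside the homology
#' arm around the edit and returns the 20-nt protospacer whose PAM is
#' nearest to the edited codon. Ties are broken deterministically: `+`
#' strand before `-`, then smaller coordinate.
#'
#' @param gene_context Genomic sequence window (character scalar).
#' @param edit_position 1-based position, within `gene_context`, of the
#'   first base of the codon to be edited.
#' @param window Optional `c(start, end)` restricting where PAM bases may
#'   lie; defaults to the 118-nt homology arm centered on the edit.
#' @return A one-row tibble with `strand`, `pam_start`, `pam_end`, `spacer`
#'   (always written 5'->3' on its own strand) and `distance` (nt between
#'   the PAM and the edited codon, 0 if touching).
#' @export
pick_spacer <- function(gene_context, edit_position, window = NULL) {
  if (is.null(window)) {
    window <- c(edit_position - ARM_LEFT, edit_position + 2L + ARM_RIGHT)
  }
  cand <- find_pam_candidates(gene_context, window[1], window[2], edit_position)
  if (nrow(cand) == 0L) stop("no targetable PAM")
  cand[1L, ]
}

#' Design a synonymous PAM-disrupting substitution
#'
#' Finds a single-nucleotide substitution that prevents re-cutting of the
#' edited locus while leaving the encoded protein unchanged. Preference
#' order: destroy the NGG PAM itself via a synonymous change to one of its
#' two G bases (plus-strand C bases for a minus-strand PAM); otherwise make
#' any synonymous change in the 10-nt seed region adjacent to the PAM,
#' nearest the PAM first. Candidate substitutions inside the targeted codon
#' are excluded so the protein-level edit stays exactly the designed one.
#'
#' @param context Genomic context sequence.
#' @param pam_start,strand PAM location, as returned by [pick_spacer()].
#' @param cds_start,cds_end 1-based positions of the coding sequence within
#'   `context` (must contain the PAM for a synonymous kill to exist).
#' @param arm `c(start, end)` of the homology arm within `context`; the
#'   substitution must fall inside it.
#' @param exclude Optional `c(start, end)` interval (the designed codon)
#'   where substitutions are not allowed.
#' @param forbidden Optional character vector of `"pos:alt"` substitutions
#'   to skip (used to resolve clashes between designs whose combined edits
#'   would otherwise be indistinguishable).
#' @return A list with `pos`, `ref`, `alt` (single bases) and `in_pam`
#'   (logical; `FALSE` when the seed-region fallback was used).
#' @export
design_pam_kill <- function(context, pam_start, strand, cds_start, cds_end,
                            arm = NULL, exclude = NULL, forbidden = NULL) {
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(context)
  if (is.null(arm)) arm <- c(1L, n)
  bases <- c("A", "C", "G", "T")

  in_cds <- function(p) p >= cds_start && p <= cds_end
  excluded <- function(p) !is.null(exclude) && p >= exclude[1] && p <= exclude[2]
  synonymous_at <- function(p, alt) {
    k <- (p - cds_start) %/% 3L                      # 0-based codon index
    c0 <- cds_start + 3L * k
    codon <- substring(context, c0, c0 + 2L)
    new_codon <- codon
    substr(new_codon, p - c0 + 1L, p - c0 + 1L) <- alt
    identical(aa_of_codon(new_codon), aa_of_codon(codon)) &&
      aa_of_codon(codon) != "*"
  }
  try_positions <- function(positions, check_pam) {
    for (p in positions) {
      if (p < arm[1] || p > arm[2] || !in_cds(p) || excluded(p)) next
      ref <- substring(context, p, p)
      for (alt in setdiff(bases, ref)) {
        if (paste0(p, ":", alt) %in% forbidden) next
        if (!synonymous_at(p, alt)) next
        if (check_pam) {
          mutated <- context
          substr(mutated, p, p) <- alt
          pam_gone <- if (strand == "+") {
            substring(mutated, pam_start + 1L, pam_start + 2L) != "GG"
          } else {
            substring(mutated, pam_start, pam_start + 1L) != "CC"
          }
          if (!pam_gone) next
        }
        return(list(pos = p, ref = ref, alt = alt, in_pam = check_pam))
      }
    }
    NULL
  }

  ## tier 1: mutate the PAM's GG (plus-strand CC for a minus-strand PAM)
  gg <- if (strand == "+") c(pam_start + 1L, pam_start + 2L) else c(pam_start, pam_start + 1L)
  hit <- try_positions(gg, check_pam = TRUE)
  if (!is.null(hit)) return(hit)

  ## tier 2: synonymous change in the 10-nt seed adjacent to the PAM
  seed <- if (strand == "+") seq(pam_start - 1L, pam_start - 10L) else seq(pam_start + 3L, pam_start + 12L)
  seed <- seed[seed >= 1L & seed <= n]
  hit <- try_positions(seed, check_pam = FALSE)
  if (!is.null(hit)) return(hit)

  stop("cannot silently disrupt PAM")
}

#' Generate priming sites for cassette assembly
#'
#' Draws random primer sequences with GC content between 40 and 60%,
#' reproducibly from a seed. Used for the 18-nt subpool priming site
#' (shared by a library) and the 12-nt variant-specific priming sites
#' (unique per design).
#'
#' @param n Number of primers.
#' @param width Primer length in nt.
#' @param seed Integer seed.
#' @return A character vector of `n` unique primer sequences.
#' @export
make_primers <- function(n, width, seed = 0L) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    seqs <- vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1))
    gc <- vapply(seqs, function(s) {
      sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    }, numeric(1))
    out <- unique(c(out, seqs[gc >= 0.4 & gc <= 0.6]))
  }
  out[seq_len(n)]
}

#' Assemble one 230-nt editing cassette
#'
#' Builds the homology arm (58 nt left flank + edited codon + 57 nt right
#' flank = 118 nt) from the genomic context, applies the designed codon
#' substitution and the synonymous PAM-kill substitution, and concatenates
#' the seven cassette components in order: 18-nt subpool primer, 12-nt
#' variant primer, 118-nt homology arm, 35-nt promoter, 3-nt linker, 20-nt
#' spacer, 24-nt scaffold. Total length is always 230 nt.
#'
#' @param design One design row (see [saturate_site()]).
#' @param context Genomic context containing the gene.
#' @param codon_start 1-based position within `context` of the first base
#'   of the targeted codon.
#' @param spacer_info One-row tibble from [pick_spacer()].
#' @param pam_kill List from [design_pam_kill()].
#' @param subpool_primer,variant_primer Priming sites (18 and 12 nt).
#' @param parts Fixed parts, see [cassette_parts()].
#' @return A one-row tibble describing the cassette, including `full_seq`,
#'   the arm boundaries (`arm_start`, `arm_end` in context coordinates) and
#'   the PAM-kill substitution.
#' @export
assemble_cassette <- function(design, context, codon_start, spacer_info, pam_kill,
                              subpool_primer, variant_primer,
                              parts = cassette_parts()) {
  design <- as.list(design)
  stopifnot(nchar(subpool_primer) == 18L, nchar(variant_primer) == 12L,
            nchar(spacer_info$spacer) == 20L)
  arm_start <- codon_start - ARM_LEFT
  arm_end <- codon_start + 2L + ARM_RIGHT
  if (arm_start < 1L || arm_end > nchar(context)) {
    stop("homology arm extends beyond the genomic context")
  }
  if (pam_kill$pos < arm_start || pam_kill$pos > arm_end) {
    stop("edit outside homology arm")
  }
  wt_codon <- substring(context, codon_start, codon_start + 2L)
  if (wt_codon != design$wt_codon) {
    stop("context does not carry the expected wild-type codon")
  }

  arm <- substring(context, arm_start, arm_end)
  arm <- str_sub_replace(arm, ARM_LEFT + 1L, ARM_LEFT + 3L, design$target_codon)
  koff <- pam_kill$pos - arm_start + 1L
  if (substring(arm, koff, koff) != pam_kill$ref) {
    stop("PAM-kill reference base mismatch (substitution collides with the codon edit?)")
  }
  arm <- str_sub_replace(arm, koff, koff, pam_kill$alt)

  full <- paste0(subpool_primer, variant_primer, arm, parts$promoter,
                 parts$linker, spacer_info$spacer, parts$scaffold5)
  stopifnot(nchar(full) == sum(CASSETTE_LENGTHS))

  tibble(
    design_id = design$design_id,
    gene_id = design$gene_id,
    subpool_primer = subpool_primer,
    variant_primer = variant_primer,
    homology_arm = arm,
    promoter = parts$promoter,
    linker = parts$linker,
    spacer = spacer_info$spacer,
    scaffold5 = parts$scaffold5,
    full_seq = full,
    arm_start = arm_start,
    arm_end = arm_end,
    codon_start = codon_start,
    spacer_strand = spacer_info$strand,
    pam_start = spacer_info$pam_start,
    pam_kill_pos = pam_kill$pos,
    pam_kill_ref = pam_kill$ref,
    pam_kill_alt = pam_kill$alt
  )
}

#' Design cassettes for every design of a gene
#'
#' Site-level work (spacer choice and PAM kill) is done once per site and
#' shared by the site's 20 designs. For each site, PAM candidates are tried
#' in nearest-first order until one admits a synonymous kill inside the
#' homology arm.
#'
#' @param designs Design tibble for one gene (see [saturate_sites()]).
#' @param context Genomic context sequence containing the gene.
#' @param cds_start,cds_end 1-based CDS coordinates within `context`.
#' @param subpool_primer Shared 18-nt subpool priming site.
#' @param variant_primers Character vector of 12-nt priming sites, one per
#'   design (recycled from [make_primers()] when `NULL`).
#' @param primer_seed Seed for primer generation when `variant_primers` is
#'   `NULL`.
#' @return A cassette tibble, one row per design (all `full_seq` 230 nt).
#' @export
design_cassettes <- function(designs, context, cds_start, cds_end,
                             subpool_primer = NULL, variant_primers = NULL,
                             primer_seed = 0L) {
  designs <- as_tibble(designs)
  if (is.null(subpool_primer)) subpool_primer <- make_primers(1L, 18L, seed = primer_seed)
  if (is.null(variant_primers)) {
    variant_primers <- make_primers(nrow(designs), 12L, seed = primer_seed + 1L)
  }
  stopifnot(length(variant_primers) == nrow(designs))

  site_key <- paste(designs$gene_id, designs$residue_index)
  choose_site <- function(residue_index, forbidden = NULL) {
    codon_start <- cds_start + 3L * (residue_index - 1L)
    arm <- c(codon_start - ARM_LEFT, codon_start + 2L + ARM_RIGHT)
    cand <- find_pam_candidates(context, arm[1], arm[2], codon_start)
    for (j in seq_len(nrow(cand))) {
      pk <- tryCatch(
        design_pam_kill(context, cand$pam_start[j], cand$strand[j],
                        cds_start, cds_end, arm = arm,
                        exclude = c(codon_start, codon_start + 2L),
                        forbidden = forbidden),
        error = function(e) NULL
      )
      if (!is.null(pk)) {
        return(list(spacer = cand[j, ], pam_kill = pk, codon_start = codon_start))
      }
    }
    NULL
  }
  site_info <- list()
  for (i in which(!duplicated(site_key))) {
    hit <- choose_site(designs$residue_index[i])
    if (is.null(hit)) stop("cannot silently disrupt PAM for site ", site_key[i])
    site_info[[site_key[i]]] <- hit
  }

  ## genomic diff signature of a design given its site's kill: the bases of
  ## the codon that change, plus the kill substitution
  signature_of <- function(i) {
    si <- site_info[[site_key[i]]]
    wt <- strsplit(designs$wt_codon[i], "")[[1]]
    tg <- strsplit(designs$target_codon[i], "")[[1]]
    d <- which(wt != tg)
    paste(sort(c(paste0(si$codon_start + d - 1L, ":", tg[d]),
                 paste0(si$pam_kill$pos, ":", si$pam_kill$alt))),
          collapse = ",")
  }
  ## neighbouring designs can commute with each other's synonymous PAM kill
  ## and become genomically indistinguishable; re-choose kills until every
  ## design's edit set is unique
  for (pass in 1:10) {
    sigs <- vapply(seq_len(nrow(designs)), signature_of, character(1))
    dup <- which(duplicated(sigs))
    if (length(dup) == 0L) break
    i <- dup[1L]
    key <- site_key[i]
    si <- site_info[[key]]
    forb <- paste0(si$pam_kill$pos, ":", si$pam_kill$alt)
    hit <- choose_site(designs$residue_index[i], forbidden = forb)
    if (is.null(hit)) {
      ## no alternative kill at this site: re-choose at the partner's site
      partner <- which(sigs == sigs[i] & site_key != key)[1L]
      if (is.na(partner)) stop("indistinguishable designs at site ", key)
      pk <- site_info[[site_key[partner]]]$pam_kill
      hit2 <- choose_site(designs$residue_index[partner],
                          forbidden = paste0(pk$pos, ":", pk$alt))
      if (is.null(hit2)) stop("indistinguishable designs at site ", key)
      site_info[[site_key[partner]]] <- hit2
    } else {
      site_info[[key]] <- hit
    }
  }
  sigs <- vapply(seq_len(nrow(designs)), signature_of, character(1))
  if (anyDuplicated(sigs)) stop("indistinguishable designs remain after kill reassignment")

  dplyr::bind_rows(lapply(seq_len(nrow(designs)), function(i) {
    si <- site_info[[site_key[i]]]
    assemble_cassette(designs[i, ], context, si$codon_start, si$spacer,
                      si$pam_kill, subpool_primer, variant_primers[i])
  }))
}
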