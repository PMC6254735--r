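#' Full codon saturation of one site
#'
#' Enumerates the 20 designs of a saturation library at one residue site:
#' one design per amino acid, each encoded by that amino acid's preferred
#' codon. No stop codons are generated. The design for the wild-type amino
#' acid is the site's synonymous design; its codon must differ from the
#' wild-type codon, so when the preferred codon *is* the wild-type codon the
#' fallback codon (by default the second most frequent) is substituted. If
#' no alternative synonymous codon exists (Met, Trp) the site cannot carry
#' an observable synonymous design and an error is raised.
#'
#' @param site One site: a list or one-row tibble with `gene_id`,
#'   `residue_index`, `wt_aa`, `wt_codon` (see [sites_from_cds()]).
#' @param codon_table Named character vector mapping the 20 amino acids to
#'   their design codon, as from [preferred_codon_table()].
#' @param synonymous_fallback Named character vector supplying an alternate
#'   synonymous codon per amino acid, used only when
#'   `codon_table[[wt_aa]] == wt_codon`. Set to `NULL` to disable fallback.
#' @return A tibble of 20 designs with columns `design_id`, `gene_id`,
#'   `residue_index`, `wt_aa`, `wt_codon`, `target_aa`, `target_codon`,
#'   `is_synonymous`.
#' @export
#' @examples
#' site <- list(gene_id = "lysC", residue_index = 5L, wt_aa = "T", wt_codon = "ACT")
#' saturate_site(site)
saturate_site <- function(site,
                          codon_table = preferred_codon_table(1),
                          synonymous_fallback = preferred_codon_table(2)) {
  site <- as.list(site)
  wt_aa <- site$wt_aa
  wt_codon <- toupper(site$wt_codon)
  stopifnot(wt_aa %in% AMINO_ACIDS, nchar(wt_codon) == 3L)
  if (!identical(aa_of_codon(wt_codon), wt_aa)) {
    stop("wild-type codon does not encode the wild-type amino acid")
  }
  if (!setequal(names(codon_table), AMINO_ACIDS) || anyNA(codon_table)) {
    stop("codon_table must map each of the 20 amino acids to one codon")
  }
  if (any(aa_of_codon(codon_table) != names(codon_table))) {
    stop("codon_table contains codons that do not encode their amino acid")
  }

  target_codon <- unname(codon_table[AMINO_ACIDS])
  names(target_codon) <- AMINO_ACIDS
  if (target_codon[[wt_aa]] == wt_codon) {
    fb <- if (is.null(synonymous_fallback)) NA_character_ else synonymous_fallback[[wt_aa]]
    if (is.na(fb) || toupper(fb) == wt_codon || !identical(aa_of_codon(fb), wt_aa)) {
      stop("synonymous design impossible at this site; supply alternate synonymous codon")
    }
    target_codon[[wt_aa]] <- toupper(fb)
  }

  tibble(
    design_id = sprintf("%s_%s%d%s", site$gene_id, wt_aa, site$residue_index, AMINO_ACIDS),
    gene_id = site$gene_id,
    residue_index = as.integer(site$residue_index),
    wt_aa = wt_aa,
    wt_codon = wt_codon,
    target_aa = AMINO_ACIDS,
    target_codon = unname(target_codon),
    is_synonymous = AMINO_ACIDS == wt_aa
  )
}

#' Saturate every site of a library
#'
#' Applies [saturate_site()] to each row of a site table, yielding the full
#' design manifest: 20 designs per site.
#'
#' @param sites Site tibble (see [sites_from_cds()]).
#' @inheritParams saturate_site
#' @return A tibble of `20 * nrow(sites)` designs; `design_id` is unique.
#' @export
saturate_sites <- function(sites,
                           codon_table = preferred_codon_table(1),
                           synonymous_fallback = preferred_codon_table(2)) {
  sites <- as_tibble(sites)
  designs <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    saturate_site(sites[i, ], codon_table, synonymous_fallback)
  }))
  if (anyDuplicated(designs$design_id)) {
    stop("duplicated design identifiers; sites are not unique")
  }
  designs
}
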