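#' Read a protein structure into an atom table
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the atom records as a
#' tibble with the columns used by [select_shell_residues()].
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `type` ("ATOM"/"HETATM"), `chain`, `resno`,
#'   `resid` (three-letter residue name), `elety` (atom name), `elesy`
#'   (element symbol) and coordinates `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  tibble(
    type = at$type, chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, elesy = at$elesy, x = at$x, y = at$y, z = at$z
  )
}

## element symbol per atom; falls back to the first alphabetic character of
## the atom name when no element column is present (PDB convention)
atom_elements <- function(atoms) {
  if (!is.null(atoms$elesy) && !all(is.na(atoms$elesy)) && !all(atoms$elesy == "")) {
    return(toupper(trimws(atoms$elesy)))
  }
  toupper(substr(gsub("^[0-9]*", "", trimws(atoms$elety)), 1L, 1L))
}

#' Select residues within a distance shell of binding-site atoms
#'
#' Builds the set of mutagenesis sites: every protein residue with at least
#' one heavy (non-hydrogen) atom within `radius` angstroms (inclusive) of
#' any declared binding atom. Binding atoms are declared by the caller and
#' typically belong to a substrate, co-factor, DNA, or allosteric-effector
#' group; hetero groups themselves are never returned as sites.
#'
#' @param atoms Atom table (tibble or data.frame) with columns `chain`,
#'   `resno`, `resid`, `x`, `y`, `z` and optionally `type` and
#'   `elety`/`elesy`, as from [read_structure()].
#' @param binding_atoms Atom table of the declared binding atoms, same
#'   columns as `atoms`.
#' @param radius Shell radius in angstroms (default 6).
#' @param gene_id Gene identifier attached to the returned sites.
#' @return A tibble of sites with columns `gene_id`, `chain`,
#'   `residue_index` and `wt_aa`, sorted by (chain, residue_index).
#' @export
select_shell_residues <- function(atoms, binding_atoms, radius = 6, gene_id = NA_character_) {
  atoms <- as_tibble(atoms)
  binding_atoms <- as_tibble(binding_atoms)
  if (nrow(binding_atoms) == 0L) stop("no binding sites declared")
  stopifnot(radius > 0)

  if (!is.null(atoms$type)) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms <- atoms[atom_elements(atoms) != "H", , drop = FALSE]

  missing_xyz <- !stats::complete.cases(atoms[, c("x", "y", "z")])
  if (any(missing_xyz)) {
    bad <- unique(paste0(atoms$chain[missing_xyz], ":", atoms$resno[missing_xyz]))
    warning("skipping residue(s) lacking coordinates: ", paste(bad, collapse = ", "))
    atoms <- atoms[!missing_xyz, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) return(empty_sites(gene_id))

  pm <- as.matrix(atoms[, c("x", "y", "z")])
  bm <- as.matrix(binding_atoms[, c("x", "y", "z")])
  ## squared distance of every protein atom to its nearest binding atom
  d2 <- outer(rowSums(pm^2), rowSums(bm^2), "+") - 2 * tcrossprod(pm, bm)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))

  hit <- atoms[mind <= radius, c("chain", "resno", "resid")]
  hit <- unique(hit)
  ## drop binding-site residues that are hetero groups (non-protein resid)
  aa1 <- suppressWarnings(bio3d::aa321(hit$resid))
  keep <- !is.na(aa1) & aa1 != "X"
  hit <- hit[keep, , drop = FALSE]
  aa1 <- aa1[keep]

  out <- tibble(
    gene_id = gene_id, chain = hit$chain,
    residue_index = as.integer(hit$resno), wt_aa = aa1
  )
  out[order(out$chain, out$residue_index), ]
}

empty_sites <- function(gene_id) {
  tibble(gene_id = character(), chain = character(),
         residue_index = integer(), wt_aa = character())
}

#' Attach coding-sequence information to selected sites
#'
#' Completes shell-selected sites with the wild-type codon and the 0-based
#' offset of the codon within the coding sequence, validating that each
#' codon translates to the expected residue.
#'
#' @param sites Site tibble with `gene_id`, `residue_index`, and `wt_aa`
#'   (protein coordinates, 1-based).
#' @param cds In-frame coding sequence of the gene.
#' @return `sites` with added columns `wt_codon` and `cds_offset`.
#' @export
sites_from_cds <- function(sites, cds) {
  sites <- as_tibble(sites)
  stopifnot(all(sites$residue_index >= 1L))
  if (any(3L * sites$residue_index > nchar(cds))) {
    stop("residue index beyond the end of the coding sequence")
  }
  sites$wt_codon <- codon_at(cds, sites$residue_index)
  sites$cds_offset <- 3L * (sites$residue_index - 1L)
  got <- aa_of_codon(sites$wt_codon)
  if ("wt_aa" %in% names(sites) && !all(is.na(sites$wt_aa))) {
    bad <- !is.na(sites$wt_aa) & got != sites$wt_aa
    if (any(bad)) {
      stop("wild-type codon does not translate to the annotated residue at: ",
           paste(sites$residue_index[bad], collapse = ", "))
    }
  }
  sites$wt_aa <- got
  sites
}
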