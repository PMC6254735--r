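make_atoms <- function(df) {
  df$type <- df$type %||% "ATOM"
  df$resid <- df$resid %||% "ALA"
  df$elety <- df$elety %||% "CA"
  df$elesy <- df$elesy %||% "C"
  df$chain <- df$chain %||% "A"
  tibble::as_tibble(df)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("shell selection is inclusive at the boundary and empty beyond it", {
  binding <- make_atoms(data.frame(resno = 999, x = 0, y = 0, z = 0, type = "HETATM"))
  at_boundary <- make_atoms(data.frame(resno = 1, x = 6.0, y = 0, z = 0))
  expect_equal(select_shell_residues(at_boundary, binding, 6)$residue_index, 1L)
  beyond <- make_atoms(data.frame(resno = 1, x = 6.0001, y = 0, z = 0))
  expect_equal(nrow(select_shell_residues(beyond, binding, 6)), 0L)
})

test_that("shell selection matches an all-pairs brute-force scan", {
  set.seed(11)
  n_res <- 25L
  atoms <- make_atoms(data.frame(
    resno = rep(seq_len(n_res), each = 4L),
    x = runif(n_res * 4L, -12, 12), y = runif(n_res * 4L, -12, 12),
    z = runif(n_res * 4L, -12, 12)
  ))
  binding <- make_atoms(data.frame(resno = 999, type = "HETATM",
                                   x = c(0, 3), y = c(0, -2), z = c(0, 1)))
  got <- select_shell_residues(atoms, binding, 6)
  want <- oracle_shell(atoms, binding, 6)
  expect_equal(got$residue_index, sort(want$resno))
})

test_that("shell selection ignores hydrogens and hetero groups, flags missing coordinates", {
  binding <- make_atoms(data.frame(resno = 999, x = 0, y = 0, z = 0, type = "HETATM"))
  atoms <- make_atoms(data.frame(
    resno = c(1L, 2L, 3L, 999L),
    elesy = c("C", "H", "C", "C"),
    resid = c("ALA", "GLY", "GLY", "LIG"),
    type = c("ATOM", "ATOM", "ATOM", "HETATM"),
    x = c(2, 1, NA, 0), y = c(0, 0, 0, 0), z = c(0, 0, 0, 0)
  ))
  expect_warning(got <- select_shell_residues(atoms, binding, 6), "lacking coordinates")
  expect_equal(got$residue_index, 1L)   # H-only residue 2 and hetero 999 excluded
  expect_error(select_shell_residues(atoms, binding[0, ], 6), "no binding sites")
})

test_that("saturating a site yields 20 designs with exactly one synonymous design", {
  site <- list(gene_id = "g", residue_index = 7L, wt_aa = "T", wt_codon = "ACT")
  d <- saturate_site(site)
  expect_equal(nrow(d), 20L)
  expect_setequal(d$target_aa, createscan:::AMINO_ACIDS)
  expect_equal(sum(d$is_synonymous), 1L)
  syn <- d[d$is_synonymous, ]
  expect_equal(syn$target_aa, "T")
  expect_false(syn$target_codon == site$wt_codon)
  expect_false(any(vapply(d$target_codon, translate_cds, "") == "*"))
  # every design's codon translates to its target amino acid
  expect_equal(vapply(d$target_codon, translate_cds, ""), d$target_aa,
               ignore_attr = TRUE)
})

test_that("synonymous fallback engages when the preferred codon is the wild type", {
  site <- list(gene_id = "g", residue_index = 3L, wt_aa = "L", wt_codon = "CTG")
  # preferred Leu codon is CTG itself: explicit table without fallback errors
  expect_error(saturate_site(site, synonymous_fallback = NULL),
               "synonymous design impossible")
  # default fallback substitutes the second most frequent Leu codon
  d <- saturate_site(site)
  expect_equal(d$target_codon[d$is_synonymous], "TTA")
  # a caller-supplied fallback wins
  fb <- preferred_codon_table(2)
  fb[["L"]] <- "CTT"
  d2 <- saturate_site(site, synonymous_fallback = fb)
  expect_equal(d2$target_codon[d2$is_synonymous], "CTT")
  # Met has no synonymous codon at all
  met <- list(gene_id = "g", residue_index = 4L, wt_aa = "M", wt_codon = "ATG")
  expect_error(saturate_site(met), "synonymous design impossible")
})

test_that("spacer choice picks the PAM nearest the edit with deterministic tie-breaks", {
  backbone <- function(n) paste(rep(c("A", "T"), length.out = n), collapse = "")
  # single + strand NGG a few nt downstream of the codon at 31..33
  ctx <- backbone(60)
  substr(ctx, 37, 38) <- "GG"
  hit <- pick_spacer(ctx, 31, window = c(1, 60))
  expect_equal(hit$strand, "+")
  expect_equal(hit$pam_start, 36)
  expect_equal(hit$spacer, substring(ctx, 16, 35))
  expect_equal(nchar(hit$spacer), 20L)
  # + strand PAM at distance 4 beats - strand PAM at distance 9
  ctx2 <- backbone(80)
  substr(ctx2, 38, 39) <- "GG"   # PAM 37..39, codon 31..33 -> distance 4
  substr(ctx2, 42, 43) <- "CC"   # minus-strand PAM 42..44 -> distance 9
  hit2 <- pick_spacer(ctx2, 31, window = c(1, 80))
  expect_equal(hit2$strand, "+")
  expect_equal(hit2$pam_start, 37)
  # no NGG anywhere
  expect_error(pick_spacer(backbone(60), 31, window = c(1, 60)), "no targetable PAM")
})

test_that("chosen PAM distance is minimal against an exhaustive PAM scan", {
  set.seed(23)
  for (i in 1:25) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE), collapse = "")
    codon_start <- 71L
    win <- c(codon_start - 58L, codon_start + 59L)
    all_pams <- oracle_pam_scan(ctx, win, codon_start)
    if (nrow(all_pams) == 0L) {
      expect_error(pick_spacer(ctx, codon_start), "no targetable PAM")
    } else {
      hit <- pick_spacer(ctx, codon_start)
      expect_true(hit$distance <= min(all_pams$distance))
      # tie-break: among minimal-distance candidates, + strand then position
      best <- all_pams[all_pams$distance == min(all_pams$distance), ]
      best <- best[order(best$strand != "+", best$pam_start), ][1, ]
      expect_equal(hit$strand, best$strand)
      expect_equal(hit$pam_start, best$pam_start)
    }
  }
})

test_that("PAM kill prefers a synonymous hit in the PAM and falls back to the seed", {
  # CDS: ATG ACG GAA CTG ... PAM 'CGG' at 5..7; position 6 is the 4-fold
  # third base of ACG (Thr), so a synonymous change there destroys the GG
  cds <- paste0("ATG", "ACG", "GAA", "CTG", "AAA")
  kill <- design_pam_kill(cds, pam_start = 5L, strand = "+",
                          cds_start = 1L, cds_end = nchar(cds))
  expect_true(kill$in_pam)
  expect_equal(kill$pos, 6L)
  mutated <- cds
  substr(mutated, kill$pos, kill$pos) <- kill$alt
  expect_false(substring(mutated, 6, 7) == "GG")
  expect_equal(translate_cds(mutated), translate_cds(cds))

  # GG of the PAM sits in codon positions 1-2 of GGT (Gly): no synonymous
  # single-nt change can touch it, so the kill lands in the 10-nt seed,
  # where CTG (Leu) offers a synonymous third-position change.
  cds2 <- paste0("ATG", "CTG", "GTA", "TAT", "CAT", "GGT", "AAA")
  # protospacer ends just before the PAM: PAM 'AGG'? construct PAM at GGT:
  # codon GGT at 16..18, PAM = 15..17 ('TGG' using pos 15 T, 16 G, 17 G)
  kill2 <- design_pam_kill(cds2, pam_start = 15L, strand = "+",
                           cds_start = 1L, cds_end = nchar(cds2))
  expect_false(kill2$in_pam)
  expect_true(kill2$pos >= 5L && kill2$pos <= 14L)   # inside the seed
  mutated2 <- cds2
  substr(mutated2, kill2$pos, kill2$pos) <- kill2$alt
  expect_equal(translate_cds(mutated2), translate_cds(cds2))

  # PAM in non-coding context cannot be silently disrupted
  expect_error(design_pam_kill(cds, pam_start = 5L, strand = "+",
                               cds_start = 100L, cds_end = 120L),
               "cannot silently disrupt PAM")
})

test_that("cassette anatomy: 230 nt, seven parts in order, 58/3/57 arm split", {
  lib <- test_library(seed = 42)$library
  cass <- lib$cassettes
  expect_true(all(nchar(cass$full_seq) == 230L))
  expect_true(all(cass$full_seq == paste0(
    cass$subpool_primer, cass$variant_primer, cass$homology_arm,
    cass$promoter, cass$linker, cass$spacer, cass$scaffold5
  )))
  expect_true(all(nchar(cass$subpool_primer) == 18L))
  expect_true(all(nchar(cass$variant_primer) == 12L))
  expect_true(all(nchar(cass$homology_arm) == 118L))
  expect_true(all(nchar(cass$promoter) == 35L))
  expect_true(all(nchar(cass$linker) == 3L))
  expect_true(all(nchar(cass$spacer) == 20L))
  expect_true(all(nchar(cass$scaffold5) == 24L))
  # the designed codon sits after the 58-nt left flank
  d <- lib$designs[match(cass$design_id, lib$designs$design_id), ]
  expect_equal(substring(cass$homology_arm, 59, 61), d$target_codon,
               ignore_attr = TRUE)
})

test_that("cassette assembly is invertible against the reference genome", {
  lib <- test_library(seed = 42)$library
  cass <- lib$cassettes
  d <- lib$designs[match(cass$design_id, lib$designs$design_id), ]
  for (i in seq_len(nrow(cass))) {
    gene <- lib$genes[lib$genes$gene_id == cass$gene_id[i], ]
    arm <- cass$homology_arm[i]
    # revert the codon edit and the PAM kill
    arm <- createscan:::str_sub_replace(arm, 59L, 61L, d$wt_codon[i])
    koff <- cass$pam_kill_pos[i] - cass$arm_start[i] + 1L
    arm <- createscan:::str_sub_replace(arm, koff, koff, cass$pam_kill_ref[i])
    expect_equal(arm, substring(gene$context, cass$arm_start[i], cass$arm_end[i]))
  }
})

test_that("edited CDS translation differs from wild type at exactly the target residue", {
  lib <- test_library(seed = 43)$library
  cass <- lib$cassettes
  d <- lib$designs[match(cass$design_id, lib$designs$design_id), ]
  for (i in seq_len(nrow(cass))) {
    gene <- lib$genes[lib$genes$gene_id == cass$gene_id[i], ]
    ctx <- gene$context
    c0 <- cass$codon_start[i]
    ctx <- createscan:::str_sub_replace(ctx, c0, c0 + 2L, d$target_codon[i])
    ctx <- createscan:::str_sub_replace(ctx, cass$pam_kill_pos[i],
                                        cass$pam_kill_pos[i], cass$pam_kill_alt[i])
    wt_prot <- translate_cds(gene$cds)
    ed_prot <- translate_cds(substring(ctx, gene$cds_start, gene$cds_end))
    diffs <- which(strsplit(wt_prot, "")[[1]] != strsplit(ed_prot, "")[[1]])
    if (d$is_synonymous[i]) {
      expect_length(diffs, 0L)
    } else {
      expect_equal(diffs, d$residue_index[i])
    }
  }
})

test_that("spacers match a genomic protospacer adjacent to an NGG PAM", {
  lib <- test_library(seed = 44)$library
  cass <- lib$cassettes
  for (i in seq_len(nrow(cass))) {
    gene <- lib$genes[lib$genes$gene_id == cass$gene_id[i], ]
    p <- cass$pam_start[i]
    if (cass$spacer_strand[i] == "+") {
      expect_equal(substring(gene$context, p + 1L, p + 2L), "GG")
      expect_equal(cass$spacer[i], substring(gene$context, p - 20L, p - 1L))
    } else {
      expect_equal(substring(gene$context, p, p + 1L), "CC")
      expect_equal(cass$spacer[i],
                   createscan:::revcomp(substring(gene$context, p + 3L, p + 22L)))
    }
  }
})

test_that("PDB files round-trip into the atom table used for shell selection", {
  pdb_line <- function(serial, name, resname, chain, resno, x, y, z, el,
                       record = "ATOM") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, "", resname, chain, resno, "", x, y, z,
            1.0, 10.0, el)
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0, "C"),
    pdb_line(3, "CA", "GLY", "A", 2, 20, 0, 0, "C"),
    pdb_line(4, "O1", "LIG", "A", 99, 2, 0, 0, "O", record = "HETATM"),
    "END"
  ), path)
  atoms <- read_structure(path)
  expect_equal(nrow(atoms), 4L)
  expect_setequal(unique(atoms$type), c("ATOM", "HETATM"))
  binding <- atoms[atoms$type == "HETATM", ]
  got <- select_shell_residues(atoms, binding, 6, gene_id = "toy")
  expect_equal(got$residue_index, 1L)   # GLY at 20 A is outside the shell
  expect_equal(got$wt_aa, "A")
  unlink(path)
})
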