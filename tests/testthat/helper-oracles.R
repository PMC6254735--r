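# Independent reference implementations used as oracles. These are written
# for clarity and checked against the package's optimised paths; they must
# stay independent of the code they verify.

# Fitting alignment oracle: the read is aligned end-to-end, the cassette's
# ends are free (clipped without charge). Linear gap penalty. Scores:
# match +1, mismatch -1, gap column -2. Computed over antidiagonals so the
# quadratic DP stays affordable in R. Returns identity (matches / columns,
# gaps counted against identity), the number of alignment columns, and
# whether the alignment spans the full cassette.
oracle_fit_align <- function(read, cassette, match = 1, mismatch = -1, gap = 2) {
  a <- strsplit(cassette, "")[[1]]   # rows (free ends)
  b <- strsplit(read, "")[[1]]       # cols (global)
  m <- length(a); n <- length(b)
  D <- matrix(-Inf, m + 1L, n + 1L)
  D[, 1L] <- 0                        # skip any cassette prefix for free
  D[1L, ] <- -gap * (0:n)             # read consumed against gaps
  S <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
  for (k in 2L:(m + n)) {             # antidiagonal sweep over D[i+1, j+1]
    i <- pmin(k - 1L, m):max(1L, k - n); j <- k - i
    ok <- j >= 1L & j <= n
    i <- i[ok]; j <- j[ok]
    diag_ <- D[cbind(i, j)] + S[cbind(i, j)]
    up <- D[cbind(i, j + 1L)] - gap
    left <- D[cbind(i + 1L, j)] - gap
    D[cbind(i + 1L, j + 1L)] <- pmax(diag_, up, left)
  }
  i_end <- which.max(D[, n + 1L]) - 1L
  # traceback, preferring diagonal moves on ties
  i <- i_end; j <- n; cols <- 0L; matches <- 0L
  while (j > 0L) {
    here <- D[i + 1L, j + 1L]
    if (i > 0L && isTRUE(all.equal(here, D[i, j] + S[i, j]))) {
      cols <- cols + 1L; matches <- matches + (a[i] == b[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && isTRUE(all.equal(here, D[i, j + 1L] - gap))) {
      cols <- cols + 1L; i <- i - 1L
    } else {
      cols <- cols + 1L; j <- j - 1L
    }
  }
  list(identity = matches / cols, cols = cols,
       full = (i_end == m) && (i == 0L), score = D[i_end + 1L, n + 1L])
}

# Exhaustive best-hit assignment under the candidate and counting tiers.
oracle_best_hit <- function(read, db, min_identity = 0.95, min_length = 150) {
  hits <- lapply(names(db), function(id) {
    o <- oracle_fit_align(read, db[[id]])
    data.frame(design_id = id, identity = o$identity, length = o$cols,
               full = o$full)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$identity >= min_identity & hits$length >= min_length, ]
  if (nrow(hits) == 0L) return(NULL)
  hits[order(-hits$identity, hits$design_id), ][1L, ]
}

# All-pairs distance scan for shell selection: loops over every
# (protein atom, binding atom) pair.
oracle_shell <- function(atoms, binding_atoms, radius) {
  atoms <- atoms[atoms$type == "ATOM", ]
  keep <- logical(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(binding_atoms))) {
      d <- sqrt((atoms$x[i] - binding_atoms$x[j])^2 +
                  (atoms$y[i] - binding_atoms$y[j])^2 +
                  (atoms$z[i] - binding_atoms$z[j])^2)
      if (d <= radius) { keep[i] <- TRUE; break }
    }
  }
  unique(atoms[keep, c("chain", "resno")])
}

# Exhaustive NGG/CCN PAM enumeration with interval distances to the codon.
oracle_pam_scan <- function(context, win, codon_start) {
  hits <- data.frame()
  for (p in seq_len(nchar(context) - 2L)) {
    trip <- substring(context, p, p + 2L)
    iv_dist <- max(0L, p - (codon_start + 2L), codon_start - (p + 2L))
    if (substring(trip, 2L, 3L) == "GG" && p >= win[1] && p + 2L <= win[2] && p - 20L >= 1L) {
      hits <- rbind(hits, data.frame(strand = "+", pam_start = p, distance = iv_dist))
    }
    if (substring(trip, 1L, 2L) == "CC" && p >= win[1] && p + 2L <= win[2] &&
        p + 22L <= nchar(context)) {
      hits <- rbind(hits, data.frame(strand = "-", pam_start = p, distance = iv_dist))
    }
  }
  hits
}

# point substitutions for building mutated reads
mutate_seq <- function(s, k) {
  pos <- sample.int(nchar(s), k)
  for (p in pos) {
    ref <- substring(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  }
  s
}

# small deterministic library fixture shared across test files
test_library <- function(seed = 42, n_sites = 2L, genes = NULL) {
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = c("g1", "g2"),
                            category = c("transport", "biosynthesis"),
                            n_sites = n_sites)
  }
  cfg <- sim_config("neutral", seed = seed, genes = genes,
                    depth_pre = 2000, depth_post = 2000)
  list(config = cfg, library = simulate_library(cfg))
}
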