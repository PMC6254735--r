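test_that("enrichment score arithmetic matches closed form, including the zero floor", {
  expect_equal(enrichment_score(20, 80, 1000, 1000), 2)
  expect_equal(enrichment_score(50, 50, 1000, 1000), 0)
  expect_equal(enrichment_score(40, 0, 1000, 1000), log2(0.0125))
  # unequal totals enter through the frequencies
  expect_equal(enrichment_score(10, 30, 2000, 6000), 0)
  expect_error(enrichment_score(10, 5, 0, 100), "empty sample")
  # antisymmetry when the zero floor does not fire
  set.seed(2)
  pre <- sample(10:500, 30); post <- sample(10:500, 30)
  expect_equal(enrichment_score(pre, post, 5000, 7000),
               -enrichment_score(post, pre, 7000, 5000))
})

test_that("weighted average reproduces the count-weighted formula and its limits", {
  expect_equal(weighted_average(c(100, 300), c(1, 3)), 2.5)
  expect_equal(weighted_average(c(120, 120), c(-1, 3)), 1)       # equal counts: mean
  expect_equal(weighted_average(250, 1.7), 1.7)                  # single replicate
  expect_error(weighted_average(c(0, 0), c(1, 2)), "no weight")
  # bounded by the replicate scores
  set.seed(4)
  for (i in 1:20) {
    cts <- sample(1:1000, 3); sc <- rnorm(3)
    w <- weighted_average(cts, sc)
    expect_gte(w, min(sc)); expect_lte(w, max(sc))
  }
})

test_that("the pre-count filter masks per replicate, keeping the boundary", {
  expect_equal(passes_count_filter(c(9, 15), 10), c(FALSE, TRUE))
  expect_true(passes_count_filter(10, 10))        # 'less than 10' excluded
  expect_false(any(passes_count_filter(rep(0, 5), 10)))
})

test_that("the bootstrap null is seeded, stable, and degenerates cleanly", {
  expect_error(fit_null(1.5), "null underdetermined")
  # degenerate distribution
  n0 <- fit_null(rep(0, 12), B = 500, seed = 1)
  expect_equal(n0$mu, 0); expect_equal(n0$sigma, 0)
  expect_equal(c(n0$ci_low, n0$ci_high), c(0, 0))
  # reproducible under the same seed
  x <- c(-1, 0, 1, 0.5, -0.5, 0.2)
  expect_identical(fit_null(x, B = 2000, seed = 7), fit_null(x, B = 2000, seed = 7))
  # CI bounds stable across seeds at the default resampling depth
  a <- fit_null(c(-1, 0, 1), B = 20000, seed = 1)
  b <- fit_null(c(-1, 0, 1), B = 20000, seed = 2)
  expect_lt(abs(a$ci_low - b$ci_low), 0.05)
  expect_lt(abs(a$ci_high - b$ci_high), 0.05)
  expect_true(a$ci_low <= a$mu && a$mu <= a$ci_high)
})

test_that("significance calls are inclusive at mu + 2 sigma with normal tail p-values", {
  null <- fit_null(c(-0.3, -0.1, 0, 0.1, 0.3), B = 200, seed = 1)
  at2 <- null$mu + 2 * null$sigma
  call <- call_significant(at2, null)
  expect_true(call$significant)
  expect_equal(call$p_value, pnorm(2, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(call_significant(null$mu, null)$p_value, 0.5)
  expect_false(call_significant(null$mu, null)$significant)
  low <- call_significant(null$mu - 3 * null$sigma, null)
  expect_false(low$significant)
  expect_true(low$depleted)
  # sigma = 0 degenerates to strict comparisons with 0/1 p-values
  d <- fit_null(rep(0.2, 5), B = 100, seed = 1)
  expect_equal(call_significant(c(0.1, 0.2, 0.3), d)$p_value, c(1, 1, 0))
  expect_equal(call_significant(c(0.1, 0.2, 0.3), d)$significant, c(FALSE, FALSE, TRUE))
})

test_that("condition p-values follow the fitted density and the empirical variant", {
  set.seed(10)
  scores <- rnorm(5000, 0, 1)
  p <- condition_pvalue(1.645, scores)
  expect_lt(abs(p - 0.05), 0.01)
  expect_equal(condition_pvalue(median(scores), scores), 0.5, tolerance = 0.02)
  # monotone decreasing
  ws <- seq(-2, 2, length.out = 9)
  expect_true(all(diff(condition_pvalue(ws, scores)) < 0))
  # empirical variant: extreme order statistic and median
  pe <- condition_pvalue(max(scores), scores, method = "empirical")
  expect_lte(pe, 1 / (length(scores) + 1) + 1e-12)
  expect_equal(condition_pvalue(median(scores), scores, method = "empirical"),
               0.5, tolerance = 0.02)
  expect_error(condition_pvalue(0, rnorm(5)), "too few scores")
})

## small deterministic scoring scenario used by the pipeline tests
make_counts_scenario <- function() {
  designs <- tibble::tibble(
    design_id = sprintf("g1_A%dX%d", rep(1:4, each = 1), 1:4),
    gene_id = "g1",
    is_synonymous = c(FALSE, FALSE, TRUE, TRUE)
  )
  counts <- matrix(
    c(100, 9, 50, 60,    # pre rep1 (design 2 fails the filter in rep1)
      400, 40, 52, 58,   # post rep1
      120, 30, 55, 65,   # pre rep2
      480, 30, 57, 63),  # post rep2
    ncol = 4, dimnames = list(designs$design_id,
                              c("pre_1", "post_1", "pre_2", "post_2"))
  )
  samples <- tibble::tibble(
    sample_id = c("pre_1", "post_1", "pre_2", "post_2"),
    condition = "aec10", replicate = c(1L, 1L, 2L, 2L),
    phase = c("pre", "post", "pre", "post")
  )
  list(designs = designs, counts = count_matrix(counts), samples = samples)
}

test_that("score_library applies the filter per replicate and the weighted combination", {
  sc <- make_counts_scenario()
  res <- score_library(sc$counts, sc$samples, sc$designs, B = 500, seed = 1)$results

  tot <- colSums(sc$counts$counts)
  w1 <- log2((400 / tot[2]) / (100 / tot[1]))
  w2 <- log2((480 / tot[4]) / (120 / tot[3]))
  d1 <- res[res$design_id == "g1_A1X1", ]
  expect_equal(d1$W_avg, (100 * w1 + 120 * w2) / 220, ignore_attr = TRUE)
  expect_equal(d1$n_replicates, 2L)
  # design 2: pre = 9 in rep1 -> masked there, scored from rep2 alone
  d2 <- res[res$design_id == "g1_A2X2", ]
  expect_equal(d2$n_replicates, 1L)
  expect_equal(d2$W_avg, log2((30 / tot[4]) / (30 / tot[3])), ignore_attr = TRUE)
  expect_equal(d2$per_replicate[[1]]$score[1], NA_real_)
  # null fitted from the two synonymous designs
  expect_equal(length(res$W_avg[res$is_synonymous]), 2L)
})

test_that("score_library rejects unpaired samples and missing designs", {
  sc <- make_counts_scenario()
  bad <- sc$samples[sc$samples$sample_id != "pre_1", ]
  expect_error(score_library(sc$counts, bad, sc$designs, B = 100), "unpaired sample")
  expect_error(score_library(sc$counts, sc$samples, sc$designs[-1, ], B = 100),
               "does not cover")
})

test_that("summaries partition designs by gene and category", {
  lib <- test_library(seed = 31)$library
  cfg <- sim_config("neutral", seed = 31,
                    genes = tibble::tibble(gene_id = c("g1", "g2"),
                                           category = c("transport", "biosynthesis"),
                                           n_sites = 2L),
                    depth_pre = 50000, depth_post = 50000)
  state <- simulate_selection(cfg, lib$designs)
  sim <- simulate_reads(state, cfg)
  scores <- score_library(sim$counts, sim$samples, lib$designs, B = 500, seed = 1)
  ann <- lib$genes[, c("gene_id", "category")]
  s <- summarize_hits(scores, ann)
  expect_setequal(s$by_gene$gene_id, c("g1", "g2"))
  # gene rows sum to their category rows
  merged <- dplyr::left_join(s$by_gene, ann, by = c("gene_id", "category"))
  agg <- dplyr::count(merged, .data$condition, .data$category,
                      wt = .data$n_enriched, name = "n_enriched")
  expect_equal(
    dplyr::arrange(agg, .data$category)$n_enriched,
    dplyr::arrange(s$by_category, .data$category)$n_enriched
  )
  expect_equal(sum(s$by_gene$n_designs), nrow(lib$designs))
  expect_error(summarize_hits(scores, ann[1, ]), "unannotated")
})

test_that("frequencies sum to one over scored designs before the zero floor", {
  sc <- make_counts_scenario()
  freqs <- sweep(sc$counts$counts, 2, sc$counts$matched_reads, "/")
  expect_equal(unname(colSums(freqs)), rep(1, 4))
})
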