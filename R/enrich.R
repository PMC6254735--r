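#' Per-replicate log2 enrichment score
#'
#' Computes the enrichment score of one design in one biological replicate:
#' the log2 ratio of its post-selection to pre-selection read frequency.
#' Frequencies divide the design's count by the sample's total matched
#' reads. Post-selection counts of 0 are replaced by 0.5 before the
#' frequency computation so the score is defined for washed-out designs.
#'
#' @param pre_count,post_count Design read counts (vectors allowed).
#' @param pre_total,post_total Total matched reads of the pre and post
#'   samples (scalars or vectors).
#' @return Numeric vector of log2 enrichment scores.
#' @export
#' @examples
#' enrichment_score(20, 80, 1000, 1000)   # log2(4) = 2
enrichment_score <- function(pre_count, post_count, pre_total, post_total) {
  if (any(pre_total <= 0) || any(post_total <= 0)) stop("empty sample")
  if (any(pre_count <= 0)) stop("pre-selection count must be positive (apply the count filter first)")
  post_count <- ifelse(post_count == 0, 0.5, post_count)
  log2((post_count / post_total) / (pre_count / pre_total))
}

#' Count-weighted average of replicate scores
#'
#' Combines per-replicate enrichment scores as
#' `sum(C_i * W_i) / sum(C_i)`, where `C_i` is the design's read count in
#' replicate `i` (by default its pre-selection count) and `W_i` the
#' replicate score. With a single replicate the score is returned
#' unchanged; with equal weights this is the arithmetic mean.
#'
#' @param counts Numeric vector of per-replicate weight counts `C_i`.
#' @param scores Numeric vector of per-replicate scores `W_i`.
#' @return The weighted average score.
#' @export
#' @examples
#' weighted_average(c(100, 300), c(1, 3))  # 2.5
weighted_average <- function(counts, scores) {
  stopifnot(length(counts) == length(scores), length(counts) >= 1L)
  if (sum(counts) <= 0) stop("no weight")
  sum(counts * scores) / sum(counts)
}

#' Mask designs with low pre-selection counts
#'
#' Designs with a pre-selection count below `threshold` are unreliable to
#' score and are masked *within that replicate only*; they still enter the
#' analysis through replicates where they pass.
#'
#' @param pre Numeric vector/matrix of pre-selection counts.
#' @param threshold Minimum pre-selection count (default 10; counts equal
#'   to the threshold are retained).
#' @return Logical vector/matrix, `TRUE` where the design is kept.
#' @export
passes_count_filter <- function(pre, threshold = 10) {
  pre >= threshold
}

#' Fit the synonymous null model
#'
#' Estimates the neutral enrichment distribution from the scores of
#' synonymous designs: mean `mu`, standard deviation `sigma`, and a
#' bootstrap 95% confidence interval for `mu` (resampling with replacement
#' `B` times, resample size = number of scores).
#'
#' @param synonymous_scores Numeric vector of weighted enrichment scores of
#'   synonymous designs (at least 2).
#' @param B Number of bootstrap resamples (default 20000).
#' @param seed Integer seed for the bootstrap.
#' @return A `null_model` object: list with `mu`, `sigma`, `ci_low`,
#'   `ci_high`, `n`, `B`, `seed`.
#' @export
fit_null <- function(synonymous_scores, B = 20000L, seed = 0L) {
  x <- synonymous_scores[!is.na(synonymous_scores)]
  if (length(x) < 2L) stop("null underdetermined")
  stopifnot(B >= 1L)
  set.seed(seed)
  n <- length(x)
  boot <- numeric(B)
  done <- 0L
  chunk <- max(1L, min(B, floor(2e6 / n)))
  while (done < B) {
    k <- min(chunk, B - done)
    m <- matrix(x[sample.int(n, n * k, replace = TRUE)], nrow = n)
    boot[(done + 1L):(done + k)] <- colMeans(m)
    done <- done + k
  }
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(mu = mean(x), sigma = sd(x), ci_low = ci[1], ci_high = ci[2],
                 n = n, B = as.integer(B), seed = as.integer(seed)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("synonymous null: mu = %.4f, sigma = %.4f (n = %d)\n", x$mu, x$sigma, x$n))
  cat(sprintf("bootstrap 95%% CI for mu: [%.4f, %.4f] (B = %d, seed = %d)\n",
              x$ci_low, x$ci_high, x$B, x$seed))
  invisible(x)
}

#' Call significance against the synonymous null
#'
#' A design is significantly *enriched* when its weighted score is at least
#' `mu + 2 sigma` (inclusive); the symmetric depleted call
#' (`W <= mu - 2 sigma`) is reported separately. The p-value is the
#' one-sided upper-tail normal probability of the score under
#' `N(mu, sigma^2)`. With `sigma == 0` the calls degenerate to strict
#' comparisons against `mu` and the p-value to 0/1.
#'
#' @param w Numeric vector of weighted enrichment scores.
#' @param null A `null_model` from [fit_null()].
#' @return A tibble with `significant` (enriched call), `depleted` and
#'   `p_value`.
#' @export
call_significant <- function(w, null) {
  stopifnot(inherits(null, "null_model"))
  if (null$sigma == 0) {
    sig <- w > null$mu
    dep <- w < null$mu
    p <- ifelse(w > null$mu, 0, 1)
  } else {
    sig <- w >= null$mu + 2 * null$sigma
    dep <- w <= null$mu - 2 * null$sigma
    p <- pnorm(w, mean = null$mu, sd = null$sigma, lower.tail = FALSE)
  }
  tibble(significant = sig, depleted = dep, p_value = p)
}

#' Per-mutant p-value within a selective condition
#'
#' One-sided upper-tail probability of a score under the distribution of
#' all scored designs in the condition. The default fits a normal density
#' to the condition's scores; `method = "empirical"` uses the empirical
#' upper-tail proportion with add-one smoothing, `(#{scores > w} + 1) /
#' (n + 1)`, so the maximum observed score gets `1 / (n + 1)`.
#'
#' @param w Score(s) to evaluate.
#' @param condition_scores All weighted scores in the condition (>= 10).
#' @param method `"normal"` (default) or `"empirical"`.
#' @return Numeric vector of p-values, monotone decreasing in `w`.
#' @export
condition_pvalue <- function(w, condition_scores, method = c("normal", "empirical")) {
  method <- match.arg(method)
  x <- condition_scores[!is.na(condition_scores)]
  if (length(x) < 10L) stop("too few scores in condition to fit a density")
  if (method == "normal") {
    pnorm(w, mean = mean(x), sd = sd(x), lower.tail = FALSE)
  } else {
    vapply(w, function(wi) (sum(x > wi) + 1) / (length(x) + 1), numeric(1))
  }
}

## resolve (condition, replicate) -> pre/post sample ids, with pairing checks
pair_samples <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "condition", "replicate", "phase")
  stopifnot(all(need %in% names(samples)))
  if (!all(samples$phase %in% c("pre", "post"))) stop("phase must be 'pre' or 'post'")
  key <- paste(samples$condition, samples$replicate, samples$phase)
  if (anyDuplicated(key)) stop("duplicate (condition, replicate, phase) in sample sheet")
  wide <- tidyr::pivot_wider(samples, id_cols = c("condition", "replicate"),
                             names_from = "phase", values_from = "sample_id")
  if (!"pre" %in% names(wide)) wide$pre <- NA_character_
  if (!"post" %in% names(wide)) wide$post <- NA_character_
  if (anyNA(wide$pre[!is.na(wide$post)])) stop("unpaired sample: post sample without matching pre sample")
  wide[!is.na(wide$post), ]
}

#' Score a library: replicate scores, weighted averages, significance
#'
#' The full statistical pipeline for one count matrix. Per condition and
#' replicate, designs passing the pre-selection count filter are scored
#' with [enrichment_score()]; replicate scores are combined with
#' [weighted_average()]; the synonymous designs' weighted scores define the
#' bootstrap null ([fit_null()]); and every scored design is tested with
#' [call_significant()] and [condition_pvalue()].
#'
#' @param counts A `count_matrix` (see [count_matrix()]).
#' @param samples Sample sheet tibble with columns `sample_id`,
#'   `condition`, `replicate`, `phase` ("pre"/"post").
#' @param manifest Design manifest tibble with `design_id`, `gene_id`,
#'   `is_synonymous` (see [saturate_sites()]).
#' @param min_pre Pre-selection count filter threshold (default 10).
#' @param weight Which count weighs a replicate in the weighted average:
#'   `"pre"` (default), `"post"`, or `"pre+post"`.
#' @param B,seed Bootstrap resamples and seed for the null model.
#' @param p_method Density family for [condition_pvalue()].
#' @param keep_replicates Attach the nested `per_replicate` list-column
#'   (default `TRUE`; disable for large simulation sweeps).
#' @return A `scan_scores` object: list with `results` (per design and
#'   condition: replicate scores nested as `per_replicate`, `W_avg`,
#'   `n_replicates`, `significant`, `depleted`, `p_value`,
#'   `p_condition`) and `null_models` (one `null_model` per condition).
#' @export
score_library <- function(counts, samples, manifest, min_pre = 10,
                          weight = c("pre", "post", "pre+post"),
                          B = 20000L, seed = 0L,
                          p_method = c("normal", "empirical"),
                          keep_replicates = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  weight <- match.arg(weight)
  p_method <- match.arg(p_method)
  manifest <- as_tibble(manifest)
  stopifnot(all(c("design_id", "gene_id", "is_synonymous") %in% names(manifest)))
  pairs <- pair_samples(samples)
  missing <- setdiff(c(pairs$pre, pairs$post), colnames(counts$counts))
  if (length(missing)) stop("samples absent from count matrix: ", paste(missing, collapse = ", "))
  designs <- rownames(counts$counts)
  if (!all(designs %in% manifest$design_id)) stop("manifest does not cover all counted designs")
  man <- manifest[match(designs, manifest$design_id), ]

  all_results <- list()
  null_models <- list()
  for (cond in unique(pairs$condition)) {
    pc <- pairs[pairs$condition == cond, ]
    rep_scores <- lapply(seq_len(nrow(pc)), function(i) {
      pre_s <- pc$pre[i]; post_s <- pc$post[i]
      pre <- counts$counts[, pre_s]
      post <- counts$counts[, post_s]
      keep <- passes_count_filter(pre, min_pre)
      w <- rep(NA_real_, length(pre))
      w[keep] <- enrichment_score(pre[keep], post[keep],
                                  counts$matched_reads[[pre_s]],
                                  counts$matched_reads[[post_s]])
      cw <- switch(weight, pre = pre, post = post, `pre+post` = pre + post)
      tibble(design_id = designs, replicate = pc$replicate[i],
             pre_count = as.numeric(pre), post_count = as.numeric(post),
             weight_count = as.numeric(cw), score = w)
    })
    per_rep <- dplyr::bind_rows(rep_scores)
    scored <- per_rep[!is.na(per_rep$score), ]
    wavg <- scored |>
      dplyr::group_by(.data$design_id) |>
      dplyr::summarise(
        W_avg = weighted_average(.data$weight_count, .data$score),
        n_replicates = dplyr::n(), .groups = "drop"
      )
    res <- tibble(design_id = designs, gene_id = man$gene_id,
                  is_synonymous = man$is_synonymous, condition = cond)
    res <- dplyr::left_join(res, wavg, by = "design_id")

    syn_scores <- res$W_avg[res$is_synonymous & !is.na(res$W_avg)]
    null <- fit_null(syn_scores, B = B, seed = seed)
    null_models[[cond]] <- null
    calls <- call_significant(res$W_avg, null)
    res$significant <- calls$significant
    res$depleted <- calls$depleted
    res$p_value <- calls$p_value
    scored_w <- res$W_avg[!is.na(res$W_avg)]
    res$p_condition <- if (length(scored_w) >= 10L) {
      ifelse(is.na(res$W_avg), NA_real_,
             condition_pvalue(res$W_avg, scored_w, p_method))
    } else NA_real_   # density fit underdetermined in tiny libraries
    if (keep_replicates) {
      split_rep <- split(per_rep[, c("replicate", "pre_count", "post_count",
                                     "weight_count", "score")],
                         factor(per_rep$design_id, levels = designs))
      res$per_replicate <- unname(split_rep[res$design_id])
    }
    all_results[[cond]] <- res
  }
  structure(list(results = dplyr::bind_rows(all_results),
                 null_models = null_models),
            class = "scan_scores")
}

#' @export
print.scan_scores <- function(x, ...) {
  r <- x$results
  cat("scan_scores:", length(unique(r$design_id)), "designs,",
      length(x$null_models), "condition(s)\n")
  for (cond in names(x$null_models)) {
    rc <- r[r$condition == cond, ]
    cat(sprintf("  %s: %d scored, %d enriched, %d depleted\n", cond,
                sum(!is.na(rc$W_avg)), sum(rc$significant, na.rm = TRUE),
                sum(rc$depleted, na.rm = TRUE)))
  }
  invisible(x)
}

#' Roll results up by gene and category
#'
#' Counts significantly enriched/depleted designs and summarises score
#' distributions per gene and per pathway category, per condition.
#'
#' @param scores A `scan_scores` object from [score_library()], or its
#'   `results` tibble.
#' @param annotation Tibble mapping `gene_id` to `category`
#'   (biosynthesis, degradation, regulation, transport); must cover every
#'   scored gene.
#' @return A list of tibbles `by_gene` and `by_category`.
#' @export
summarize_hits <- function(scores, annotation) {
  res <- if (inherits(scores, "scan_scores")) scores$results else as_tibble(scores)
  annotation <- as_tibble(annotation)
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  missing <- setdiff(unique(res$gene_id), annotation$gene_id)
  if (length(missing)) stop("unannotated gene(s): ", paste(missing, collapse = ", "))
  res <- dplyr::left_join(res, annotation[, c("gene_id", "category")], by = "gene_id")

  summarise_block <- function(df, keys) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        n_designs = dplyr::n(),
        n_scored = sum(!is.na(.data$W_avg)),
        n_enriched = sum(.data$significant, na.rm = TRUE),
        n_depleted = sum(.data$depleted, na.rm = TRUE),
        mean_score = mean(.data$W_avg, na.rm = TRUE),
        median_score = median(.data$W_avg, na.rm = TRUE),
        max_score = suppressWarnings(max(.data$W_avg, na.rm = TRUE)),
        .groups = "drop"
      )
  }
  list(
    by_gene = summarise_block(res, c("condition", "category", "gene_id")),
    by_category = summarise_block(res, c("condition", "category"))
  )
}
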