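#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: with margins
#' fixed, the p-value is the sum of probabilities of all tables whose
#' point probability does not exceed the observed table's (with relative
#' tolerance 1e-7 on the comparison).  The odds ratio is the sample odds
#' ratio `a*d / (b*c)`: `Inf` when `b*c = 0` and `a*d > 0`, and 1 when
#' both products are 0.
#'
#' @param a Either a 2x2 matrix `rbind(c(a, b), c(c, d))` or the `a` cell.
#' @param b,c,d Remaining cells when `a` is scalar.
#' @return List with `odds_ratio`, `p_value`, and `table` (2x2 matrix).
#' @examples
#' fisher_exact(3, 0, 0, 3)$p_value  # 0.1
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("table must be 2x2")
    tb <- a; a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(!is.finite(cells))) stop("cells must be finite")
  if (any(cells < 0)) stop("cells must be non-negative")
  if (any(abs(cells - round(cells)) > 1e-8)) stop("cells must be integers")
  a <- round(a); b <- round(b); c <- round(c); d <- round(d)

  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0L || k == 0L || k == m + n2) {
    p <- 1
  } else {
    lo <- max(0, k - n2); hi <- min(k, m)
    x <- lo:hi
    probs <- stats::dhyper(x, m, n2, k)
    p_obs <- stats::dhyper(a, m, n2, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  ad <- as.numeric(a) * d; bc <- as.numeric(b) * c
  or <- if (ad == 0 && bc == 0) 1 else if (bc == 0) Inf else ad / bc
  list(odds_ratio = or, p_value = p,
       table = matrix(c(a, c, b, d), 2, 2,
                      dimnames = list(c("specific", "nonspecific"),
                                      c("homologous", "non_homologous"))))
}

#' One gene-subsampled co-occurrence fold
#'
#' Let `G_spec` be the genes with at least one group-A reference
#' transcript (a reference-specific TR) and `G_nonspec` the genes with at
#' least one group-B transcript and none in group A.  One fold samples
#' `|G_spec|` genes from `G_nonspec` uniformly without replacement (all of
#' them, with a warning, when fewer are available), counts homologous and
#' non-homologous pair events for group A over `G_spec` and group B over
#' the sampled genes, and runs [fisher_exact()] on the resulting 2x2
#' table.
#'
#' @param groups A `gene_groups` object.
#' @param flags Output of [flag_transcripts()].
#' @param w Weight vector.
#' @param category Core-length category the flags were computed under
#'   (recorded in the result; the filtering itself happened upstream).
#' @param seed Integer seed for the gene subsample.
#' @param fold_index Recorded fold number.
#' @return Class `tr_fold`: list with `fold_index`, `table`, `odds_ratio`,
#'   `p_value`, `n_specific_genes`, `sampled_gene_count`, `seed`,
#'   `category`, `weights`.
#' @export
run_fold <- function(groups, flags, w = "W1", category = "all", seed,
                     fold_index = 1L) {
  w <- .as_weights(w)
  rf <- flags[flags$is_reference, , drop = FALSE]
  g_spec <- unique(rf$gene_key[rf$has_ref_specific_tr])
  g_b <- unique(rf$gene_key[rf$has_any_tr & !rf$has_ref_specific_tr])
  g_nonspec <- setdiff(g_b, g_spec)
  if (length(g_spec) == 0L)
    stop("no genes carry a reference-specific TR in this category; ",
         "nothing to test (try category = \"all\" or a larger dataset)")
  n_take <- min(length(g_spec), length(g_nonspec))
  if (n_take < length(g_spec))
    warning("only ", length(g_nonspec), " non-specific genes available for ",
            length(g_spec), " specific genes; using all of them")
  sampled <- with_seed(seed, sample(g_nonspec, n_take))
  ca <- count_events(groups, flags, w, "specific", gene_subset = g_spec)
  cb <- count_events(groups, flags, w, "nonspecific", gene_subset = sampled)
  ft <- fisher_exact(ca$n_homologous, ca$n_non_homologous,
                     cb$n_homologous, cb$n_non_homologous)
  structure(list(fold_index = fold_index, table = ft$table,
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 n_specific_genes = length(g_spec),
                 sampled_gene_count = n_take, seed = seed,
                 category = category, weights = attr(w, "label")),
            class = "tr_fold")
}

#' @export
print.tr_fold <- function(x, ...) {
  cat(sprintf("Fold %d (seed %d, %s, category %s)\n", x$fold_index, x$seed,
              x$weights, as.character(x$category)))
  print(x$table)
  cat(sprintf("  odds ratio %.4g, Fisher p = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Gene-subsampled k-fold replication of the co-occurrence test
#'
#' Runs [run_fold()] `k` times with seeds `base_seed + 1 .. base_seed + k`
#' and aggregates the 2x2 tables by arithmetic cell-wise mean.  Per-fold
#' p-values are reported individually — they are not pooled.
#'
#' @inheritParams run_fold
#' @param k Number of folds (default 10).
#' @param base_seed Base seed; fold `i` uses `base_seed + i`.
#' @return Class `tr_cv`: list with `folds`, `mean_table`, `p_values`,
#'   `odds_ratios`, `k`, `base_seed`, `weights`, `category`.
#' @export
cross_validate <- function(groups, flags, w = "W1", category = "all",
                           k = 10L, base_seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  folds <- lapply(seq_len(k), function(i)
    run_fold(groups, flags, w, category, seed = base_seed + i, fold_index = i))
  mean_table <- Reduce(`+`, lapply(folds, `[[`, "table")) / k
  structure(list(folds = folds, mean_table = mean_table,
                 p_values = vapply(folds, `[[`, numeric(1), "p_value"),
                 odds_ratios = vapply(folds, `[[`, numeric(1), "odds_ratio"),
                 k = k, base_seed = base_seed,
                 weights = folds[[1]]$weights, category = category),
            class = "tr_cv")
}

#' @export
print.tr_cv <- function(x, ...) {
  cat(sprintf("%d-fold co-occurrence analysis (%s, category %s)\n",
              x$k, x$weights, as.character(x$category)))
  cat("Mean 2x2 table (events):\n")
  print(round(x$mean_table, 1))
  cat(sprintf("Odds ratios: median %.3g (range %.3g–%.3g)\n",
              stats::median(x$odds_ratios), min(x$odds_ratios),
              max(x$odds_ratios)))
  cat(sprintf("Fisher p-values: max %.3g across folds\n", max(x$p_values)))
  invisible(x)
}
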