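#' Impute missing expression values by K nearest neighbouring samples
#'
#' Each missing entry (sample i, gene j) is replaced by the unweighted mean of
#' gene j over the `k` samples nearest to i that have gene j observed (all of
#' them, if fewer than `k` exist). Distance between two samples is the
#' missing-aware Euclidean distance: the Euclidean distance over the genes
#' observed in both, rescaled by `sqrt(n_genes / n_shared)` — the convention
#' of standard KNN imputers. Observed entries are never altered.
#'
#' @param x Samples-by-genes tibble (optionally labelled).
#' @param k Number of neighbouring samples (default 2).
#' @return `x` with no missing entries.
#' @export
impute_missing_knn <- function(x, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be a positive integer")
  m <- expr_matrix(x)
  if (!anyNA(m)) return(x)
  all_missing <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(all_missing) > 0) {
    abort(sprintf("gene(s) missing in every sample: %s",
                  paste(head(all_missing, 5), collapse = ", ")))
  }
  if (any(rowSums(!is.na(m)) == 0)) abort("a sample has no observed values")
  n_genes <- ncol(m)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  n_samp <- nrow(m)
  # pairwise missing-aware Euclidean distances
  d <- matrix(Inf, n_samp, n_samp)
  for (i in seq_len(n_samp)) {
    for (j in seq_len(n_samp)) {
      if (i == j) next
      shared <- obs[i, ] & obs[j, ]
      ns <- sum(shared)
      if (ns == 0) next
      d[i, j] <- sqrt(n_genes / ns * sum((m[i, shared] - m[j, shared])^2))
    }
  }
  out <- m
  for (i in seq_len(n_samp)) {
    miss_j <- which(!obs[i, ])
    if (length(miss_j) == 0) next
    ord <- order(d[i, ])           # stable: ties broken by sample index
    for (j in miss_j) {
      donors <- ord[obs[ord, j] & is.finite(d[i, ord])]
      if (length(donors) == 0) {
        abort(sprintf("no donor sample for gene %s", colnames(m)[j]))
      }
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(m[use, j])
    }
  }
  x[, colnames(out)] <- expr_tibble(out, x$sample_id)[, colnames(out)]
  x
}

#' Merge studies on their shared genes
#'
#' Restricts every study to the genes present in all of them (sorted symbol
#' order), stacks the samples in input order, and prefixes sample IDs with a
#' study tag so they stay unique. All studies must be labelled.
#'
#' @param datasets A list of labelled samples-by-genes tibbles; names, if
#'   given, are used as study tags (otherwise `ds1`, `ds2`, ...).
#' @return One labelled samples-by-genes tibble.
#' @export
merge_by_gene_intersection <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2) {
    abort("need at least two datasets to merge")
  }
  tags <- names(datasets)
  if (is.null(tags) || any(tags == "")) tags <- paste0("ds", seq_along(datasets))
  purrr::walk(datasets, assert_labelled, what = "every merged dataset")
  shared <- sort(purrr::reduce(purrr::map(datasets, expr_genes), intersect))
  if (length(shared) == 0) abort("gene intersection is empty")
  pieces <- purrr::map2(datasets, tags, function(d, tag) {
    out <- d[, c("sample_id", "label", shared)]
    out$sample_id <- paste(tag, out$sample_id, sep = "_")
    out
  })
  dplyr::bind_rows(pieces)
}

#' Standardise each sample to zero mean and unit variance across genes
#'
#' Per-sample z-scoring removes study- and platform-specific affine scale and
#' offset differences, which is what makes cross-platform merging of
#' expression studies meaningful. The population (divide-by-n) standard
#' deviation is used.
#'
#' @param x Complete (no missing values) samples-by-genes tibble with at
#'   least two genes.
#' @return `x` with every sample row standardised.
#' @export
zscore_per_sample <- function(x) {
  assert_complete(x)
  m <- expr_matrix(x)
  if (ncol(m) < 2) abort("need at least two genes per sample to z-score")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  zero <- which(sd_pop == 0)
  if (length(zero) > 0) {
    abort(sprintf("zero variance in sample(s): %s",
                  paste(head(x$sample_id[zero], 5), collapse = ", ")))
  }
  z <- (m - mu) / sd_pop
  x[, colnames(z)] <- expr_tibble(z, x$sample_id)[, colnames(z)]
  x
}
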