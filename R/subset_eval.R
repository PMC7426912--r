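#' Evaluation configuration for stability selection
#'
#' @param n_runs Number of selector runs R (default 100).
#' @param k Cross-validation folds (default 5).
#' @param repeats Repetitions of the k-fold split (default 3).
#' @param base_seed Base RNG seed; run r uses seed `base_seed + r - 1` and
#'   CV repeat r uses fold seed `base_seed + 1000 * r`.
#' @param top_t Number of top-scoring subsets carried forward (default 4).
#' @param svm_cost Soft-margin cost of the linear SVM used in scoring
#'   (default 1).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_runs = 100, k = 5, repeats = 3, base_seed = 1L,
                        top_t = 4, svm_cost = 1) {
  if (k < 2) abort("`k` must be at least 2")
  if (n_runs < 1) abort("`n_runs` must be at least 1")
  if (repeats < 1) abort("`repeats` must be at least 1")
  structure(list(n_runs = as.integer(n_runs), k = as.integer(k),
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed),
                 top_t = as.integer(top_t), svm_cost = svm_cost),
            class = "eval_config")
}

#' Run the DRPT selector repeatedly
#'
#' Produces `config$n_runs` subsets with seeds `base_seed`, `base_seed + 1`,
#' ..., the raw material of stability selection.
#'
#' @param D Labelled, z-scored samples-by-genes tibble.
#' @param params A [drpt_params()] object.
#' @param config An [eval_config()] object.
#' @return A named list of `feature_subset` objects (`run1`, `run2`, ...).
#' @export
run_repeated_selection <- function(D, params = drpt_params(), config = eval_config()) {
  seeds <- config$base_seed + seq_len(config$n_runs) - 1L
  out <- purrr::map(seeds, function(s) drpt_select(D, params, seed = s))
  names(out) <- paste0("run", seq_along(out))
  out
}

#' Stratified k-fold assignment
#'
#' Shuffles each class with the given seed and deals samples to folds
#' cyclically, continuing the cycle across classes, so that within every
#' class and overall the fold sizes differ by at most one. A class smaller
#' than `k` is allowed (some folds then miss that class; with `k` equal to
#' the sample count this degenerates to a leave-one-out partition), but
#' downstream cross-validation requires each held-out fold to contain a
#' positive sample, which holds whenever each class has at least `k`
#' members.
#'
#' @param labels Binary vector (0/1).
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @return Integer vector of fold indices in 1..k, one per sample.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2")
  if (k > length(labels)) abort("more folds than samples")
  folds <- integer(length(labels))
  pos <- 0L
  withr::with_seed(as.integer(seed), {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (pos + seq_along(idx) - 1L) %% k + 1L
      pos <- pos + length(idx)
    }
  })
  folds
}

#' Average precision of a score-ranked labelling
#'
#' Sorts samples by decreasing score, treats tied scores as a single
#' threshold, and sums precision weighted by the recall increments:
#' `AP = sum_n (R_n - R_(n-1)) * P_n` with `R_0 = 0`. This is the standard
#' step-wise summary of the precision-recall curve.
#'
#' @param scores Numeric decision scores (higher = more UC-like).
#' @param labels Binary labels (1 = positive/UC).
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  pts <- pr_points(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

# Shared threshold sweep: one row per distinct score threshold, descending.
pr_points <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores and labels must align")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) abort("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rle(s)$lengths)        # last index of each tied block
  tp <- cumsum(y)[last]
  n_pred <- last
  tibble::tibble(threshold = s[last],
                 recall = tp / n_pos,
                 precision = tp / n_pred)
}

#' Cross-validated average precision of a gene subset
#'
#' Scores a candidate subset by `repeats` repetitions of stratified k-fold
#' cross-validation: in every fold a linear SVM is trained on the subset's
#' columns of the training folds and average precision is computed on the
#' held-out fold. Fold seeds are `base_seed + 1000 * repeat`.
#'
#' @param D Labelled samples-by-genes tibble.
#' @param subset A `feature_subset` (or character vector of gene symbols).
#' @param config An [eval_config()] object.
#' @param id Optional identifier carried into the result.
#' @return An object of class `subset_score`: list with `id`, `genes`,
#'   `size`, `mean_ap`, `sd_ap`, `fold_aps`.
#' @export
cross_validate_subset <- function(D, subset, config = eval_config(), id = NA) {
  genes <- if (inherits(subset, "feature_subset")) subset$genes else as.character(subset)
  missing <- setdiff(genes, expr_genes(D))
  if (length(missing) > 0) {
    abort(sprintf("subset gene(s) absent from dataset: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- expr_matrix(D)[, genes, drop = FALSE]
  y <- as.integer(D$label)
  aps <- numeric(0)
  for (r in seq_len(config$repeats)) {
    folds <- stratified_kfold(y, config$k, seed = config$base_seed + 1000L * r)
    for (f in seq_len(config$k)) {
      test <- folds == f
      fit <- svm_fit(m[!test, , drop = FALSE], y[!test], cost = config$svm_cost)
      sc <- drop(m[test, , drop = FALSE] %*% fit$w) + fit$bias
      aps <- c(aps, average_precision(sc, y[test]))
    }
  }
  structure(list(id = id, genes = genes, size = length(genes),
                 mean_ap = mean(aps), sd_ap = sd(aps), fold_aps = aps),
            class = "subset_score")
}

#' Tidy cross-validation scores
#'
#' @param x A `subset_score`.
#' @param ... Unused.
#' @return One row per CV fold with columns `id`, `fold`, `ap`.
#' @export
tidy.subset_score <- function(x, ...) {
  tibble::tibble(id = x$id, fold = seq_along(x$fold_aps), ap = x$fold_aps)
}

#' One-line summary of a subset score
#'
#' @param x A `subset_score`.
#' @param ... Unused.
#' @return A one-row tibble with `id`, `size`, `mean_ap`, `sd_ap`, `n_folds`.
#' @export
glance.subset_score <- function(x, ...) {
  tibble::tibble(id = x$id, size = x$size, mean_ap = x$mean_ap,
                 sd_ap = x$sd_ap, n_folds = length(x$fold_aps))
}

#' Rank subsets and keep the top t
#'
#' Orders subset scores by mean average precision (descending), breaking
#' ties by smaller subset size and then lower id, and returns the ids of the
#' best `t`. The parsimony tie-break favours panels with fewer genes.
#'
#' @param scores List of `subset_score` objects.
#' @param t How many ids to return.
#' @return The ids of the top `t` subsets, best first.
#' @export
rank_subsets_top_t <- function(scores, t) {
  if (t > length(scores)) abort("`t` exceeds the number of scored subsets")
  tab <- dplyr::bind_rows(purrr::map(scores, glance))
  tab <- tab[order(-tab$mean_ap, tab$size, tab$id), ]
  tab$id[seq_len(t)]
}

#' Count how often each gene was selected
#'
#' @param subsets List of `feature_subset` objects (one per selector run).
#' @return A tibble with columns `gene` and `count`, count-descending then
#'   alphabetical; genes never selected are omitted.
#' @export
selection_frequencies <- function(subsets) {
  if (length(subsets) == 0) abort("need at least one subset")
  genes <- unlist(purrr::map(subsets, function(s) {
    if (inherits(s, "feature_subset")) s$genes else as.character(s)
  }))
  tab <- table(genes)
  out <- tibble::tibble(gene = names(tab), count = as.integer(tab))
  out[order(-out$count, out$gene), ]
}

#' Selection-frequency threshold from normal QQ deviation
#'
#' Finds the selection count above which the observed frequency distribution
#' departs most from a Gaussian: the counts' order statistics are plotted
#' against standard normal quantiles, a reference line is fitted through the
#' first/third-quartile QQ points (as in a standard QQ line), and the
#' threshold is placed where the departure from Gaussian behaviour begins:
#' at the largest count below the terminal run of upper-tail points
#' (positive theoretical quantile) that all sit more than three robust
#' standard deviations (three times the reference-line slope, the usual
#' outlier convention) above the line. The
#' deviating genes themselves thus end up above the threshold. Genes are
#' "frequent" when their count strictly exceeds the threshold. When no
#' tail point deviates, the counts look Gaussian and the maximum count is
#' returned, making the frequent set empty. When all counts are equal the
#' rule is undefined and a manual `override` is required.
#'
#' @param freq Frequency tibble from [selection_frequencies()].
#' @param override Optional integer bypassing the rule.
#' @return Integer threshold `c*`.
#' @export
qq_frequency_threshold <- function(freq, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  counts <- sort(as.numeric(freq$count))
  n <- length(counts)
  if (n < 10) abort("need at least 10 genes to fit the QQ reference line")
  if (length(unique(counts)) == 1) abort("no tail deviation: all counts equal (use `override`)")
  z <- qnorm(ppoints(n))
  qs_obs <- quantile(counts, c(0.25, 0.75), names = FALSE)
  qs_the <- qnorm(c(0.25, 0.75))
  slope <- (qs_obs[2] - qs_obs[1]) / (qs_the[2] - qs_the[1])
  intercept <- qs_obs[1] - slope * qs_the[1]
  dev <- counts - (intercept + slope * z)
  deviating <- z > 0 & dev > 3 * slope
  # no outlying tail: return the maximum count so the frequent set is empty
  # rather than arbitrary
  if (!deviating[n]) return(as.integer(max(counts)))
  onset <- max(which(!deviating)) + 1L   # start of the terminal deviating run
  as.integer(counts[onset - 1L])
}

#' Genes selected more often than the threshold
#'
#' @param freq Frequency tibble from [selection_frequencies()].
#' @param c_star Integer threshold; genes with `count > c_star` are kept.
#' @return A `feature_subset` ordered by count descending then symbol.
#' @export
frequent_gene_subset <- function(freq, c_star) {
  keep <- freq[freq$count > c_star, ]
  if (nrow(keep) == 0) abort(sprintf("no gene selected more than %d times", c_star))
  keep <- keep[order(-keep$count, keep$gene), ]
  structure(list(genes = keep$gene, entropy = NULL, count = keep$count,
                 seed = NA_integer_, params = NULL),
            class = "feature_subset")
}
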