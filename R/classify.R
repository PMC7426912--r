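# Linear SVM fit on a plain matrix; returns a weight vector and bias with
# the convention that positive decision scores favour class 1 (UC).
svm_fit <- function(x, y, cost = 1) {
  if (length(unique(y)) < 2) abort("both classes must be present to train")
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  bias <- -fit$rho
  # libsvm orients decision values toward the first class it encounters;
  # flip when that class is not 1 so positive scores always favour class 1
  if (as.character(fit$levels[fit$labels[1]]) != "1") {
    w <- -w
    bias <- -bias
  }
  list(w = w, bias = bias)
}

#' Train the final linear SVM on a gene panel
#'
#' Fits a soft-margin linear support vector machine on the panel's columns of
#' the (per-sample z-scored) training data. The resulting model stores one
#' weight per panel gene and a bias; the decision score of a sample `z` is
#' `w . z + bias`, with positive scores favouring the UC class.
#'
#' @param D Labelled samples-by-genes tibble (z-scored).
#' @param panel A `feature_subset` or character vector of panel genes.
#' @param cost Soft-margin regularisation parameter C (default 1).
#' @return An object of class `uc_svm`: list with `genes`, `w`, `bias`,
#'   `cost`, `normalization`.
#' @export
train_linear_svm <- function(D, panel, cost = 1) {
  assert_labelled(D)
  genes <- if (inherits(panel, "feature_subset")) panel$genes else as.character(panel)
  missing <- setdiff(genes, expr_genes(D))
  if (length(missing) > 0) {
    abort(sprintf("panel gene(s) absent from dataset: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- expr_matrix(D)[, genes, drop = FALSE]
  fit <- svm_fit(m, as.integer(D$label), cost = cost)
  structure(list(genes = genes, w = unname(fit$w), bias = fit$bias,
                 cost = cost, normalization = "zscore_per_sample"),
            class = "uc_svm")
}

#' @export
print.uc_svm <- function(x, ...) {
  cat(sprintf("<uc_svm> linear SVM on %d genes (C = %g, expects %s input)\n",
              length(x$genes), x$cost, x$normalization))
  invisible(x)
}

#' Tidy a trained panel SVM
#'
#' @param x A `uc_svm` model.
#' @param ... Unused.
#' @return A tibble with one row per panel gene (`gene`, `weight`).
#' @export
tidy.uc_svm <- function(x, ...) {
  tibble::tibble(gene = x$genes, weight = x$w)
}

#' One-line summary of a trained panel SVM
#'
#' @param x A `uc_svm` model.
#' @param ... Unused.
#' @return A one-row tibble with `n_genes`, `bias`, `cost`, `normalization`.
#' @export
glance.uc_svm <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), bias = x$bias, cost = x$cost,
                 normalization = x$normalization)
}

#' Decision scores of a model on new samples
#'
#' Matches panel genes by symbol (column order in `X` is irrelevant) and
#' returns `w . z + bias` per sample. `X` must already follow the model's
#' recorded normalisation convention.
#'
#' @param model A `uc_svm` model.
#' @param X Samples-by-genes tibble containing every panel gene.
#' @return Named numeric vector of decision scores (names = sample IDs).
#' @export
decision_scores <- function(model, X) {
  missing <- setdiff(model$genes, expr_genes(X))
  if (length(missing) > 0) {
    abort(sprintf("panel gene(s) missing from data: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  m <- expr_matrix(X)[, model$genes, drop = FALSE]
  setNames(drop(m %*% model$w) + model$bias, X$sample_id)
}

#' Precision-recall curve of scored samples
#'
#' One point per distinct score threshold, descending, with tied scores
#' grouped; the stored average precision equals [average_precision()] on the
#' same scores exactly.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels (1 = UC).
#' @return A tibble of class `pr_curve` with columns `threshold`, `recall`,
#'   `precision` and attribute `average_precision`.
#' @export
precision_recall_curve <- function(scores, labels) {
  pts <- pr_points(scores, labels)
  ap <- sum(diff(c(0, pts$recall)) * pts$precision)
  structure(pts, class = c("pr_curve", class(pts)), average_precision = ap)
}

#' Average precision stored on a PR curve
#'
#' @param curve A `pr_curve`.
#' @return The curve's average precision.
#' @export
curve_ap <- function(curve) {
  attr(curve, "average_precision")
}

#' Validate a model on a held-out labelled dataset
#'
#' Computes decision scores on the validation samples (which must be
#' normalised per-sample, the model's recorded convention) and summarises
#' them as a precision-recall curve.
#'
#' @param model A `uc_svm` model.
#' @param validation Labelled samples-by-genes tibble.
#' @return A `pr_curve`.
#' @export
evaluate_model <- function(model, validation) {
  assert_labelled(validation)
  sc <- decision_scores(model, validation)
  precision_recall_curve(sc, validation$label)
}

#' Friedman rank test across models and datasets
#'
#' Ranks the models within every dataset (average ranks on ties) and
#' computes the Friedman chi-square statistic
#' `12 N / (k (k + 1)) * sum_j (Rbar_j - (k + 1) / 2)^2` for `k` models over
#' `N` datasets, with the p-value from the chi-square distribution on
#' `k - 1` degrees of freedom. Used to ask whether candidate panels perform
#' comparably across validation datasets.
#'
#' @param ap_matrix Numeric matrix, models in rows, datasets in columns.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n_models`,
#'   `n_datasets`.
#' @export
friedman_compare <- function(ap_matrix) {
  ap_matrix <- as.matrix(ap_matrix)
  k <- nrow(ap_matrix)
  n <- ncol(ap_matrix)
  if (k < 2 || n < 2) abort("need at least 2 models and 2 datasets")
  ranks <- apply(ap_matrix, 2, rank)
  rbar <- rowMeans(ranks)
  stat <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  tibble::tibble(statistic = stat, df = k - 1,
                 p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
                 n_models = k, n_datasets = n)
}
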