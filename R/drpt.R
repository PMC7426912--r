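#' DRPT tuning parameters
#'
#' Knobs of the perturbation-based feature selector. Defaults follow the
#' package's documented realisation of the method: `alpha` scales the
#' local-maximum magnitude threshold; `epsilon` is the relative scale of the
#' Gaussian perturbation; features whose weight change exceeds the
#' `delta_quantile` quantile are flagged as unstable; flagged features are
#' kept only while pairwise absolute Pearson correlation with already-kept
#' features stays below `rho`; `n_bins` controls the equal-width entropy
#' discretisation; `max_features` optionally caps the subset size.
#'
#' @param alpha Positive multiplier on the mean of local-maximum weights
#'   (default 1).
#' @param epsilon Perturbation scale relative to the sd of the data entries.
#'   The default 1 re-solves the system under a second, equally strong
#'   realisation of measurement noise, which is what makes repeated runs
#'   select genuinely different borderline features while robust features
#'   persist; values near 0 make every run return the same subset.
#' @param delta_quantile Quantile of the weight-change vector above which a
#'   feature counts as unstable (default 0.90).
#' @param rho Absolute-correlation cutoff for redundancy (default 0.95).
#' @param n_bins Number of equal-width bins for feature entropy (default 10).
#' @param max_features Optional upper bound on subset size (default `NULL`).
#' @return An object of class `drpt_params`.
#' @export
drpt_params <- function(alpha = 1, epsilon = 1, delta_quantile = 0.90,
                        rho = 0.95, n_bins = 10, max_features = NULL) {
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(epsilon, "epsilon")
  assert_scalar_number(delta_quantile, "delta_quantile")
  assert_scalar_number(rho, "rho")
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (epsilon <= 0) abort("`epsilon` must be > 0")
  if (delta_quantile < 0 || delta_quantile > 1) abort("`delta_quantile` must be in [0, 1]")
  if (rho <= 0 || rho > 1) abort("`rho` must be in (0, 1]")
  if (!is.numeric(n_bins) || n_bins < 1) abort("`n_bins` must be a positive integer")
  if (!is.null(max_features) && (!is.numeric(max_features) || max_features < 1)) {
    abort("`max_features` must be NULL or a positive integer")
  }
  structure(list(alpha = alpha, epsilon = epsilon,
                 delta_quantile = delta_quantile, rho = rho,
                 n_bins = as.integer(n_bins),
                 max_features = if (is.null(max_features)) NULL else as.integer(max_features)),
            class = "drpt_params")
}

#' Minimum 2-norm least-squares solution of A x = b
#'
#' Among all least-squares minimisers of ||Ax - b||_2, returns the one of
#' minimal Euclidean norm (the Moore-Penrose solution), computed from the
#' thin singular value decomposition with singular values below
#' `max(dim(A)) * eps * max(d)` treated as zero. Component `x[i]` is read as
#' the weight of feature i in explaining the label vector.
#'
#' @param A Numeric matrix (samples x features).
#' @param b Numeric vector, one entry per row of `A`.
#' @return Numeric vector of length `ncol(A)`.
#' @export
min_norm_solution <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (!all(is.finite(A)) || !all(is.finite(b))) abort("non-finite entries in A or b")
  if (nrow(A) != length(b)) abort("nrow(A) must equal length(b)")
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(numeric(ncol(A)))
  drop(s$v[, keep, drop = FALSE] %*%
         (crossprod(s$u[, keep, drop = FALSE], b) / s$d[keep]))
}

#' Retain features whose weight clears the local-maximum threshold
#'
#' Scans `|x|` in the original feature order, marks every index whose value
#' is at least as large as each existing neighbour as a local maximum, and
#' retains all features with `|x| >= alpha * mean(|x| at local maxima)`. For
#' `alpha <= 1` the retained set always contains the global maximum.
#'
#' @param x Weight vector.
#' @param alpha Positive threshold multiplier.
#' @return Sorted integer vector of retained feature indices.
#' @export
local_maximum_filter <- function(x, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) abort("`alpha` must be > 0")
  w <- abs(as.numeric(x))
  n <- length(w)
  if (n == 0) abort("empty weight vector")
  left <- c(-Inf, w[-n])
  right <- c(w[-1], -Inf)
  locmax <- w >= left & w >= right
  threshold <- alpha * mean(w[locmax])
  which(w >= threshold)
}

#' Perturb the reduced system and measure weight instability
#'
#' Adds an i.i.d. Gaussian matrix `E` with standard deviation
#' `epsilon * sd(A_r)` to the reduced data, re-solves the minimum-norm system
#' and returns the absolute component-wise change `delta = |x_tilde - x|`.
#' Correlated (redundant) features split their weight unstably between each
#' other, so they show large `delta`; this is the randomness that makes
#' repeated runs of the selector produce different subsets.
#'
#' @param A_r Reduced numeric matrix (samples x retained features).
#' @param b Label vector.
#' @param epsilon Relative perturbation scale (> 0).
#' @param seed Integer RNG seed; results are reproducible given the seed.
#' @return An object of class `perturbation_result`: list with `x`,
#'   `x_tilde`, `delta`, `epsilon`, `seed`.
#' @export
perturb_and_delta <- function(A_r, b, epsilon = 1e-3, seed = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("`epsilon` must be > 0")
  }
  A_r <- as.matrix(A_r)
  if (length(A_r) == 0) abort("empty reduced matrix")
  x <- min_norm_solution(A_r, b)
  noise_sd <- epsilon * sd(as.vector(A_r))
  E <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(length(A_r), sd = noise_sd),
                               nrow = nrow(A_r)))
  x_tilde <- min_norm_solution(A_r + E, b)
  structure(list(x = x, x_tilde = x_tilde, delta = abs(x_tilde - x),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "perturbation_result")
}

#' Shannon entropy of a feature under equal-width binning
#'
#' Discretises the values into `n_bins` equal-width bins over their range
#' (one bin when the range is zero) and returns the entropy in bits,
#' `-sum(p * log2(p))` over non-empty bins. Bounded by `log2(n_bins)`.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins (default 10).
#' @return Entropy in bits.
#' @export
feature_entropy <- function(values, n_bins = 10) {
  values <- as.numeric(values)
  if (length(values) == 0) abort("empty value vector")
  if (!is.numeric(n_bins) || n_bins < 1) abort("`n_bins` must be a positive integer")
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  bin <- pmin(floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, as.integer(n_bins))
  p <- tabulate(bin, nbins = as.integer(n_bins))
  p <- p[p > 0] / length(values)
  -sum(p * log2(p))
}

#' Drop redundant unstable features
#'
#' Features whose perturbation instability `delta` is at or below the
#' `delta_quantile` quantile — and which are not strongly correlated
#' (absolute Pearson correlation at or above `rho`) with any other feature —
#' are kept outright as stable. The flagged remainder (unstable features,
#' plus every member of a strongly correlated pair, whose weight splitting
#' is inherently unstable) is visited in entropy-descending order (ties:
#' lower column index) and each is kept only if its absolute correlation
#' with every already-kept feature is below `rho`, so exactly one
#' representative of a duplicated or block-correlated gene group survives.
#'
#' @param A_r Reduced matrix whose columns the other arguments index.
#' @param delta Instability vector from [perturb_and_delta()].
#' @param entropies Per-feature entropies.
#' @param params A [drpt_params()] object.
#' @return Sorted integer vector of kept column indices (never empty).
#' @export
redundancy_prune <- function(A_r, delta, entropies, params = drpt_params()) {
  A_r <- as.matrix(A_r)
  n <- ncol(A_r)
  stopifnot(length(delta) == n, length(entropies) == n)
  q <- unname(quantile(delta, params$delta_quantile))
  cm <- suppressWarnings(abs(cor(A_r)))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  correlated <- apply(cm, 1, max) >= params$rho
  kept <- which(delta <= q & !correlated)
  flagged <- setdiff(seq_len(n), kept)
  flagged <- flagged[order(-entropies[flagged], flagged)]
  for (j in flagged) {
    if (length(kept) == 0) {
      kept <- j
      next
    }
    r <- suppressWarnings(abs(cor(A_r[, j], A_r[, kept, drop = FALSE])))
    r[is.na(r)] <- 0                      # constant column: no evidence of redundancy
    if (all(r < params$rho)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Select a gene subset with the DRPT procedure
#'
#' Runs the full selector on a labelled, z-scored dataset: minimum-norm
#' feature weights, local-maximum magnitude filtering, Gaussian perturbation
#' of the reduced system with redundancy pruning of unstable correlated
#' features, a second local-maximum filter on the perturbed weights (a
#' feature earns its place only if its weight survives re-solving under
#' fresh noise), and final entropy-descending ordering (optionally truncated
#' to `max_features`). Deterministic given `seed`; different seeds perturb
#' with different noise, so robust features recur across runs while
#' borderline ones churn — the signal that stability selection counts.
#'
#' @param D Labelled samples-by-genes tibble (z-scored, no missing values).
#' @param params A [drpt_params()] object.
#' @param seed Integer RNG seed for the perturbation.
#' @return An object of class `feature_subset`: list with `genes` (ordered
#'   entropy-descending), `entropy`, `seed` and `params`.
#' @export
drpt_select <- function(D, params = drpt_params(), seed = 1L) {
  assert_labelled(D)
  assert_complete(D)
  m <- expr_matrix(D)
  b <- as.numeric(D$label)
  if (length(unique(b)) < 2) abort("both classes must be present")
  genes <- colnames(m)
  x <- min_norm_solution(m, b)
  idx1 <- local_maximum_filter(x, params$alpha)
  A_r <- m[, idx1, drop = FALSE]
  pert <- perturb_and_delta(A_r, b, params$epsilon, seed)
  H <- apply(A_r, 2, feature_entropy, n_bins = params$n_bins)
  kept <- redundancy_prune(A_r, pert$delta, H, params)
  # keep only features whose weight also clears the magnitude bar after the
  # noisy re-solve; the global maximum always does, so this never empties
  # the intersection down to nothing unless pruning removed it first
  strong <- local_maximum_filter(pert$x_tilde, params$alpha)
  final <- intersect(kept, strong)
  if (length(final) == 0) final <- kept[which.max(H[kept])]
  ord <- final[order(-H[final], final)]
  if (!is.null(params$max_features)) ord <- head(ord, params$max_features)
  structure(list(genes = genes[idx1][ord],
                 entropy = unname(H[ord]),
                 seed = as.integer(seed),
                 params = params),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %d genes (seed %s)\n",
              length(x$genes), ifelse(is.na(x$seed), "-", x$seed)))
  cat(" ", paste(head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Write and read a feature subset as a plain-text gene list
#'
#' The genes are written one symbol per line, in their selection order, with
#' a JSON sidecar (`<path>.json`) recording the seed and selector parameters
#' that produced the subset.
#'
#' @param subset A `feature_subset`.
#' @param path Output path for the gene list.
#' @return `path`, invisibly (for the writer); a `feature_subset` (reader).
#' @export
write_feature_subset <- function(subset, path) {
  writeLines(subset$genes, path)
  jsonlite::write_json(list(seed = subset$seed,
                            params = unclass(subset$params)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_subset
#' @export
read_feature_subset <- function(path) {
  genes <- readLines(path)
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"))
  }
  params <- if (!is.null(meta$params)) {
    # JSON has no distinct NULL scalar: unset optional fields come back as
    # empty lists and are dropped before rebuilding the parameter object
    do.call(drpt_params, purrr::discard(meta$params, function(v) length(v) == 0))
  }
  seed <- if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed)
  structure(list(genes = genes, entropy = NULL, seed = seed, params = params),
            class = "feature_subset")
}

#' Tidy a selected feature subset
#'
#' @param x A `feature_subset`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `gene`, `entropy`.
#' @export
tidy.feature_subset <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$genes), gene = x$genes,
                 entropy = if (is.null(x$entropy)) NA_real_ else x$entropy)
}
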