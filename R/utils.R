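# Internal helpers shared across the pipeline.
#
# Expression tables travel as wide tibbles:
#   * probe level : `probe_id` column + one numeric column per sample
#   * sample level: `sample_id` column, optional `label` column (0 = control,
#     1 = UC), + one numeric column per gene

RESERVED_COLS <- c("sample_id", "label", "probe_id")

#' Gene columns of a sample-level expression tibble
#'
#' @param x A samples-by-genes expression tibble (`sample_id`, optional
#'   `label`, one column per gene).
#' @return Character vector of gene symbols in column order.
#' @export
expr_genes <- function(x) {
  setdiff(names(x), RESERVED_COLS)
}

#' Numeric matrix view of a sample-level expression tibble
#'
#' @inheritParams expr_genes
#' @return A samples x genes numeric matrix with sample IDs as row names.
#' @export
expr_matrix <- function(x) {
  genes <- expr_genes(x)
  m <- as.matrix(x[, genes, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

# Rebuild a sample-level tibble from a samples x genes matrix, carrying labels.
expr_tibble <- function(m, sample_ids, labels = NULL) {
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE),
                           .name_repair = "minimal")
  out <- tibble::add_column(out, sample_id = sample_ids, .before = 1)
  if (!is.null(labels)) {
    out <- tibble::add_column(out, label = as.integer(labels), .after = "sample_id")
  }
  out
}

assert_labelled <- function(x, what = "dataset") {
  if (!"label" %in% names(x)) {
    abort(sprintf("%s must carry a `label` column (0 = control, 1 = UC)", what))
  }
  if (!all(x$label %in% c(0L, 1L))) {
    abort(sprintf("%s labels must be 0 or 1", what))
  }
  invisible(x)
}

assert_complete <- function(x, what = "matrix") {
  if (anyNA(expr_matrix(x))) {
    abort(sprintf("%s contains missing values; impute first", what))
  }
  invisible(x)
}

assert_scalar_number <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(v)
}
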