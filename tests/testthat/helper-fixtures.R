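# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Wide sample-level expression tibble from a samples x genes matrix.
make_expr <- function(m, labels = NULL, sample_ids = NULL, genes = NULL) {
  m <- as.matrix(m)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(m)))
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  colnames(m) <- genes
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE))
  out <- tibble::add_column(out, sample_id = sample_ids, .before = 1)
  if (!is.null(labels)) {
    out <- tibble::add_column(out, label = as.integer(labels), .after = "sample_id")
  }
  out
}

# Probe-level tibble from a probes x samples matrix.
make_probe_tbl <- function(m, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(m)
  if (is.null(probe_ids)) probe_ids <- paste0("p", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE))
  tibble::add_column(out, probe_id = probe_ids, .before = 1)
}

# Random z-scored labelled dataset with planted signal in `signal_cols`.
make_labelled_dataset <- function(seed, m = 40, n = 60, effect = 1.5,
                                  signal_cols = c(1, 5), duplicate_of = NULL) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = m / 2)
    A <- matrix(rnorm(m * n), m, n)
    for (j in signal_cols) A[, j] <- A[, j] + effect * y
    if (!is.null(duplicate_of)) A[, duplicate_of[2]] <- A[, duplicate_of[1]]
    zscore_per_sample(make_expr(A, labels = y))
  })
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
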