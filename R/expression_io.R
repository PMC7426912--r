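#' Read a delimited expression table
#'
#' Reads a tab-separated expression table with one header row and one ID
#' column, as exported from GEO series matrices. Blank cells and the tokens
#' `NA`/`NaN` (case-insensitive) become missing values. The result is always
#' oriented probes-in-rows: a `probe_id` column plus one numeric column per
#' sample.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"probes_in_rows"` (default; first column is the
#'   probe/gene ID, remaining columns are samples) or `"samples_in_rows"`
#'   (first column is the sample ID, remaining columns are probes/genes).
#' @return A tibble with a `probe_id` column and one double column per sample.
#' @export
read_expression_table <- function(path,
                                  orientation = c("probes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        name_repair = "minimal")
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("ragged table: row %d of '%s' (%s)",
                  prob$row[1], path, prob$expected[1]))
  }
  if (ncol(df) < 2) abort(sprintf("'%s' has no data columns", path))
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate row IDs in '%s': %s", path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[tolower(trimws(vals)) %in% c("", "na", "nan")] <- NA
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (orientation == "samples_in_rows") vals <- t(vals)
  out <- tibble::as_tibble(as.data.frame(vals, optional = TRUE),
                           .name_repair = "minimal")
  tibble::add_column(out, probe_id = rownames(vals), .before = 1)
}

#' Write a probe-level expression table
#'
#' Inverse of [read_expression_table()]: writes a `probe_id` + samples tibble
#' as TSV with `NA` for missing entries, so that a read/write/read round trip
#' reproduces all observed values.
#'
#' @param pm Probe-level tibble (`probe_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(pm, path) {
  readr::write_tsv(pm, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Reads a two-column TSV (`probe_id`, `gene_symbol`). Probes with an empty
#' symbol are unmapped and dropped, as are probes annotated with a composite
#' multi-gene symbol (e.g. `"G1///G2"`), which cannot be averaged into a
#' single gene. A probe mapped to two different symbols is an error.
#'
#' @param path Path to a TSV file with columns probe ID and gene symbol.
#' @return A tibble with columns `probe_id` and `gene_symbol`, one row per
#'   mapped probe.
#' @export
read_probe_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        name_repair = "minimal")
  if (nrow(df) == 0) {
    return(tibble::tibble(probe_id = character(), gene_symbol = character()))
  }
  if (ncol(df) < 2) abort(sprintf("'%s' is not a two-column probe map", path))
  map <- tibble::tibble(probe_id = as.character(df[[1]]),
                        gene_symbol = trimws(as.character(df[[2]])))
  map <- dplyr::distinct(map)
  conflict <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(conflict) > 0) {
    abort(sprintf("probe(s) mapped to more than one symbol: %s",
                  paste(head(conflict, 5), collapse = ", ")))
  }
  dplyr::filter(map,
                !is.na(.data$gene_symbol),
                .data$gene_symbol != "",
                tolower(.data$gene_symbol) != "na",
                !grepl("///", .data$gene_symbol, fixed = TRUE))
}

#' Collapse probe-level values to gene level
#'
#' Drops probes without a gene mapping and summarises each gene, per sample,
#' as the arithmetic mean of the gene's non-missing probe values. A gene whose
#' probes are all missing for a sample stays missing there. The output is
#' sample-level: `sample_id` + one column per gene, genes in sorted symbol
#' order.
#'
#' @param pm Probe-level tibble from [read_expression_table()].
#' @param map Probe map tibble from [read_probe_map()].
#' @return A samples-by-genes tibble.
#' @export
collapse_probes_to_genes <- function(pm, map) {
  idx <- match(pm$probe_id, map$probe_id)
  mapped <- !is.na(idx)
  if (!any(mapped)) abort("no mapped probes")
  genes <- map$gene_symbol[idx[mapped]]
  vals <- as.matrix(pm[mapped, setdiff(names(pm), "probe_id"), drop = FALSE])
  mode(vals) <- "double"
  obs <- !is.na(vals)
  vals[!obs] <- 0
  sums <- rowsum(vals, genes)
  counts <- rowsum(obs + 0, genes)
  means <- sums / counts           # 0/0 -> NaN where every probe is missing
  means[counts == 0] <- NA
  means <- means[order(rownames(means)), , drop = FALSE]
  expr_tibble(t(means), sample_ids = colnames(means))
}

#' Read a sample label file
#'
#' @param path TSV with columns sample ID and label (0 = control, 1 = UC).
#' @return Tibble with columns `sample_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, name_repair = "minimal")
  out <- tibble::tibble(sample_id = as.character(df[[1]]),
                        label = suppressWarnings(as.integer(df[[2]])))
  if (anyNA(out$label) || !all(out$label %in% c(0L, 1L))) {
    abort(sprintf("labels in '%s' must be 0 or 1", path))
  }
  out
}

#' Attach labels to a sample-level expression tibble
#'
#' @param x Samples-by-genes tibble.
#' @param labels Tibble with `sample_id` and `label` columns.
#' @return `x` with a `label` column inserted after `sample_id`.
#' @export
attach_labels <- function(x, labels) {
  idx <- match(x$sample_id, labels$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("no label for sample(s): %s",
                  paste(head(x$sample_id[is.na(idx)], 5), collapse = ", ")))
  }
  x$label <- NULL
  tibble::add_column(x, label = as.integer(labels$label[idx]), .after = "sample_id")
}
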