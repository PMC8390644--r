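# Plain-text I/O for the pipeline's tables. Spectral counts travel as a
# long TSV (one row per protein x experiment x role), matrices as TSV with
# a header row of sample ids and row names in the first column.

#' Write spectral-count records as a long TSV
#'
#' Columns: `protein_id`, `experiment_id`, `role` (bait/control),
#' `counts`, `id_score`, `n_peptides`.
#'
#' @param records wide records tibble (see [filter_identifications()]).
#' @param path output path.
#' @export
write_spectral_counts <- function(records, path) {
  check_spectral_records(records)
  long <- dplyr::bind_rows(
    dplyr::transmute(records, .data$protein_id, .data$experiment_id,
                     role = "bait", counts = .data$bait_counts,
                     id_score = .data$identification_score,
                     n_peptides = .data$n_peptides),
    dplyr::transmute(records, .data$protein_id, .data$experiment_id,
                     role = "control", counts = .data$control_counts,
                     id_score = .data$identification_score,
                     n_peptides = .data$n_peptides)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long spectral-count TSV back into wide records
#'
#' @param path TSV written by [write_spectral_counts()] (or equivalent).
#' @return wide records tibble.
#' @export
read_spectral_counts <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("protein_id", "experiment_id", "role", "counts")
  if (!all(need %in% names(long)))
    stop("spectral-count TSV needs columns: ", paste(need, collapse = ", "))
  wide <- tidyr::pivot_wider(long, names_from = "role",
                             values_from = "counts", values_fill = 0L)
  tibble::tibble(
    protein_id = wide$protein_id,
    experiment_id = wide$experiment_id,
    bait_counts = as.integer(wide$bait),
    control_counts = as.integer(wide$control),
    identification_score = if ("id_score" %in% names(wide))
      wide$id_score else Inf,
    n_peptides = if ("n_peptides" %in% names(wide))
      as.integer(wide$n_peptides) else .Machine$integer.max
  )
}

#' Write a numeric matrix as TSV with row names in the first column
#' @param mat matrix with row and column names.
#' @param path output path.
#' @param id_column name for the row-name column, default `"id"`.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
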