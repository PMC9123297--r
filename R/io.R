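#' Read and write rectangular datasets with empty cells as missing
#'
#' Datasets (complete, amputed or completed) round-trip through plain CSV
#' with the header naming the columns and missing cells written as empty
#' fields, so the missingness mask is recoverable from emptiness.
#'
#' @param data A data frame.
#' @param path File path.
#' @return `write_dataset_csv()` returns `data` invisibly;
#'   `read_dataset_csv()` returns a tibble with empty cells read as `NA`.
#' @export
write_dataset_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path, na = "")
  invisible(data)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  readr::read_csv(path, na = "", col_types = readr::cols(.default = "d"),
                  progress = FALSE)
}

#' Serialize an imputed stack to a directory of CSV files
#'
#' Writes the incomplete source data, the `m` completed datasets and a JSON
#' manifest recording the imputation configuration.
#'
#' @param stack An [impute_chained()] result.
#' @param dir Directory to create.
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputed_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset_csv(stack$amputed, file.path(dir, "amputed.csv"))
  for (i in seq_len(stack$m)) {
    write_dataset_csv(stack$completed[[i]],
                      file.path(dir, sprintf("imputation_%03d.csv", i)))
  }
  manifest <- stack[c("method", "m", "n_cycles", "donors", "n_trees", "seed")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_imputed_stack
#' @export
read_imputed_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^imputation_\\d+\\.csv$",
                           full.names = TRUE))
  structure(
    c(
      list(
        completed = lapply(files, read_dataset_csv),
        amputed = read_dataset_csv(file.path(dir, "amputed.csv"))
      ),
      manifest
    ),
    class = "imputed_stack"
  )
}
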