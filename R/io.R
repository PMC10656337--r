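#' Read a response CSV
#'
#' Reads a CSV with a header row, one binary group column (0 = reference,
#' 1 = focal) and binary 0/1 item columns, and validates it. Respondents
#' with missing values are rejected with an informative error (the
#' marginal likelihood assumes complete data).
#'
#' @param path Path to the CSV file.
#' @param group_col Name of the group column. Default `"group"`.
#' @return A `response_data` object.
#' @export
read_responses_csv <- function(path, group_col = "group") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_response_data(df, group_col = group_col)
}

#' Write a response dataset to CSV
#'
#' @param data A data frame with group + item columns, or a
#'   `response_data` object.
#' @param path Output path.
#' @param group_col Group column name used in the output.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(data, path, group_col = "group") {
  rd <- as_response_data(data, group_col = group_col)
  df <- as_tibble(rd)
  names(df)[1] <- group_col
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write an inference table as TSV plus JSON metadata
#'
#' Serialises a [dif_infer()] result: a TSV with columns `item`,
#' `gamma_hat`, `ci_lo`, `ci_hi`, `p_value`, `bh_reject`, and (when
#' jsonlite is available) a sidecar `<path>.meta.json` recording `M`,
#' `level`, `alpha` and `seed`.
#'
#' @param inference A `dif_inference` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_inference_tsv <- function(inference, path) {
  stopifnot(inherits(inference, "dif_inference"))
  readr::write_tsv(
    inference[c("item", "gamma_hat", "ci_lo", "ci_hi", "p_value",
                "bh_reject")],
    path, progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(M = attr(inference, "M"), level = attr(inference, "level"),
                 alpha = attr(inference, "alpha"),
                 seed = attr(inference, "seed"))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
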