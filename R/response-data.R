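#' Validate and convert a response data frame
#'
#' User-facing functions in ml1dif take a data frame with one row per
#' respondent: a binary group column (0 = reference, 1 = focal) plus one
#' binary 0/1 column per item. `as_response_data()` validates it and builds
#' the internal representation used by the likelihood code.
#'
#' @param data A data frame (or an existing `response_data` object, returned
#'   unchanged), or a binary matrix when `groups` is supplied.
#' @param group_col Name of the group column. Default `"group"`.
#' @param groups Optional group vector when `data` is a bare matrix.
#'
#' @return An object of class `response_data`: a list with `responses`
#'   (N x J integer matrix), `groups` (length-N integer vector) and `items`
#'   (item names).
#' @export
as_response_data <- function(data, group_col = "group", groups = NULL) {
  if (inherits(data, "response_data")) return(data)
  if (is.matrix(data)) {
    if (is.null(groups))
      abort("`groups` must be supplied when `data` is a matrix.")
    Y <- data
    x <- as.numeric(groups)
    items <- colnames(Y) %||% paste0("item", seq_len(ncol(Y)))
  } else {
    data <- as.data.frame(data)
    if (!group_col %in% names(data))
      abort(sprintf("Group column '%s' not found in `data`.", group_col))
    x <- as.numeric(data[[group_col]])
    item_cols <- setdiff(names(data), group_col)
    if (length(item_cols) < 1L) abort("No item columns found.")
    Y <- as.matrix(data[item_cols])
    items <- item_cols
  }
  if (anyNA(Y) || anyNA(x)) {
    bad <- which(rowSums(is.na(cbind(Y, x))) > 0)
    abort(sprintf(
      "Missing values are not supported (rows: %s). Remove incomplete respondents first.",
      paste(head(bad, 5), collapse = ", ")))
  }
  storage.mode(Y) <- "numeric"
  bad_cell <- which(!(Y == 0 | Y == 1), arr.ind = TRUE)
  if (nrow(bad_cell) > 0)
    abort(sprintf(
      "Non-binary response value %s at row %d, item '%s'. Responses must be 0/1.",
      format(Y[bad_cell[1, , drop = FALSE]]), bad_cell[1, 1],
      items[bad_cell[1, 2]]))
  if (!all(x %in% c(0, 1)))
    abort("Group labels must be 0 (reference) or 1 (focal).")
  if (nrow(Y) < 1L) abort("At least one respondent is required.")
  storage.mode(Y) <- "integer"
  colnames(Y) <- items
  structure(list(responses = Y, groups = as.integer(x), items = items),
            class = "response_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf(
    "<response_data> N = %d (reference %d, focal %d), J = %d items\n",
    nrow(x$responses), sum(x$groups == 0), sum(x$groups == 1),
    ncol(x$responses)))
  invisible(x)
}

# Checks needed at fit time (stricter than evaluation-time validity).
check_fit_ready <- function(rd) {
  Y <- rd$responses
  if (ncol(Y) < 3L)
    abort("Fitting requires at least 3 items (J >= 3) for identifiability.")
  if (sum(rd$groups == 0) < 1L || sum(rd$groups == 1) < 1L)
    abort("Fitting requires at least one respondent in each group.")
  p <- colMeans(Y)
  const <- which(p == 0 | p == 1)
  if (length(const) > 0)
    abort(sprintf(
      "Item(s) %s have constant responses (all 0 or all 1) and cannot be fitted.",
      paste(rd$items[const], collapse = ", ")))
  invisible(rd)
}

#' Response data as a tibble
#'
#' @param x A `response_data` object.
#' @param ... Unused.
#' @return A tibble with a `group` column followed by the item columns.
#' @export
as_tibble.response_data <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$responses))
  dplyr::bind_cols(tibble::tibble(group = x$groups), out)
}
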