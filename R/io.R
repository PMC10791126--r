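# Plain-text (TSV) interchange: trial tables, pre/post samples, event
# tables, draws, and fixed-effect summaries. Floats are written with 6
# significant digits.

format_num_cols <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' Read and write tab-separated tables
#'
#' Thin wrappers with the package's conventions: tab separator, header
#' row, no quoting, doubles at 6 significant digits.
#'
#' @param df A data.frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(format_num_cols(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @export
write_trial_table <- function(df, path) write_tsv(df, path)

#' @rdname write_tsv
#' @export
read_trial_table <- function(path) {
  df <- read_tsv(path)
  need <- c("subject_id", "group", "rating", "censored")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("not a trial table; missing: ", paste(miss, collapse = ", "))
  df
}

#' @rdname write_tsv
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  if (!all(c("onset", "duration", "trial_type") %in% names(df)))
    stop("not an events table (need onset, duration, trial_type)")
  df
}

#' Long-format draws table of a fit
#'
#' Serializes posterior draws as (parameter, chain, draw, value) rows,
#' suitable for TSV storage and re-analysis.
#'
#' @param fit A `vas_fit` or `roi_fit`.
#' @param parameters Optional subset of parameter labels.
#' @return A data.frame.
#' @export
draws_table <- function(fit, parameters = NULL) {
  out <- lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]]
    if (!is.null(parameters)) m <- m[, parameters, drop = FALSE]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, draw = seq_len(nrow(m)),
               value = as.vector(m))
  })
  do.call(rbind, out)
}
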