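#' Read a delimited time-series file
#'
#' Expects one row per time point and one column per channel, with a header
#' row of channel names. Comma (`.csv`) or tab (anything else) delimited;
#' lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @return Numeric matrix (time x channel) with channel names.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("series file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric column(s) in %s: %s", path,
                 paste(names(df)[bad], collapse = ", ")))
  as_series_matrix(df)
}

#' Write a time series to a delimited file
#'
#' @param X Series matrix or vector.
#' @param path Output path; `.csv` for comma-separated, otherwise tabs.
#' @export
write_series <- function(X, path) {
  X <- as_series_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("ch", seq_len(ncol(X)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(X, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground-truth change points
#'
#' Accepts either one integer index per line, or a delimited file with a
#' header containing a column named `t`. Lines starting with `#` are
#' ignored. Indices are 1-based.
#'
#' @param path Path to the file.
#' @return Sorted integer vector of change-point times.
#' @export
read_changepoints <- function(path) {
  if (!file.exists(path)) stop(sprintf("change-point file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  if (!length(lines)) return(integer(0))
  if (grepl("[^0-9[:space:]+-]", lines[1])) {
    sep <- if (grepl(",", lines[1])) "," else "\t"
    df <- utils::read.table(text = lines, header = TRUE, sep = sep)
    if (!"t" %in% names(df)) stop("expected a column named 't'")
    v <- df$t
  } else {
    v <- as.numeric(lines)
  }
  if (anyNA(v)) stop(sprintf("non-integer change-point entries in %s", path))
  sort(as.integer(v))
}

#' Write a change-score series to a delimited file
#'
#' Writes `t,score` rows for every time point, with an empty score field
#' where the score is undefined, preceded by a `#` header line echoing the
#' method and parameters.
#'
#' @param fit A fitted [cpd()] object.
#' @param path Output path.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "cpd"))
  hdr <- sprintf("# method=%s h=%d r1=%d r2=%d lag=%d stride=%d%s",
                 fit$method, fit$config$h, fit$config$r1, fit$config$r2,
                 fit$config$lag, fit$config$stride,
                 if (length(fit$params))
                   paste0(" ", paste(names(fit$params), unlist(fit$params),
                                     sep = "=", collapse = " "))
                 else "")
  sc <- ifelse(is.finite(fit$scores),
               formatC(fit$scores, format = "g", digits = 15), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "t,score", paste(seq_len(fit$N), sc, sep = ",")), con)
  invisible(path)
}

#' Read a change-score file written by [write_scores()]
#'
#' @param path Path to the file.
#' @return A list with `t`, `scores` (NA where undefined) and the header
#'   line.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("score file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], header = TRUE)
  list(t = as.integer(df$t), scores = as.numeric(df$score),
       header = if (length(hdr)) hdr[1] else "")
}
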