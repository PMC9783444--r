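#' Remove extreme outliers per FD measure
#'
#' Screens each FD column independently: values outside
#' `[Q1 - mult * IQR, Q3 + mult * IQR]` (default `mult = 3`, the extreme-
#' outlier rule) are set to missing. Only the offending data points are
#' dropped; the subject's other measures are kept. Quartiles use the
#' linear-interpolation quantile definition (R type 7).
#'
#' @param table Subject FD table (data frame with `fd_*` columns; an `id`
#'   column is used for the log when present).
#' @param multiplier IQR multiplier; 3 flags extreme outliers, 1.5 ordinary.
#' @return List with `table` (filtered copy) and `log` (data frame
#'   `subject`, `measure`, `value`, one row per removed point).
#' @export
#' @examples
#' t <- data.frame(id = 1:11, fd_lh = c(1:10 / 10 + 2, 1000))
#' remove_extreme_outliers(t)$log
remove_extreme_outliers <- function(table, multiplier = 3) {
  if (nrow(table) == 0L) cfd_stop("table is empty", "argument_error")
  ids <- if ("id" %in% names(table)) table$id else seq_len(nrow(table))
  logs <- list()
  for (col in intersect(FD_COLUMNS, names(table))) {
    x <- table[[col]]
    ok <- !is.na(x)
    if (sum(ok) < 4L) next
    q <- quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out <- ok & (x < q[1] - multiplier * iqr | x > q[2] + multiplier * iqr)
    if (any(out)) {
      logs[[col]] <- data.frame(subject = ids[out], measure = col,
                                value = x[out])
      table[[col]][out] <- NA_real_
    }
  }
  log <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
         else data.frame(subject = ids[0], measure = character(0),
                         value = numeric(0))
  list(table = table, log = log)
}
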