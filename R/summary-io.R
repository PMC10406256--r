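#' Build a regional summary table
#'
#' @param df data.frame with columns `subject`, `region`, `class`,
#'   `measure`, `average`, `heterogeneity`, `n`
#' @return a validated [RegionalSummary-class]
#' @export
regionalSummary <- function(df) {
  df <- as.data.frame(df)
  need <- c("subject", "region", "class", "measure", "average",
            "heterogeneity", "n")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("summary table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[, need]
  df$subject <- as.character(df$subject)
  df$region <- as.character(df$region)
  df$class <- as.character(df$class)
  df$measure <- as.character(df$measure)
  df$n <- as.integer(df$n)
  new("RegionalSummary", df)
}

#' Write a regional summary table as CSV
#'
#' UTF-8, '.' decimal separator, header row. `readSummaryTable()` of the
#' written file round-trips the table.
#'
#' @param table a [RegionalSummary-class]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeSummaryTable <- function(table, path) {
  if (!is(table, "RegionalSummary")) table <- regionalSummary(table)
  df <- asS4(as(table, "data.frame"), FALSE)  # plain data.frame for write.csv
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a regional summary table from CSV
#'
#' @param path CSV written by [writeSummaryTable()]
#' @return a validated [RegionalSummary-class]
#' @export
readSummaryTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  regionalSummary(df)
}
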