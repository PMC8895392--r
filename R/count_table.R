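#' Construct a validated count table
#'
#' A count table holds, for one disease entity, the observed case count
#' \eqn{C_i} and the expected case count \eqn{E_i} for each of \eqn{I}
#' registry areas.  Expected counts come from internal or external
#' age/sex standardization and are treated as fixed offsets; the model's
#' relative risk for area \eqn{i} is \eqn{R_i = E(C_i)/E_i}.
#'
#' @param area_ids character vector of area labels (length \eqn{I \ge 2}).
#' @param observed non-negative integer case counts \eqn{C_i}.
#' @param expected positive expected case counts \eqn{E_i}.
#' @param entity_id single text label for the disease entity.
#'
#' @return An object of class `count_table`: a data frame with columns
#'   `area`, `observed`, `expected` and attribute `entity_id`.  Row order
#'   is preserved through all downstream operations.
#' @export
#' @examples
#' count_table(c("A", "B"), observed = c(3, 0), expected = c(2.5, 1.2))
count_table <- function(area_ids, observed, expected, entity_id = "entity") {
  area_ids <- as.character(area_ids)
  if (length(area_ids) < 2L)
    stop("a count table needs at least 2 areas, got ", length(area_ids))
  if (length(observed) != length(area_ids) || length(expected) != length(area_ids))
    stop("area_ids, observed and expected must have equal length")
  if (anyNA(observed) || anyNA(expected) || anyNA(area_ids))
    stop("count table fields must not contain NA")
  bad <- which(observed < 0 | observed != round(observed))
  if (length(bad))
    stop("observed counts must be non-negative integers; offending row(s): ",
         paste(area_ids[bad], collapse = ", "))
  bad <- which(!(expected > 0))
  if (length(bad))
    stop("expected counts must be > 0; offending row(s): ",
         paste(area_ids[bad], collapse = ", "))
  out <- data.frame(area = area_ids,
                    observed = as.integer(round(observed)),
                    expected = as.numeric(expected),
                    stringsAsFactors = FALSE)
  attr(out, "entity_id") <- as.character(entity_id)[1L]
  class(out) <- c("count_table", "data.frame")
  out
}

#' @exportS3Method base::print
print.count_table <- function(x, ...) {
  cat("Count table for entity '", attr(x, "entity_id"), "': ",
      nrow(x), " areas, ", sum(x$observed), " cases total\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a count table from CSV
#'
#' Expects a header `area,observed,expected`.  Extra columns are ignored;
#' row order is preserved.
#'
#' @param path path to a CSV file.
#' @param entity_id entity label attached to the result; defaults to the
#'   file name without extension.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, entity_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "observed", "expected")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("count table CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(entity_id))
    entity_id <- sub("\\.[^.]*$", "", basename(path))
  count_table(df$area, df$observed, df$expected, entity_id = entity_id)
}

#' Write a result table to CSV or JSON
#'
#' CSV numeric fields are written at 15 significant digits so that a
#' read-back reproduces the table to floating-point precision.
#'
#' @param results a non-empty data frame (CSV) or list/data frame (JSON).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (length(results) == 0L || (is.data.frame(results) && nrow(results) == 0L))
    stop("refusing to write an empty result table")
  if (format == "csv") {
    if (!is.data.frame(results)) stop("CSV output requires a data frame")
    df <- results
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a count table to CSV
#'
#' @param table a [count_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(area = table$area,
                   observed = table$observed,
                   expected = sprintf("%.15g", table$expected))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
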