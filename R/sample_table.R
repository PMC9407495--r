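#' Construct and validate a sample table
#'
#' A sample table is the pipeline's universal currency: one row per peel
#' provenance, with an identifier, an optional geographic group, optional
#' altitude/longitude/latitude, flavonoid contents (mg/g) under the catalog
#' codes of [analyte_catalog()], optional per-analyte standard deviations in
#' \code{<code>_sd} columns, an optional CIELAB color triple in columns
#' \code{L}, \code{a}, \code{b}, and optional annual climate factors under
#' the codes of [climate_catalog()].
#'
#' @param df A data.frame holding at least \code{sample_id} and one analyte
#'   column.
#' @return The validated data.frame with class \code{"sample_table"}.
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("schema error: mandatory column 'sample_id' is missing")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("validation error: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  an <- intersect(analyte_catalog()$code, names(df))
  if (nrow(df) > 0 && length(an) == 0)
    stop("schema error: no flavonoid analyte column present")
  num_cols <- intersect(
    c(an, paste0(an, "_sd"), geo_columns(), color_axes(), climate_catalog()$code),
    names(df))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]]))
      stop("parse error: column '", cl, "' is not numeric")
    bad <- which(!is.na(df[[cl]]) & !is.finite(df[[cl]]))
    if (length(bad))
      stop("validation error: non-finite value in column '", cl,
           "', row ", bad[1])
  }
  for (cl in c(an, paste0(an, "_sd"))) {
    if (cl %in% names(df) && any(df[[cl]] < 0, na.rm = TRUE))
      stop("validation error: negative content/SD in column '", cl, "'")
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' @export
print.sample_table <- function(x, ...) {
  an <- intersect(analyte_catalog()$code, names(x))
  cl <- intersect(climate_catalog()$code, names(x))
  cat("Sample table: ", nrow(x), " samples, ", length(an), " analytes, ",
      length(cl), " climate factors",
      if (all(color_axes() %in% names(x))) ", CIELAB color" else "",
      "\n", sep = "")
  print(as.data.frame(utils::head(x, 6)), ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# tokens treated as missing on read (case-insensitive)
.missing_tokens <- c("", "na", "nan")

parse_numeric_column <- function(vals, col) {
  raw <- trimws(as.character(vals))
  miss <- is.na(raw) | tolower(raw) %in% .missing_tokens
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!miss & is.na(out))
  if (length(bad))
    stop("parse error: non-numeric cell at row ", bad[1], ", column '", col,
         "': \"", raw[bad[1]], "\"")
  out[miss] <- NA_real_
  out
}

#' Read a sample table from CSV or TSV
#'
#' The delimiter is taken from the extension (\code{.tsv}/\code{.tab} means
#' tab) or sniffed from the header line. Empty cells, \code{NA} and
#' \code{NaN} (any case) are missing. An optional \code{schema} mapping
#' renames arbitrary source headers to canonical codes.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector, canonical code ->
#'   source header, e.g. \code{c(sample_id = "Provenance")}.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE) ||
             (grepl("\t", header) && !grepl(",", header))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema error: mapped column '", src, "' not found in ", path)
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"sample_id" %in% names(raw))
    stop("schema error: mandatory column 'sample_id' is missing")
  an <- analyte_catalog()$code
  numeric_cols <- intersect(
    c(an, paste0(an, "_sd"), geo_columns(), color_axes(), climate_catalog()$code),
    names(raw))
  for (cl in numeric_cols) raw[[cl]] <- parse_numeric_column(raw[[cl]], cl)
  sample_table(raw)
}

#' Write a sample table to CSV or TSV
#'
#' Numeric values are written with 15 significant digits so that a
#' read/write round trip reproduces them to at least 12 significant digits.
#' Optional columns that are absent from the table are simply not written.
#'
#' @param table A [sample_table()].
#' @param path Output path; a \code{.tsv} extension selects tab delimiting.
#' @return \code{path}, invisibly.
#' @export
write_sample_table <- function(table, path) {
  table <- sample_table(table)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- as.data.frame(table)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      v <- format(out[[cl]], digits = 15, trim = TRUE, scientific = FALSE)
      v[is.na(out[[cl]])] <- "NA"
      out[[cl]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Load the bundled 26-provenance flavonoid quantification fixture
#'
#' Twenty-six peel provenances (A1--A6, B1--B5, C1--C7, D1--D3, E1--E5) with
#' the mean and standard deviation of each of the 15 analytes (mg/g, n = 3
#' analytical replicates). The \code{<code>_note} columns carry the source
#' table's homogeneous-group letters; they are annotation only and are never
#' used computationally.
#'
#' @return A [sample_table()] with 26 rows.
#' @export
#' @examples
#' tab <- load_table1_fixture()
#' summarize_ranges(tab, "Y_QI")
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_flavonoids.csv", package = "peelpath",
                      mustWork = TRUE)
  read_sample_table(path)
}

#' Report presence and missingness of required variables
#'
#' @param table A [sample_table()].
#' @param required Character vector of variable codes to check.
#' @return A data.frame with columns \code{variable}, \code{present}
#'   (logical) and \code{n_missing} (missing cells among rows; \code{NA}
#'   when the column is absent).
#' @export
validate_schema <- function(table, required) {
  table <- sample_table(table)
  data.frame(
    variable = required,
    present = required %in% names(table),
    n_missing = vapply(required, function(v) {
      if (!v %in% names(table)) return(NA_integer_)
      sum(is.na(table[[v]]))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-variable minimum, maximum and mean over samples
#'
#' Ranges are computed over the per-sample means (not the analytical-replicate
#' SDs); the reported argmin/argmax take the first occurrence on ties.
#'
#' @param table A [sample_table()].
#' @param variables Variable codes present in the table.
#' @return A data.frame with columns \code{variable}, \code{min}, \code{max},
#'   \code{mean}, \code{which_min}, \code{which_max}.
#' @export
summarize_ranges <- function(table, variables) {
  table <- sample_table(table)
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop("lookup error: unknown variable code(s): ",
         paste(missing_vars, collapse = ", "))
  do.call(rbind, lapply(variables, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    data.frame(variable = v,
               min = min(x[ok]), max = max(x[ok]), mean = mean(x[ok]),
               which_min = table$sample_id[ok][which.min(x[ok])],
               which_max = table$sample_id[ok][which.max(x[ok])],
               stringsAsFactors = FALSE)
  }))
}
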