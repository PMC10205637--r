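# Delimited-table I/O. Files are UTF-8 text with a header row; comma is the
# default separator with tab selectable. Absent identifiers are empty cells
# on disk and NA in memory, so writers and readers round-trip exactly.

.read_table <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 na.strings = character(), check.names = FALSE,
                 fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

.write_table <- function(df, path, sep = ",") {
  for (col in names(df)) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- ""
    df[[col]] <- x
  }
  tryCatch(
    write.table(df, path, sep = sep, row.names = FALSE, col.names = TRUE,
                quote = FALSE, fileEncoding = "UTF-8", eol = "\n"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  invisible(path)
}

#' Read a claims table from a delimited file
#'
#' @param path path to a file with header
#'   `claim_id,service_month,id1,id2`
#' @param sep field separator (`","` default, `"\t"` selectable)
#' @return a validated claims `data.frame`, rows in file order
#' @seealso [write_claims()], [validate_claims()]
#' @export
read_claims <- function(path, sep = ",") {
  df <- .read_table(path, c("claim_id", "service_month", "id1", "id2"), sep)
  validate_claims(df)
}

#' Write a claims table to a delimited file
#'
#' Absent identifiers become empty cells, never a literal sentinel string;
#' [read_claims()] on the result reproduces the input field for field.
#'
#' @param claims validated claims table
#' @param path output path
#' @param sep field separator
#' @return the path, invisibly
#' @export
write_claims <- function(claims, path, sep = ",") {
  claims <- validate_claims(claims)
  .write_table(claims, path, sep)
}

#' Read an enrollment-history table
#' @param path path to a file with header
#'   `citizen_number,id1,id2,start_month,end_month`
#' @param sep field separator
#' @return a validated enrollment `data.frame`
#' @export
read_enrollment <- function(path, sep = ",") {
  df <- .read_table(path, c("citizen_number", "id1", "id2", "start_month",
                            "end_month"), sep)
  validate_enrollment(df)
}

#' Write an enrollment-history table
#' @param enrollment validated enrollment table
#' @param path output path
#' @param sep field separator
#' @return the path, invisibly
#' @export
write_enrollment <- function(enrollment, path, sep = ",") {
  enrollment <- validate_enrollment(enrollment)
  .write_table(enrollment, path, sep)
}

#' Read a ground-truth file (`claim_id,citizen_number`)
#'
#' Rows with an empty `citizen_number` cell are the unresolved claims.
#'
#' @param path path to the truth file
#' @param sep field separator
#' @return a `vpid_truth` object
#' @export
read_truth <- function(path, sep = ",") {
  df <- .read_table(path, c("claim_id", "citizen_number"), sep)
  resolved <- df$citizen_number != ""
  ground_truth(df[resolved, , drop = FALSE],
               unresolved = df$claim_id[!resolved])
}

#' Write a ground-truth file
#' @param truth a `vpid_truth` object
#' @param path output path
#' @param sep field separator
#' @return the path, invisibly
#' @export
write_truth <- function(truth, path, sep = ",") {
  stopifnot(inherits(truth, "vpid_truth"))
  df <- truth$mapping
  if (length(truth$unresolved)) {
    df <- rbind(df, data.frame(claim_id = truth$unresolved,
                               citizen_number = NA_character_,
                               stringsAsFactors = FALSE))
  }
  .write_table(df, path, sep)
}

#' Read a vPID assignment map (`claim_id,vpid`)
#' @param path path to the map file
#' @param sep field separator
#' @return data.frame with columns `claim_id`, `vpid`
#' @export
read_vpid_map <- function(path, sep = ",") {
  .read_table(path, c("claim_id", "vpid"), sep)
}
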