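# Claims and enrollment tables are plain data.frames with character columns;
# an absent identifier is NA_character_ in memory and an empty cell on disk.
# Identifier values are opaque case-sensitive byte strings; ":" and "|" are
# reserved by the vPID rendering and rejected at validation.

MONTH_RE <- "^[0-9]{4}-(0[1-9]|1[0-2])$"

#' Convert `YYYY-MM` strings to a monotone integer month index
#' @param x character vector of `YYYY-MM` months
#' @return integer vector (year * 12 + month)
#' @keywords internal
month_index <- function(x) {
  as.integer(substr(x, 1L, 4L)) * 12L + as.integer(substr(x, 6L, 7L))
}

#' Render a month index back to `YYYY-MM`
#' @param i integer month index as produced by [month_index()]
#' @keywords internal
month_label <- function(i) {
  y <- (i - 1L) %/% 12L
  m <- i - y * 12L
  sprintf("%04d-%02d", y, m)
}

.check_id_values <- function(x, what) {
  bad <- !is.na(x) & grepl("[:|]", x)
  if (any(bad)) {
    stop(sprintf("%s contains reserved characters ':' or '|' (first offender: '%s')",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  .check_token(x, what)
}

# tokens travel unquoted through delimited files
.check_token <- function(x, what) {
  bad <- !is.na(x) & grepl("[,\t\r\n\"]", x)
  if (any(bad)) {
    stop(sprintf("%s contains a separator or quote character at position %d",
                 what, which(bad)[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Construct and validate a claims table
#'
#' A claim carries an opaque unique `claim_id`, a `service_month`
#' (`YYYY-MM`; Japanese claims are monthly statements, so no day is
#' modeled), and the two anonymized identifiers `id1` and `id2`, either of
#' which may be absent (`NA`).  Claims lacking both identifiers are legal:
#' they cannot participate in consolidation but are retained so that claim
#' counts are conserved end to end.
#'
#' @param claim_id character vector of unique claim tokens
#' @param service_month character vector of `YYYY-MM` months
#' @param id1,id2 character vectors of identifier values (`NA` = absent;
#'   empty strings are normalized to `NA`, never used as linkable values)
#' @return a validated `data.frame` with the four columns
#' @examples
#' claims_table(c("c1", "c2"), c("2013-04", "2013-05"),
#'              id1 = c("A", "B"), id2 = c("X", "X"))
#' @export
claims_table <- function(claim_id, service_month, id1 = NA_character_,
                         id2 = NA_character_) {
  df <- data.frame(claim_id = as.character(claim_id),
                   service_month = as.character(service_month),
                   id1 = .blank_to_na(rep_len(id1, length(claim_id))),
                   id2 = .blank_to_na(rep_len(id2, length(claim_id))),
                   stringsAsFactors = FALSE)
  validate_claims(df)
}

#' Validate a claims table
#'
#' Checks the claim invariants: unique `claim_id`, parseable
#' `service_month`, no reserved characters in identifier values.  Empty
#' identifier cells are normalized to `NA`.
#'
#' @param claims a data.frame with columns `claim_id`, `service_month`,
#'   `id1`, `id2`
#' @return the normalized claims data.frame (invisibly usable in pipelines)
#' @export
validate_claims <- function(claims) {
  required <- c("claim_id", "service_month", "id1", "id2")
  missing_cols <- setdiff(required, names(claims))
  if (length(missing_cols)) {
    stop("claims table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  claims <- claims[required]
  claims$claim_id <- as.character(claims$claim_id)
  claims$service_month <- as.character(claims$service_month)
  claims$id1 <- .blank_to_na(claims$id1)
  claims$id2 <- .blank_to_na(claims$id2)
  if (anyNA(claims$claim_id) || any(claims$claim_id == "")) {
    stop("claim_id must be present for every row", call. = FALSE)
  }
  dup <- duplicated(claims$claim_id)
  if (any(dup)) {
    stop(sprintf("duplicate claim_id '%s'", claims$claim_id[which(dup)[1L]]),
         call. = FALSE)
  }
  .check_token(claims$claim_id, "claim_id")
  badm <- !grepl(MONTH_RE, claims$service_month)
  if (any(badm)) {
    stop(sprintf("service_month not in YYYY-MM form at row %d ('%s')",
                 which(badm)[1L], claims$service_month[which(badm)[1L]]),
         call. = FALSE)
  }
  .check_id_values(claims$id1, "id1")
  .check_id_values(claims$id2, "id2")
  rownames(claims) <- NULL
  claims
}

#' Construct and validate an enrollment-history table
#'
#' One row per enrollment era: an anonymized unique `citizen_number` bound
#' to an (`id1`, `id2`) value pair over a validity period
#' `[start_month, end_month]` (inclusive, `YYYY-MM`).  Enrollment records
#' are the ground-truth source: the citizen number is the reliable
#' identifier the anonymized ones are evaluated against.
#'
#' @param citizen_number,id1,id2 character vectors
#' @param start_month,end_month character vectors of `YYYY-MM` months
#' @return a validated `data.frame` with the five columns
#' @export
enrollment_table <- function(citizen_number, id1, id2, start_month, end_month) {
  df <- data.frame(citizen_number = as.character(citizen_number),
                   id1 = .blank_to_na(id1),
                   id2 = .blank_to_na(id2),
                   start_month = as.character(start_month),
                   end_month = as.character(end_month),
                   stringsAsFactors = FALSE)
  validate_enrollment(df)
}

#' Validate an enrollment-history table
#' @param enrollment a data.frame with columns `citizen_number`, `id1`,
#'   `id2`, `start_month`, `end_month`
#' @return the normalized enrollment data.frame
#' @export
validate_enrollment <- function(enrollment) {
  required <- c("citizen_number", "id1", "id2", "start_month", "end_month")
  missing_cols <- setdiff(required, names(enrollment))
  if (length(missing_cols)) {
    stop("enrollment table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  enrollment <- enrollment[required]
  for (col in required) enrollment[[col]] <- as.character(enrollment[[col]])
  enrollment$id1 <- .blank_to_na(enrollment$id1)
  enrollment$id2 <- .blank_to_na(enrollment$id2)
  for (col in c("start_month", "end_month")) {
    badm <- !grepl(MONTH_RE, enrollment[[col]])
    if (any(badm)) {
      stop(sprintf("%s not in YYYY-MM form at row %d", col, which(badm)[1L]),
           call. = FALSE)
    }
  }
  rev <- month_index(enrollment$start_month) > month_index(enrollment$end_month)
  if (any(rev)) {
    stop(sprintf("enrollment row %d has start_month after end_month",
                 which(rev)[1L]), call. = FALSE)
  }
  .check_token(enrollment$citizen_number, "citizen_number")
  key <- paste(enrollment$citizen_number, enrollment$id1, enrollment$id2,
               enrollment$start_month, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate enrollment era at row %d", which(dup)[1L]),
         call. = FALSE)
  }
  .check_id_values(enrollment$id1, "id1")
  .check_id_values(enrollment$id2, "id2")
  rownames(enrollment) <- NULL
  enrollment
}

#' Construct a ground-truth object
#'
#' Partitions the claim universe into claims with a uniquely resolved
#' citizen (`mapping`) and claims with no unique match (`unresolved`).
#' Every claim id appears in exactly one of the two.
#'
#' @param mapping data.frame with columns `claim_id`, `citizen_number`
#' @param unresolved character vector of claim ids with no unique citizen
#' @return an object of class `vpid_truth`
#' @export
ground_truth <- function(mapping, unresolved = character()) {
  mapping <- data.frame(claim_id = as.character(mapping$claim_id),
                        citizen_number = as.character(mapping$citizen_number),
                        stringsAsFactors = FALSE)
  unresolved <- as.character(unresolved)
  if (anyDuplicated(mapping$claim_id)) {
    stop("ground truth maps a claim_id more than once", call. = FALSE)
  }
  if (length(intersect(mapping$claim_id, unresolved))) {
    stop("a claim_id cannot be both mapped and unresolved", call. = FALSE)
  }
  structure(list(mapping = mapping, unresolved = unresolved),
            class = "vpid_truth")
}

#' @export
print.vpid_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d claims mapped to %d citizens, %d unresolved\n",
              nrow(x$mapping), length(unique(x$mapping$citizen_number)),
              length(x$unresolved)))
  invisible(x)
}

#' Resolve ground truth by joining claims to enrollment history
#'
#' A claim maps to citizen `u` iff exactly one citizen has an enrollment
#' era whose validity period contains the claim's service month and whose
#' `id1` equals the claim's `id1` or whose `id2` equals the claim's `id2`
#' (kind-respecting OR match).  Matching on either identifier tolerates a
#' clerical error in the other; requiring a unique citizen keeps ambiguous
#' claims out of the truth instead of guessing.  Claims matching zero or
#' several citizens are reported as unresolved — ambiguity is data, not an
#' error.
#'
#' @param claims validated claims table (see [validate_claims()])
#' @param enrollment validated enrollment table
#' @return a `vpid_truth` object (see [ground_truth()])
#' @examples
#' cl <- claims_table("c1", "2013-06", "A", "X")
#' en <- enrollment_table("u1", "A", "X", "2013-04", "2014-03")
#' resolve_ground_truth(cl, en)
#' @export
resolve_ground_truth <- function(claims, enrollment) {
  claims <- validate_claims(claims)
  enrollment <- validate_enrollment(enrollment)
  n <- nrow(claims)
  if (n == 0L) return(ground_truth(
    data.frame(claim_id = character(), citizen_number = character())))
  cmonth <- month_index(claims$service_month)
  es <- month_index(enrollment$start_month)
  ee <- month_index(enrollment$end_month)

  match_on <- function(cl_val, er_val) {
    ci <- which(!is.na(cl_val))
    ei <- which(!is.na(er_val))
    if (!length(ci) || !length(ei)) {
      return(data.frame(claim = integer(), era = integer()))
    }
    p <- merge(data.frame(val = cl_val[ci], claim = ci),
               data.frame(val = er_val[ei], era = ei),
               by = "val")
    keep <- cmonth[p$claim] >= es[p$era] & cmonth[p$claim] <= ee[p$era]
    p[keep, c("claim", "era")]
  }
  pairs <- rbind(match_on(claims$id1, enrollment$id1),
                 match_on(claims$id2, enrollment$id2))
  pairs$citizen <- enrollment$citizen_number[pairs$era]
  pairs <- unique(pairs[c("claim", "citizen")])

  ncit <- tabulate(pairs$claim, nbins = n)
  uniq <- ncit == 1L
  mapping <- data.frame(
    claim_id = claims$claim_id[pairs$claim[uniq[pairs$claim]]],
    citizen_number = pairs$citizen[uniq[pairs$claim]],
    stringsAsFactors = FALSE)
  ord <- match(mapping$claim_id, claims$claim_id)
  mapping <- mapping[order(ord), , drop = FALSE]
  ground_truth(mapping, unresolved = claims$claim_id[!uniq])
}
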