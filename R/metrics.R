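# Patient-level, all-or-nothing accuracy scores for claim identifiers.
# A citizen is traceable under an identifier iff ALL of its scored claims
# carry one single value (all claims collectible under one value), and
# identifiable iff NONE of its values is shared with another citizen.
# Both scores are deliberately stricter than record-level precision/recall.

#' Attach ground-truth citizens and an identifier labeling to claims
#'
#' Restricts scoring to claims that (a) possess the evaluated identifier
#' and (b) resolve to a citizen in the ground truth; excluded counts are
#' kept on the object.  The label may be an ID1 value, an ID2 value, a
#' vPID value, or any other claim-level labeling to be evaluated.
#'
#' @param claims validated claims table
#' @param truth a `vpid_truth` object covering these claims
#' @param label character vector aligned with `claims` rows: the value of
#'   the evaluated identifier per claim (`NA` where the claim lacks it)
#' @param name display name of the identifier being evaluated
#' @return an object of class `labeled_claims`
#' @export
label_claims <- function(claims, truth, label, name = "identifier") {
  claims <- validate_claims(claims)
  stopifnot(inherits(truth, "vpid_truth"))
  if (length(label) != nrow(claims)) {
    stop("label must have one entry per claim", call. = FALSE)
  }
  citizen <- truth$mapping$citizen_number[match(claims$claim_id,
                                                truth$mapping$claim_id)]
  unknown <- is.na(citizen) &
    !(claims$claim_id %in% truth$unresolved)
  if (any(unknown)) {
    stop(sprintf("ground truth does not cover claim '%s'",
                 claims$claim_id[which(unknown)[1L]]), call. = FALSE)
  }
  scored <- !is.na(citizen) & !is.na(label)
  structure(list(name = name,
                 citizen = citizen[scored],
                 label = as.character(label)[scored],
                 n_excluded_unresolved = sum(is.na(citizen)),
                 n_excluded_unlabeled = sum(!is.na(citizen) & is.na(label))),
            class = "labeled_claims")
}

#' @export
print.labeled_claims <- function(x, ...) {
  cat(sprintf(
    "Labeled claims (%s): %d scored, %d unresolved, %d without the identifier\n",
    x$name, length(x$label), x$n_excluded_unresolved, x$n_excluded_unlabeled))
  invisible(x)
}

.dedup_pairs <- function(lc) {
  keep <- !duplicated(paste(lc$citizen, lc$label, sep = "\r"))
  list(citizen = lc$citizen[keep], label = lc$label[keep])
}

.require_citizens <- function(lc) {
  if (!length(lc$citizen)) {
    stop("score undefined: no resolvable citizens among scored claims",
         call. = FALSE)
  }
}

#' Identifier values observed per citizen
#' @param lc a `labeled_claims` object
#' @return named list: citizen number -> character vector of distinct
#'   label values over that citizen's scored claims
#' @export
values_per_citizen <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  p <- .dedup_pairs(lc)
  split(p$label, p$citizen)
}

#' Citizens observed per identifier value
#' @param lc a `labeled_claims` object
#' @return named list: label value -> character vector of distinct
#'   citizens whose scored claims carry it
#' @export
citizens_per_value <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  p <- .dedup_pairs(lc)
  split(p$citizen, p$label)
}

#' Traceability score of an identifier
#'
#' Fraction of citizens all of whose scored claims carry one single
#' identifier value — the identifier collects every claim of such a
#' citizen.  A citizen given two or more values (after a life event or
#' clerical error) is untraceable under this all-or-nothing definition.
#'
#' @param lc a `labeled_claims` object
#' @return a fraction in \[0, 1\]
#' @export
traceability_score <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  .require_citizens(lc)
  nval <- vapply(split(lc$label, lc$citizen),
                 function(v) length(unique(v)), integer(1))
  1 - sum(nval > 1L) / length(nval)
}

#' Identifiability score of an identifier
#'
#' Fraction of citizens none of whose identifier values is shared with any
#' other citizen — the identifier cleanly separates such a citizen's
#' claims from everyone else's.  A value shared across citizens (twins
#' sharing an ID1, a garbage sentinel) makes every involved citizen
#' unidentifiable.
#'
#' @param lc a `labeled_claims` object
#' @return a fraction in \[0, 1\]
#' @export
identifiability_score <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  .require_citizens(lc)
  p <- .dedup_pairs(lc)
  cit_per_val <- table(p$label)
  shared <- names(cit_per_val)[cit_per_val >= 2L]
  n_bad <- length(unique(p$citizen[p$label %in% shared]))
  1 - n_bad / length(unique(p$citizen))
}

#' Cardinality of an identifier
#' @param lc a `labeled_claims` object
#' @return count of distinct label values among scored claims
#' @export
cardinality <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  length(unique(lc$label))
}

#' Full score report for one identifier
#'
#' Computes the complete per-identifier evaluation: cardinality,
#' identifiability, traceability, average number of identifier values per
#' citizen, and the supporting counts.  `traceability` and
#' `n_multi_value_citizens` are computed by independent code paths; the
#' identity `traceability == 1 - n_multi_value_citizens / n_citizens`
#' holds exactly and is exercised by the test suite.
#'
#' @param lc a `labeled_claims` object
#' @return an object of class `score_report` (a named list)
#' @export
score_report <- function(lc) {
  stopifnot(inherits(lc, "labeled_claims"))
  .require_citizens(lc)
  p <- .dedup_pairs(lc)
  n_citizens <- length(unique(p$citizen))
  # independent path for the multi-value count: tabulate deduped pairs
  per_cit <- table(p$citizen)
  n_multi <- sum(per_cit >= 2L)
  cit_per_val <- table(p$label)
  structure(list(
    identifier_name = lc$name,
    n_citizens = n_citizens,
    n_claims_scored = length(lc$label),
    n_excluded_unresolved = lc$n_excluded_unresolved,
    n_excluded_unlabeled = lc$n_excluded_unlabeled,
    cardinality = cardinality(lc),
    identifiability = identifiability_score(lc),
    traceability = traceability_score(lc),
    avg_instances_per_citizen = length(p$label) / n_citizens,
    n_multi_value_citizens = n_multi,
    n_shared_values = sum(cit_per_val >= 2L)),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Score report: %s\n", x$identifier_name))
  cat(sprintf("  citizens scored:       %d (claims: %d)\n",
              x$n_citizens, x$n_claims_scored))
  cat(sprintf("  cardinality:           %d\n", x$cardinality))
  cat(sprintf("  identifiability:       %.3f\n", x$identifiability))
  cat(sprintf("  traceability:          %.3f\n", x$traceability))
  cat(sprintf("  avg instances/citizen: %.3f\n", x$avg_instances_per_citizen))
  invisible(x)
}

#' Evaluate ID1, ID2 and vPID against ground truth
#'
#' Runs the full comparative evaluation over one claim set: each of the
#' three identifiers is scored on the same claims (restricted, per
#' identifier, to claims that carry it and resolve to a citizen).  The
#' printed form is a three-column grid of instance counts,
#' identifiability, traceability and average instances per citizen.
#'
#' @param claims claims table
#' @param truth a `vpid_truth` object; if `NULL`, resolved internally from
#'   `enrollment` via [resolve_ground_truth()]
#' @param fit a `vpid` object for these claims; fitted on the fly if `NULL`
#' @param enrollment enrollment table, used when `truth` is `NULL`
#' @return an object of class `vpid_eval`: list of `score_report`s keyed
#'   `ID1`, `ID2`, `vPID`
#' @examples
#' cl <- claims_table(c("c1", "c2", "c3", "c4"), rep("2013-05", 4),
#'                    id1 = c("A", "B", "B", "C"),
#'                    id2 = c("X", "X", "Y", "Z"))
#' tr <- ground_truth(data.frame(claim_id = c("c1", "c2", "c3", "c4"),
#'                               citizen_number = c("u1", "u1", "u1", "u2")))
#' evaluate_identifiers(cl, tr)
#' @export
evaluate_identifiers <- function(claims, truth = NULL, fit = NULL,
                                 enrollment = NULL) {
  claims <- validate_claims(claims)
  if (is.null(truth)) {
    if (is.null(enrollment)) {
      stop("either truth or enrollment must be supplied", call. = FALSE)
    }
    truth <- resolve_ground_truth(claims, enrollment)
  }
  if (is.null(fit)) fit <- vpid(claims)
  vp <- fit$assignment$vpid[match(claims$claim_id, fit$assignment$claim_id)]
  if (anyNA(vp)) stop("vpid fit does not cover all claims", call. = FALSE)
  reports <- list(
    ID1 = score_report(label_claims(claims, truth, claims$id1, "ID1")),
    ID2 = score_report(label_claims(claims, truth, claims$id2, "ID2")),
    vPID = score_report(label_claims(claims, truth, vp, "vPID")))
  structure(list(reports = reports), class = "vpid_eval")
}

#' @export
print.vpid_eval <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  grid <- rbind(
    `Number of instances` = sprintf("%d", df$cardinality),
    `Identifiability score` = sprintf("%.*f", digits, df$identifiability),
    `Traceability score` = sprintf("%.*f", digits, df$traceability),
    `Average instances per citizen` =
      sprintf("%.*f", digits, df$avg_instances_per_citizen))
  colnames(grid) <- df$identifier_name
  cat(sprintf("Identifier evaluation (%d citizens)\n",
              x$reports$vPID$n_citizens))
  print(grid, quote = FALSE, right = TRUE)
  invisible(x)
}

#' @export
as.data.frame.vpid_eval <- function(x, ...) {
  rows <- lapply(x$reports, function(r) as.data.frame(unclass(r)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
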