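# vPID consolidation: identifier values that co-occur in an identical claim
# are merged transitively. Nodes of the co-occurrence graph are (kind,
# value) pairs rendered "1:<value>" / "2:<value>", so an ID1 value and an
# ID2 value with equal bytes remain distinct nodes. Connected components
# are computed with a disjoint-set forest (path compression + union by
# size), giving near-linear behavior in the number of claims. All string
# orderings use radix sort for locale-independent, seed-free determinism.

.node_keys <- function(kind, value) paste0(ifelse(kind == "ID1", "1", "2"),
                                           ":", value)

#' Build the identifier co-occurrence graph from claims
#'
#' One edge per claim carrying both identifiers; a claim with exactly one
#' identifier contributes an isolated node.  Duplicate edges are allowed
#' (deduplicated by the disjoint-set forest).  Claims with neither
#' identifier cannot participate and are returned in the skip log.
#'
#' @param claims validated claims table
#' @return a list of class `vpid_graph` with elements `nodes` (all node
#'   keys, lexicographically sorted), `from`/`to` (integer node indices,
#'   one edge per two-identifier claim) and `skipped` (claim ids with
#'   neither identifier)
#' @export
build_edges <- function(claims) {
  claims <- validate_claims(claims)
  k1 <- ifelse(is.na(claims$id1), NA_character_, paste0("1:", claims$id1))
  k2 <- ifelse(is.na(claims$id2), NA_character_, paste0("2:", claims$id2))
  nodes <- sort(unique(c(k1[!is.na(k1)], k2[!is.na(k2)])), method = "radix")
  i1 <- match(k1, nodes)
  i2 <- match(k2, nodes)
  both <- !is.na(i1) & !is.na(i2)
  structure(list(nodes = nodes,
                 from = i1[both], to = i2[both],
                 claim_node = ifelse(is.na(i1), i2, i1),
                 skipped = claims$claim_id[is.na(i1) & is.na(i2)]),
            class = "vpid_graph")
}

#' Partition identifier nodes into connected components
#'
#' Computes the connected components of the co-occurrence graph with a
#' disjoint-set forest.  Component labels are deterministic: each
#' component is labeled by its lexicographically smallest member
#' rendering, so the partition is invariant to claim order.
#'
#' @param graph a `vpid_graph` from [build_edges()]
#' @return an object of class `vpid_partition`: list with `nodes`
#'   (character node keys) and `label` (character component label per
#'   node)
#' @export
consolidate <- function(graph) {
  stopifnot(inherits(graph, "vpid_graph"))
  n <- length(graph$nodes)
  comp <- if (n) .uf_components(graph$from, graph$to, n) else integer()
  structure(list(nodes = graph$nodes,
                 label = graph$nodes[comp],
                 comp_index = comp),
            class = "vpid_partition")
}

#' @export
print.vpid_partition <- function(x, ...) {
  cat(sprintf("Identifier partition: %d nodes in %d components\n",
              length(x$nodes), length(unique(x$label))))
  invisible(x)
}

#' List the members of each component of a partition
#' @param partition a `vpid_partition`
#' @return named list: component label -> character vector of member node
#'   keys (sorted)
#' @export
partition_components <- function(partition) {
  stopifnot(inherits(partition, "vpid_partition"))
  split(partition$nodes, partition$label)
}

#' Derive the canonical vPID value of a component
#'
#' Members are rendered as `"1:<value>"` (ID1) or `"2:<value>"` (ID2),
#' sorted lexicographically, and joined with `"|"`.  Equal member sets
#' always yield equal vPID values regardless of insertion or claim order.
#' The kind prefix keeps an ID1 and an ID2 value with equal bytes from
#' colliding, and the reserved separator keeps the value decodable
#' (identifier values containing `":"` or `"|"` are rejected at
#' validation).
#'
#' @param kind character vector, `"ID1"` or `"ID2"` per member
#' @param value character vector of member identifier values
#' @param digest if `TRUE`, return a fixed-width 16-hex-character digest of
#'   the canonical string instead of the decodable concatenation
#' @return the canonical vPID value (length-1 character)
#' @examples
#' derive_vpid_value(c("ID1", "ID2", "ID1", "ID2"), c("B", "X", "A", "Y"))
#' @export
derive_vpid_value <- function(kind, value, digest = FALSE) {
  if (!length(value)) stop("a vPID component cannot be empty", call. = FALSE)
  if (!all(kind %in% c("ID1", "ID2"))) {
    stop("kind must be 'ID1' or 'ID2'", call. = FALSE)
  }
  canon <- paste(sort(unique(.node_keys(kind, value)), method = "radix"),
                 collapse = "|")
  if (digest) as.character(.fnv1a64(canon)) else canon
}

#' Assign a vPID value to every claim
#'
#' Every claim whose identifier nodes lie in a component receives that
#' component's canonical vPID.  A claim with neither identifier receives a
#' unique per-claim fallback vPID `"0:<claim_id>"` so claim counts are
#' conserved end to end (the `"0"` prefix cannot collide with component
#' vPIDs).
#'
#' @param claims validated claims table
#' @param partition a `vpid_partition` built from these claims
#' @param digest if `TRUE`, emit fixed-width hex digests of the canonical
#'   values (same partition, relabeled)
#' @return an object of class `vpid` (see [vpid()])
#' @export
assign_vpids <- function(claims, partition, digest = FALSE) {
  claims <- validate_claims(claims)
  stopifnot(inherits(partition, "vpid_partition"))
  graph <- build_edges(claims)
  if (!all(graph$nodes %in% partition$nodes)) {
    stop("partition does not cover all identifier nodes of these claims",
         call. = FALSE)
  }
  node_at <- match(graph$nodes, partition$nodes)

  # canonical value per component: members arrive pre-sorted because the
  # node universe is sorted and split() preserves order
  members <- split(partition$nodes, partition$comp_index)
  canon <- vapply(members, paste, "", collapse = "|")
  comp_of_label <- setNames(seq_along(members), names(members))
  vpid_values <- if (digest) as.character(.fnv1a64(canon)) else canon

  node_vpid <- vpid_values[comp_of_label[as.character(partition$comp_index)]]
  claim_node <- graph$claim_node
  vp <- character(nrow(claims))
  has_node <- !is.na(claim_node)
  vp[has_node] <- node_vpid[node_at[claim_node[has_node]]]
  vp[!has_node] <- paste0("0:", claims$claim_id[!has_node])

  member_kind <- ifelse(substr(partition$nodes, 1L, 1L) == "1", "ID1", "ID2")
  members_df <- data.frame(
    vpid = node_vpid,
    kind = member_kind,
    value = substring(partition$nodes, 3L),
    stringsAsFactors = FALSE)
  members_df <- members_df[order(members_df$vpid, members_df$kind,
                                 members_df$value, method = "radix"), ]
  rownames(members_df) <- NULL

  structure(list(
    assignment = data.frame(claim_id = claims$claim_id, vpid = vp,
                            stringsAsFactors = FALSE),
    members = members_df,
    skipped = graph$skipped,
    n_claims = nrow(claims),
    n_components = length(canon),
    digest = digest),
    class = "vpid")
}

#' Consolidate claims into virtual patient identifiers
#'
#' Runs the full vPID algorithm over a claims table: build the ID1/ID2
#' co-occurrence graph, compute its connected components with a
#' disjoint-set forest, derive a canonical value for each component
#' (sorted, prefixed member renderings joined with `"|"`), and assign each
#' claim the vPID of its component.  Two claims share a vPID exactly when
#' their identifier values are connected by a chain of co-occurrences, so
#' a patient's claims stay collectible across a change of either
#' identifier as long as the other one bridges the change.
#'
#' @param claims a claims table (see [claims_table()] / [read_claims()])
#' @param digest if `TRUE`, emit fixed-width 16-hex-character vPID digests
#'   instead of decodable concatenations (default `FALSE`)
#' @return an object of class `vpid` with components:
#'   \describe{
#'     \item{assignment}{data.frame `claim_id`, `vpid` (claims order)}
#'     \item{members}{data.frame `vpid`, `kind`, `value`: the identifier
#'       values merged into each vPID}
#'     \item{skipped}{claim ids carrying neither identifier (these receive
#'       per-claim fallback vPIDs)}
#'     \item{n_claims, n_components}{sizes}
#'   }
#' @examples
#' cl <- claims_table(c("c1", "c2", "c3", "c4"),
#'                    rep("2013-04", 4),
#'                    id1 = c("A", "B", "B", "C"),
#'                    id2 = c("X", "X", "Y", "Z"))
#' fit <- vpid(cl)
#' fit$assignment
#' @export
vpid <- function(claims, digest = FALSE) {
  claims <- validate_claims(claims)
  partition <- consolidate(build_edges(claims))
  assign_vpids(claims, partition, digest = digest)
}

#' @export
print.vpid <- function(x, ...) {
  cat("vPID consolidation\n")
  cat(sprintf("  claims:          %d (%d without any identifier)\n",
              x$n_claims, length(x$skipped)))
  cat(sprintf("  components:      %d\n", x$n_components))
  cat(sprintf("  distinct vPIDs:  %d\n", length(unique(x$assignment$vpid))))
  k1 <- sum(x$members$kind == "ID1")
  k2 <- sum(x$members$kind == "ID2")
  cat(sprintf("  merged values:   %d ID1, %d ID2\n", k1, k2))
  invisible(x)
}

#' @export
summary.vpid <- function(object, ...) {
  h1 <- merge_histogram(object, "ID1")
  h2 <- merge_histogram(object, "ID2")
  out <- list(n_claims = object$n_claims,
              n_components = object$n_components,
              n_skipped = length(object$skipped),
              cardinality_id1 = length(unique(
                object$members$value[object$members$kind == "ID1"])),
              cardinality_id2 = length(unique(
                object$members$value[object$members$kind == "ID2"])),
              histogram_id1 = h1, histogram_id2 = h2)
  class(out) <- "summary.vpid"
  out
}

#' @export
print.summary.vpid <- function(x, ...) {
  cat(sprintf("vPID consolidation of %d claims -> %d components\n",
              x$n_claims, x$n_components))
  cat(sprintf("  identifier cardinalities: ID1 %d, ID2 %d, vPID %d\n",
              x$cardinality_id1, x$cardinality_id2, x$n_components))
  for (kind in c("ID1", "ID2")) {
    h <- x[[if (kind == "ID1") "histogram_id1" else "histogram_id2"]]
    multi <- sum(h$fraction[h$k > 1])
    cat(sprintf("  vPIDs merging >1 %s value: %.1f%%\n", kind, 100 * multi))
  }
  invisible(x)
}

#' Histogram of identifier values merged per vPID
#'
#' For each vPID, counts the distinct member values of the requested kind;
#' returns the distribution of those counts over vPIDs containing at least
#' one value of that kind, normalized to fractions summing to one.  The
#' mass above `k = 1` is the fraction of vPID instances that actually
#' consolidated several values of that identifier — the consolidation the
#' naive identifier would have missed.
#'
#' @param x a `vpid` object, or a members data.frame with columns `vpid`,
#'   `kind`, `value` (as written by the `link` command)
#' @param kind `"ID1"` or `"ID2"`
#' @return data.frame with columns `k` (number of merged values) and
#'   `fraction`; attribute `n_vpids` gives the denominator
#' @export
merge_histogram <- function(x, kind = c("ID1", "ID2")) {
  kind <- match.arg(kind)
  members <- if (inherits(x, "vpid")) {
    x$members
  } else if (is.data.frame(x)) {
    required <- c("vpid", "kind", "value")
    if (!all(required %in% names(x))) {
      stop("members table needs columns vpid, kind, value", call. = FALSE)
    }
    unique(x[required])
  } else {
    stop("x must be a vpid object or a members data.frame", call. = FALSE)
  }
  m <- members[members$kind == kind, ]
  if (!nrow(m)) {
    out <- data.frame(k = integer(), fraction = numeric())
    attr(out, "n_vpids") <- 0L
    return(out)
  }
  counts <- table(m$vpid)  # one row per (vpid, value), values are distinct
  tab <- table(as.integer(counts))
  out <- data.frame(k = as.integer(names(tab)),
                    fraction = as.numeric(tab) / length(counts))
  rownames(out) <- NULL
  attr(out, "n_vpids") <- length(counts)
  out
}

#' Plot the consolidation histograms of a vPID fit
#'
#' Side-by-side fraction histograms of the numbers of ID1 and ID2 values
#' merged into a single vPID value.
#'
#' @param x a `vpid` object
#' @param kmax right-truncate the x axis at this merge count
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, the two histogram data.frames
#' @export
plot.vpid <- function(x, kmax = 6L, ...) {
  h1 <- merge_histogram(x, "ID1")
  h2 <- merge_histogram(x, "ID2")
  ks <- seq_len(max(1L, min(kmax, max(c(h1$k, h2$k, 1L)))))
  grab <- function(h) {
    if (!nrow(h)) return(setNames(numeric(length(ks)), ks))
    f <- tapply(h$fraction, factor(pmin(h$k, max(ks)), levels = ks), sum)
    f[is.na(f)] <- 0
    f
  }
  mat <- rbind(ID1 = grab(h1), ID2 = grab(h2))
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  barplot(mat, beside = TRUE, names.arg = ks,
          xlab = "identifier values merged into one vPID",
          ylab = "fraction of vPID instances",
          legend.text = TRUE, ...)
  invisible(list(ID1 = h1, ID2 = h2))
}

#' Rewrite claims with their vPID as both identifiers
#'
#' Utility for idempotence checks and downstream pipelines: each claim's
#' `id1` and `id2` are replaced by its (digested) vPID value, so
#' re-consolidating the result reproduces the same partition of claims.
#'
#' @param claims validated claims table
#' @param fit the `vpid` object fitted on `claims`
#' @return a claims table with both identifiers set to the claim's vPID
#' @export
relabel_claims <- function(claims, fit) {
  claims <- validate_claims(claims)
  stopifnot(inherits(fit, "vpid"))
  vp <- fit$assignment$vpid[match(claims$claim_id, fit$assignment$claim_id)]
  if (anyNA(vp)) stop("fit does not cover all claims", call. = FALSE)
  # digest so values are free of the reserved ":"/"|" characters
  token <- as.character(.fnv1a64(vp))
  claims$id1 <- token
  claims$id2 <- token
  claims
}
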