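# Shared fixtures and the independent components oracle.

# Toy world: citizen u1 changes ID1 (A -> B) and then ID2 (X -> Y), each
# change bridged by the other identifier; u2 is stable.
toy_claims <- function() {
  claims_table(c("c1", "c2", "c3", "c4"),
               c("2013-04", "2013-05", "2013-06", "2013-04"),
               id1 = c("A", "B", "B", "C"),
               id2 = c("X", "X", "Y", "Z"))
}

toy_truth <- function() {
  ground_truth(data.frame(claim_id = c("c1", "c2", "c3", "c4"),
                          citizen_number = c("u1", "u1", "u1", "u2"),
                          stringsAsFactors = FALSE))
}

# Twin world: two citizens share ID1 value D (same insured token, gender,
# birthdate) but have distinct ID2 values.
twin_claims <- function() {
  claims_table(c("t1", "t2"), c("2013-04", "2013-04"),
               id1 = c("D", "D"), id2 = c("P", "Q"))
}

twin_truth <- function() {
  ground_truth(data.frame(claim_id = c("t1", "t2"),
                          citizen_number = c("u3", "u4"),
                          stringsAsFactors = FALSE))
}

# Independent oracle: connected components by breadth-first search over an
# adjacency list, no shared code with the disjoint-set implementation.
# Returns a canonical partition: list of sorted member vectors, sorted by
# first member.
bfs_components <- function(claims) {
  k1 <- ifelse(is.na(claims$id1), NA_character_, paste0("1:", claims$id1))
  k2 <- ifelse(is.na(claims$id2), NA_character_, paste0("2:", claims$id2))
  nodes <- unique(c(k1[!is.na(k1)], k2[!is.na(k2)]))
  adj <- new.env(parent = emptyenv())
  for (v in nodes) assign(v, character(), envir = adj)
  both <- which(!is.na(k1) & !is.na(k2))
  for (i in both) {
    assign(k1[i], c(get(k1[i], envir = adj), k2[i]), envir = adj)
    assign(k2[i], c(get(k2[i], envir = adj), k1[i]), envir = adj)
  }
  unvisited <- new.env(parent = emptyenv())
  for (v in nodes) assign(v, TRUE, envir = unvisited)
  comps <- list()
  for (start in nodes) {
    if (!exists(start, envir = unvisited)) next
    queue <- start
    seen <- character()
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!exists(v, envir = unvisited)) next
      rm(list = v, envir = unvisited)
      seen <- c(seen, v)
      queue <- c(queue, get(v, envir = adj))
    }
    comps[[length(comps) + 1L]] <- sort(seen, method = "radix")
  }
  comps[order(vapply(comps, `[`, "", 1L), method = "radix")]
}

# Canonical partition form of a consolidate() result, comparable with the
# oracle's output.
partition_as_sets <- function(partition) {
  comps <- unname(partition_components(partition))
  comps <- lapply(comps, sort, method = "radix")
  comps[order(vapply(comps, `[`, "", 1L), method = "radix")]
}

# Random claims instance with small identifier pools and mixed missing
# identifiers (claims with neither identifier allowed).
random_claims <- function(n_claims, n_id1 = 30L, n_id2 = 30L,
                          p_miss1 = 0.15, p_miss2 = 0.15) {
  id1 <- sprintf("a%03d", sample.int(n_id1, n_claims, replace = TRUE))
  id2 <- sprintf("b%03d", sample.int(n_id2, n_claims, replace = TRUE))
  id1[runif(n_claims) < p_miss1] <- NA_character_
  id2[runif(n_claims) < p_miss2] <- NA_character_
  claims_table(sprintf("c%05d", seq_len(n_claims)),
               rep("2014-01", n_claims), id1 = id1, id2 = id2)
}

# Small simulated world with selected mechanisms switched on.
quick_world <- function(seed, n = 500L, months = 12L, rate = 1.0, ...) {
  over <- list(...)
  cfg <- unclass(sim_config(n_citizens = n, n_months = months,
                            claims_per_citizen_month = rate, seed = seed))
  cfg[names(over)] <- over
  simulate_world(validate_sim_config(cfg))
}
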