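test_that("co-occurrence edges follow the claim structure", {
  g <- build_edges(toy_claims()[1:3, ])
  expect_setequal(paste(g$nodes[g$from], g$nodes[g$to]),
                  c("1:A 2:X", "1:B 2:X", "1:B 2:Y"))
  # single-identifier claim contributes an isolated node
  g <- build_edges(claims_table("c1", "2013-04", id1 = "C"))
  expect_equal(g$nodes, "1:C")
  expect_length(g$from, 0L)
  # claims with neither identifier are skipped and logged
  g <- build_edges(claims_table(c("c1", "c2"), "2013-04",
                                id1 = c("A", NA), id2 = c("X", NA)))
  expect_equal(g$skipped, "c2")
  # empty input
  g <- build_edges(toy_claims()[0, ])
  expect_length(g$nodes, 0L)
})

test_that("an ID1 and an ID2 value with equal bytes are distinct nodes", {
  cl <- claims_table(c("c1", "c2"), "2013-04",
                     id1 = c("A", "B"), id2 = c("A", "Z"))
  p <- consolidate(build_edges(cl))
  sets <- partition_as_sets(p)
  expect_equal(sets, list(list("1:A", "2:A"), list("1:B", "2:Z")) |>
                 lapply(unlist))
})

test_that("consolidation matches the breadth-first oracle on crafted cases", {
  # toy graph plus an isolated pair
  cl <- toy_claims()
  expect_equal(partition_as_sets(consolidate(build_edges(cl))),
               bfs_components(cl))
  # claims (L_i, R_i) and (L_{i+1}, R_i), i = 1..1000, chain into a single
  # component of 2001 nodes
  n <- 1000L
  chain <- claims_table(
    sprintf("c%04d", seq_len(2L * n)),
    "2014-01",
    id1 = sprintf("L%04d", c(seq_len(n), seq_len(n) + 1L)),
    id2 = sprintf("R%04d", c(seq_len(n), seq_len(n))))
  p <- consolidate(build_edges(chain))
  sets <- partition_as_sets(p)
  expect_length(sets, 1L)
  expect_length(sets[[1L]], 2L * n + 1L)
  expect_equal(sets, bfs_components(chain))
  # n fresh pairs -> n components of size 2
  fresh <- claims_table(sprintf("c%03d", 1:50), "2014-01",
                        id1 = sprintf("p%03d", 1:50),
                        id2 = sprintf("q%03d", 1:50))
  sets <- partition_as_sets(consolidate(build_edges(fresh)))
  expect_length(sets, 50L)
  expect_true(all(lengths(sets) == 2L))
})

test_that("consolidation equals the oracle on random instances with missing ids", {
  set.seed(90)
  for (i in 1:60) {
    cl <- random_claims(sample(1:120, 1),
                        n_id1 = sample(3:40, 1), n_id2 = sample(3:40, 1))
    expect_equal(partition_as_sets(consolidate(build_edges(cl))),
                 bfs_components(cl))
  }
})

test_that("vPID values are canonical renderings of the member set", {
  expect_equal(derive_vpid_value(c("ID1", "ID2", "ID1", "ID2"),
                                 c("B", "X", "A", "Y")),
               "1:A|1:B|2:X|2:Y")
  expect_equal(derive_vpid_value(c("ID1", "ID2"), c("C", "Z")), "1:C|2:Z")
  # insertion order never matters
  expect_equal(derive_vpid_value(c("ID2", "ID1"), c("Z", "C")), "1:C|2:Z")
  expect_error(derive_vpid_value(character(), character()), "empty")
  expect_error(derive_vpid_value("ID3", "A"), "kind")
})

test_that("claims are assigned the vPID of their component", {
  fit <- vpid(toy_claims())
  expect_equal(fit$assignment$vpid,
               c(rep("1:A|1:B|2:X|2:Y", 3), "1:C|2:Z"))
  # a claim with only id1 = C joins the component of (C, Z)
  cl <- claims_table(c("c1", "c2"), "2013-04",
                     id1 = c("C", "C"), id2 = c(NA, "Z"))
  fit <- vpid(cl)
  expect_equal(unique(fit$assignment$vpid), "1:C|2:Z")
  # a claim with no identifiers gets the per-claim fallback vPID
  cl <- claims_table(c("c9", "c2"), "2013-04",
                     id1 = c(NA, "C"), id2 = c(NA, "Z"))
  fit <- vpid(cl)
  expect_equal(fit$assignment$vpid[1], "0:c9")
  expect_equal(fit$skipped, "c9")
  expect_equal(fit$n_claims, 2L)
})

test_that("vPID assignment is invariant to claim order", {
  set.seed(91)
  cl <- random_claims(200)
  fit <- vpid(cl)
  for (i in 1:5) {
    perm <- cl[sample.int(nrow(cl)), ]
    fitp <- vpid(validate_claims(perm))
    m <- match(fit$assignment$claim_id, fitp$assignment$claim_id)
    expect_identical(fitp$assignment$vpid[m], fit$assignment$vpid)
  }
})

test_that("re-consolidating vPID-relabeled claims is idempotent", {
  set.seed(92)
  cl <- random_claims(300)
  fit <- vpid(cl)
  again <- vpid(relabel_claims(cl, fit))
  # same partition of claims: vPID labels induce identical claim groupings
  g1 <- split(fit$assignment$claim_id, fit$assignment$vpid)
  g2 <- split(again$assignment$claim_id, again$assignment$vpid)
  canon <- function(g) unname(lapply(g, sort))[order(vapply(
    lapply(g, sort), `[`, "", 1L))]
  expect_equal(canon(g1), canon(g2))
})

test_that("adding claims only ever merges components, never splits them", {
  set.seed(93)
  cl <- random_claims(250)
  base <- vpid(cl[1:150, ])
  grown <- vpid(cl)
  # any two claims sharing a vPID in the smaller set still share one
  g <- split(base$assignment$claim_id, base$assignment$vpid)
  vp <- setNames(grown$assignment$vpid, grown$assignment$claim_id)
  for (members in g[lengths(g) > 1]) {
    expect_length(unique(vp[members]), 1L)
  }
})

test_that("digesting relabels vPIDs without changing the partition", {
  set.seed(94)
  cl <- random_claims(200, p_miss1 = 0, p_miss2 = 0)
  plain <- vpid(cl)
  hexed <- vpid(cl, digest = TRUE)
  expect_true(all(grepl("^[0-9a-f]{16}$", hexed$assignment$vpid)))
  # bijection between plain and digested labels
  n_hex_per_plain <- tapply(hexed$assignment$vpid, plain$assignment$vpid,
                            function(v) length(unique(v)))
  expect_true(all(n_hex_per_plain == 1L))
  expect_equal(length(unique(hexed$assignment$vpid)),
               length(unique(plain$assignment$vpid)))
})

test_that("component count is bounded by both cardinalities when ids are complete", {
  set.seed(95)
  for (i in 1:10) {
    cl <- random_claims(150, p_miss1 = 0, p_miss2 = 0)
    fit <- vpid(cl)
    expect_lte(fit$n_components,
               min(length(unique(cl$id1)), length(unique(cl$id2))))
  }
})

test_that("merge histograms count distinct merged values and sum to one", {
  fit <- vpid(toy_claims())
  h <- merge_histogram(fit, "ID1")
  expect_equal(h, data.frame(k = 1:2, fraction = c(0.5, 0.5)),
               ignore_attr = TRUE)
  h2 <- merge_histogram(fit, "ID2")
  expect_equal(h2$fraction, c(0.5, 0.5))
  # all-singleton world
  fresh <- claims_table(sprintf("c%02d", 1:9), "2014-01",
                        id1 = sprintf("p%02d", 1:9),
                        id2 = sprintf("q%02d", 1:9))
  h <- merge_histogram(vpid(fresh), "ID1")
  expect_equal(h, data.frame(k = 1L, fraction = 1), ignore_attr = TRUE)
  # normalization on random inputs
  set.seed(96)
  for (i in 1:5) {
    fit <- vpid(random_claims(200))
    expect_equal(sum(merge_histogram(fit, "ID1")$fraction), 1,
                 tolerance = 1e-9)
    expect_equal(sum(merge_histogram(fit, "ID2")$fraction), 1,
                 tolerance = 1e-9)
  }
})
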