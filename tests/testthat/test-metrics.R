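toy_labeled <- function(label, name = "x") {
  label_claims(toy_claims(), toy_truth(), label, name)
}

test_that("value and citizen maps are enumerated per the toy world", {
  cl <- toy_claims()
  lc <- toy_labeled(cl$id1, "ID1")
  v <- values_per_citizen(lc)
  expect_equal(v, list(u1 = c("A", "B"), u2 = "C"))
  u <- citizens_per_value(lc)
  expect_equal(u, list(A = "u1", B = "u1", C = "u2"))

  fit <- vpid(cl)
  lcv <- toy_labeled(fit$assignment$vpid, "vPID")
  expect_equal(values_per_citizen(lcv),
               list(u1 = "1:A|1:B|2:X|2:Y", u2 = "1:C|2:Z"))

  # twin world: both twins carry the shared ID1 value
  lct <- label_claims(twin_claims(), twin_truth(), twin_claims()$id1, "ID1")
  expect_equal(citizens_per_value(lct), list(D = c("u3", "u4")))

  # empty inputs give empty maps
  lce <- label_claims(toy_claims()[0, ], ground_truth(
    data.frame(claim_id = character(), citizen_number = character())),
    character())
  expect_equal(values_per_citizen(lce), setNames(list(), character()))
  expect_equal(citizens_per_value(lce), setNames(list(), character()))
})

test_that("traceability is the fraction of citizens with one single value", {
  expect_equal(traceability_score(toy_labeled(toy_claims()$id1)), 0.5)
  expect_equal(traceability_score(toy_labeled(toy_claims()$id2)), 0.5)
  fit <- vpid(toy_claims())
  expect_equal(traceability_score(toy_labeled(fit$assignment$vpid)), 1.0)
  # simultaneous-change citizen: two claims with disjoint identifier pairs
  sim <- claims_table(c("s1", "s2"), c("2013-04", "2013-09"),
                      id1 = c("E", "F"), id2 = c("R", "S"))
  tr <- ground_truth(data.frame(claim_id = c("s1", "s2"),
                                citizen_number = c("u5", "u5")))
  fit <- vpid(sim)
  expect_equal(traceability_score(
    label_claims(sim, tr, fit$assignment$vpid)), 0.0)
})

test_that("identifiability is the fraction of citizens sharing no value", {
  expect_equal(identifiability_score(
    label_claims(twin_claims(), twin_truth(), twin_claims()$id1)), 0.0)
  expect_equal(identifiability_score(toy_labeled(toy_claims()$id1)), 1.0)
  # single-citizen world has nobody to collide with
  one <- claims_table("c1", "2013-04", "A", "X")
  tr1 <- ground_truth(data.frame(claim_id = "c1", citizen_number = "u1"))
  expect_equal(identifiability_score(label_claims(one, tr1, one$id1)), 1.0)
})

test_that("scores are undefined without citizens", {
  lc <- label_claims(toy_claims()[0, ], ground_truth(
    data.frame(claim_id = character(), citizen_number = character())),
    character())
  expect_error(traceability_score(lc), "undefined")
  expect_error(identifiability_score(lc), "undefined")
  expect_equal(cardinality(lc), 0L)
})

test_that("cardinality counts distinct values among scored claims", {
  expect_equal(cardinality(toy_labeled(toy_claims()$id1)), 3L)
  fit <- vpid(toy_claims())
  expect_equal(cardinality(toy_labeled(fit$assignment$vpid)), 2L)
})

test_that("claims without the identifier or without truth are excluded and counted", {
  cl <- claims_table(c("c1", "c2", "c3"), "2013-04",
                     id1 = c("A", NA, "B"), id2 = c("X", "Y", "Z"))
  tr <- ground_truth(data.frame(claim_id = c("c1", "c2"),
                                citizen_number = c("u1", "u2")),
                     unresolved = "c3")
  lc <- label_claims(cl, tr, cl$id1)
  expect_length(lc$label, 1L)
  expect_equal(lc$n_excluded_unresolved, 1L)
  expect_equal(lc$n_excluded_unlabeled, 1L)
  # claims absent from the truth altogether are an error, not silence
  expect_error(
    label_claims(cl, ground_truth(data.frame(claim_id = "c1",
                                             citizen_number = "u1")),
                 cl$id1),
    "does not cover")
})

test_that("the three-identifier evaluation reproduces the toy enumeration", {
  ev <- evaluate_identifiers(toy_claims(), toy_truth())
  df <- as.data.frame(ev)
  expect_equal(df$identifier_name, c("ID1", "ID2", "vPID"))
  expect_equal(df$cardinality, c(3L, 3L, 2L))
  expect_equal(df$traceability, c(0.5, 0.5, 1.0))
  expect_equal(df$identifiability, c(1.0, 1.0, 1.0))
  expect_equal(df$avg_instances_per_citizen, c(1.5, 1.5, 1.0))
})

test_that("score reports keep the traceability identity across two code paths", {
  set.seed(71)
  worlds <- list(
    list(cl = toy_claims(), tr = toy_truth()),
    list(cl = twin_claims(), tr = twin_truth()))
  for (s in c(3, 14)) {
    w <- quick_world(s, n = 300L, p_id1_change = 0.02, p_id2_change = 0.04,
                     p_simultaneous = 0.002, twin_fraction = 0.02,
                     p_garbage = 0.003)
    worlds[[length(worlds) + 1L]] <- list(cl = w$claims, tr = w$truth)
  }
  for (wd in worlds) {
    ev <- evaluate_identifiers(wd$cl, wd$tr)
    for (r in ev$reports) {
      expect_identical(r$traceability,
                       1 - r$n_multi_value_citizens / r$n_citizens)
      expect_identical(r$avg_instances_per_citizen == 1,
                       r$traceability == 1)
      expect_gte(r$identifiability, 0); expect_lte(r$identifiability, 1)
      expect_gte(r$traceability, 0); expect_lte(r$traceability, 1)
      expect_gte(r$avg_instances_per_citizen, 1)
    }
  }
})

test_that("vPID traceability dominates and identifiability is dominated when ids are complete", {
  for (s in c(5, 23, 57)) {
    w <- quick_world(s, n = 400L, p_id1_change = 0.03, p_id2_change = 0.05,
                     p_simultaneous = 0.004, twin_fraction = 0.03,
                     p_garbage = 0.004, p_clerical_id1 = 0.002,
                     p_clerical_id2 = 0.002)
    df <- as.data.frame(evaluate_identifiers(w$claims, w$truth))
    rownames(df) <- df$identifier_name
    expect_gte(df["vPID", "traceability"],
               max(df["ID1", "traceability"], df["ID2", "traceability"]))
    expect_lte(df["vPID", "identifiability"],
               min(df["ID1", "identifiability"], df["ID2", "identifiability"]))
    expect_lte(df["vPID", "cardinality"],
               min(df["ID1", "cardinality"], df["ID2", "cardinality"]))
  }
})

test_that("a world where 0.582% of citizens carry multiple values scores 0.994", {
  # definitional self-consistency of the all-or-nothing traceability score:
  # give exactly 582 of 100,000 citizens a second label and score it
  n <- 100000L
  n_multi <- 582L
  citizen <- sprintf("u%06d", c(seq_len(n), seq_len(n_multi)))
  label <- sprintf("v%06d", c(seq_len(n), n + seq_len(n_multi)))
  cl <- claims_table(sprintf("c%06d", seq_along(citizen)), "2013-04",
                     id1 = label, id2 = label)
  tr <- ground_truth(data.frame(claim_id = cl$claim_id,
                                citizen_number = citizen))
  lc <- label_claims(cl, tr, label, "vPID")
  expect_equal(round(traceability_score(lc), 3), 0.994)
})
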