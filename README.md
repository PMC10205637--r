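# vpid — virtual patient identifiers for anonymized claims databases

Japan's national claims repository (NDB) stores no raw personal
identifiers. Each healthcare insurance claim instead carries two anonymized
hash identifiers: **ID1**, derived from the insured identifier, gender and
birthdate, and **ID2**, derived from name, gender and birthdate. Both churn
with life events — ID1 when a citizen changes insurance programs (job
changes), ID2 on name changes (marriage) and name typos — so neither can
collect all of a patient's claims, which blocks longitudinal analyses.

This package implements the **virtual patient identifier (vPID)**: ID1 and
ID2 values that co-occur in an identical claim are merged transitively, and
each connected component of that bipartite co-occurrence graph becomes one
canonical identifier value (the sorted, prefixed member renderings joined
with `|`). As long as only one of the two identifiers changes at a time,
the other bridges the change and the patient's claims remain collectible
under a single vPID.

For an identifier *I* evaluated against ground-truth citizen numbers *u*
(from enrollment-history records), with *V(u)* the set of *I*-values on
*u*'s claims and *U(v)* the set of citizens carrying value *v*, the package
scores:

- **traceability** = |{u : |V(u)| = 1}| / #citizens — the fraction of
  citizens whose claims are all collectible under one value;
- **identifiability** = |{u : U(v) = {u} for every v ∈ V(u)}| / #citizens —
  the fraction of citizens none of whose values is shared with anyone else.

Both are patient-level and all-or-nothing, deliberately stricter than
record-level precision/recall. Consolidation trades one for the other:
vPID traceability is provably ≥ that of either input identifier, and vPID
identifiability is provably ≤ (shared values — twins' common ID1, garbage
sentinel values — propagate into the merged identifier).

Because the prefecture-level datasets the method was validated on are not
shareable, the package ships a synthetic claims-world simulator with exact
ground truth, reproducing the churn mechanisms above plus the known failure
modes (simultaneous ID1+ID2 change, same-sex twins, clerical typos, garbage
claims with identical wrong values), so every property of the method is
testable at desk scale.

## Worked example

```r
library(vpid)

# Citizen u1 changes ID1 (A -> B), later ID2 (X -> Y); u2 is stable.
cl <- claims_table(c("c1","c2","c3","c4"),
                   c("2013-04","2013-05","2013-06","2013-04"),
                   id1 = c("A","B","B","C"), id2 = c("X","X","Y","Z"))
fit <- vpid(cl)
fit$assignment
#>   claim_id            vpid
#> 1       c1 1:A|1:B|2:X|2:Y
#> 2       c2 1:A|1:B|2:X|2:Y
#> 3       c3 1:A|1:B|2:X|2:Y
#> 4       c4         1:C|2:Z

tr <- ground_truth(data.frame(claim_id = paste0("c", 1:4),
                              citizen_number = c("u1","u1","u1","u2")))
evaluate_identifiers(cl, tr, fit)
#> Identifier evaluation (2 citizens)
#>                                 ID1   ID2  vPID
#> Number of instances               3     3     2
#> Identifiability score         1.000 1.000 1.000
#> Traceability score            0.500 0.500 1.000
#> Average instances per citizen 1.500 1.500 1.000
```

Under ID1 (or ID2) alone, u1's claims split across two values —
traceability 0.5. The chain A–X, B–X, B–Y connects everything u1 ever
carried, so the vPID traces both citizens perfectly.

At scale, on the calibrated synthetic world (10,000 citizens, 36 months,
all churn mechanisms active):

```r
w  <- simulate_world(scenario_preset("mie_like"))
evaluate_identifiers(w$claims, w$truth)
#> Identifier evaluation (10000 citizens)
#>                                 ID1   ID2  vPID
#> Number of instances           12048 16032 10052
#> Identifiability score         0.998 1.000 0.998
#> Traceability score            0.814 0.542 0.994
#> Average instances per citizen 1.206 1.603 1.006
```

The naive identifiers lose 19–46% of citizens to churn; consolidation
recovers near-complete traceability at a small identifiability cost (twin
pairs sharing ID1).

## Command-line pipeline

The installed script `inst/cli/vpid.R` drives the four pipeline stages:

```sh
RS="Rscript $(Rscript -e 'cat(system.file("cli","vpid.R",package="vpid"))')"
$RS simulate --preset mie_like --out world/
$RS link     --claims world/claims.csv --out linked/
$RS evaluate --claims world/claims.csv --truth world/truth.csv \
             --vpid-map linked/vpid_map.csv --out report/ --format table
$RS histogram --members linked/members.csv --kind ID1 --out hist/
```

Each command writes a `manifest.json` (resolved parameters, input
checksums, outputs, version, timestamp). Exit codes: 0 success, 1 data
error, 2 usage error.

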