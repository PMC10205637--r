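---
title: "Consolidating churn-prone anonymized identifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating churn-prone anonymized identifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpid)
```

## The identifier problem

Anonymized claims repositories replace personal identifiers with hashes of
quasi-identifiers. Here two such identifiers coexist on every claim: ID1,
hashed from the insured identifier plus gender and birthdate, and ID2,
hashed from name plus gender and birthdate. Each is stable only as long as
its source fields are: ID1 churns when a citizen's insurance program
changes, ID2 when a name changes or is mistyped. An analyst grouping claims
by either identifier therefore fragments many patients' histories.

## The consolidation model

Treat every identifier value as a node of a graph — nodes are (kind, value)
pairs, so an ID1 value and an ID2 value with identical bytes stay distinct.
Every claim carrying both identifiers contributes an edge between its two
nodes. The virtual patient identifier (vPID) of a claim is the connected
component its nodes fall into, rendered canonically: each member as
`1:<value>` or `2:<value>`, members sorted lexicographically, joined with
`|`.

The single modeling assumption is that **the two identifiers rarely change
at the same instant**. A change of one identifier between two claims is
bridged by the unchanged other identifier; only a simultaneous change of
both (or a citizen with no claim in the bridging window) disconnects a
patient's history.

Components are computed with a disjoint-set forest (path compression +
union by size, implemented in C++), giving near-linear cost in the number
of claims. Component labels are chosen as the lexicographically smallest
member rendering, so output is deterministic and independent of claim
order; all orderings use radix (byte) sorting, never locale collation.

Degenerate inputs are kept, not dropped: a claim with one identifier
contributes an isolated node and joins whatever component that node ends up
in; a claim with neither identifier receives the per-claim fallback vPID
`0:<claim_id>` (the `0` prefix cannot collide with component vPIDs), so
claim counts are conserved through the pipeline. Identifier values
containing the reserved `:` or `|` are rejected at validation, keeping
every vPID decodable; an optional flag digests the canonical string to a
fixed-width hex token for compactness (off by default, so tests and
downstream joins see decodable values).

## Scoring against ground truth

Enrollment-history records bind identifier values to an anonymized unique
citizen number over validity periods; joining claims to them gives ground
truth. The join rule is deliberately conservative: a claim maps to a
citizen only if **exactly one** citizen has an era containing the claim's
service month whose id1 matches the claim's id1 *or* whose id2 matches the
claim's id2. OR-matching tolerates a clerical error in one identifier;
the uniqueness requirement sends ambiguous claims (e.g. a garbage value
matching several citizens, or a twin's claim matching both twins' eras via
the shared ID1) to an explicit `unresolved` set rather than guessing.

For an identifier labeling, with $V(u)$ the distinct values on citizen
$u$'s scored claims and $U(v)$ the citizens carrying value $v$:

- traceability $= \frac{1}{|C|}\,|\{u : |V(u)| = 1\}|$,
- identifiability $= \frac{1}{|C|}\,|\{u : U(v)=\{u\}\ \forall v \in V(u)\}|$,

where $C$ is the set of citizens with at least one scored claim (an
identifier derived from claims can say nothing about citizens who have
none). Both definitions are patient-level and all-or-nothing, which makes
them stricter than record-level precision and recall. Scored claims are
those carrying the evaluated identifier and resolving to a citizen;
exclusions are counted on the report.

Two consequences are theorems when every scored claim carries both
identifiers, and the test suite asserts them on randomized worlds:

- **traceability(vPID) ≥ max(traceability(ID1), traceability(ID2))** — if
  all of $u$'s claims share one ID1 value, they all contain that node, so
  they lie in one component;
- **identifiability(vPID) ≤ min(identifiability(ID1),
  identifiability(ID2))** — a value shared between two citizens places both
  citizens' claims in one shared component.

A numerical note: the report computes traceability and the multi-value
citizen count by independent code paths and guarantees
`traceability == 1 - n_multi_value_citizens / n_citizens` *exactly*. In
IEEE arithmetic `(n-m)/n` and `1 - m/n` can differ in the last ulp, so both
paths evaluate the same final expression `1 - count/n`, with the *count*
established independently (per-citizen split/unique versus deduplicated
pair tabulation).

## The synthetic claims world

No real claims or enrollment data can ship with the package, so the
simulator provides worlds with exact ground truth. Each citizen carries
surrogate source tokens; identifiers are 64-bit digests (FNV-1a, hex
rendered) of kind + token + gender + birthdate. The digest is this
package's stand-in for the production hashing scheme, which is not public;
all that matters structurally is determinism, avalanche on any field
change, and a collision probability that is negligible at the simulated
scale (~$10^{-11}$ for $2\times10^4$ values in a 64-bit space).

Per citizen-month (from the second month on), three Bernoulli events can
fire: an insurance change (fresh insured token → new ID1), a name change
(fresh name token → new ID2), and a simultaneous change (both tokens change
at the same month boundary, so no claim can intervene). Claim counts per
citizen-month are Poisson — the minimal choice absent any published
claim-frequency model; the mean is a configuration knob. Per claim, a
clerical error replaces one identifier by a one-off wrong value (typos are
transient, tied to a single document; a persistent misspelling is
representable as a name-change event), and a garbage event replaces ID2 by
the single shared sentinel — the digest of a blank name and zero birthdate
— emulating batches of claims with identical incorrect values. A configured
fraction of citizens form same-sex twin pairs sharing insured token, gender
and birthdate, hence sharing ID1 for as long as neither changes insurance.
Enrollment eras are emitted at every identifier change, tiling each
citizen's months exactly.

Two structural subtleties are worth stating. First, independent ID1 and
ID2 changes that happen to fall in the *same* month are effectively
simultaneous — this coincidence term is part of the calibration below.
Second, claims of twins are inherently ambiguous to the conservative
ground-truth join (the co-twin's era also matches via the shared ID1), so
the resolver-recovers-simulation-truth property is exercised with twins
and clerical errors disabled; the simulator's own truth table, which knows
the emitting citizen, is exact always.

What the simulator does **not** emulate: demographic structure, diagnosis
and cost content, insurer heterogeneity, seasonal claim volume, and the
heavy-tailed per-citizen distribution of identifier churn seen in real
data (events are i.i.d. across citizen-months). Passing tests therefore
demonstrate the method's structural properties and the direction and
rough size of its trade-offs — not the exact scores of any real dataset.

## Calibration of the prefecture-like presets

The `mie_like` preset targets the published per-citizen identifier
statistics: about 1.206 ID1 and 1.584 ID2 values per citizen, and a
multi-vPID citizen fraction near 0.58%. At 36 months and 1.5 claims per
citizen-month, the expected number of distinct values per citizen is
approximately

$$E[\#\text{values}] \approx 1 + 35\,(p_{\text{change}} + p_{\text{sim}})
  + 54\,p_{\text{clerical}},$$

and the multi-vPID fraction is approximately
$35\,(p_{\text{sim}} + p_1 p_2) + \text{(adjacent-gap term)}$. Solving
these identities (with $p_{\text{clerical}}$ fixed at 0.0005 for ID1 and
0.001 for ID2 — names are more typo-prone — and twin fraction 0.002,
matching the ~0.1% shared-vPID rate) gives the preset's rates; they were
derived from these formulas, not fitted to runs. `gifu_like` repeats the
exercise for the second published column and adds a garbage rate of
0.00035, sized so that roughly 2% of citizens acquire the sentinel and
lose identifiability. Presets run at 10,000 citizens × 36 months — a
deliberate scale-down (the originating datasets are ~10^6 citizens over
~5 years) that keeps a full simulate–link–evaluate cycle under ten
seconds while leaving Monte-Carlo noise on the scores at the ±0.003
level.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `claims_per_citizen_month` | mean claims / citizen-month | 1.0 (presets 1.0–1.5) | matches ~1.5 observed in prefecture data; controls bridging density |
| `p_id1_change`, `p_id2_change` | prob. / citizen-month | 0 | churn rates; calibrated in presets |
| `p_simultaneous` | prob. / citizen-month | 0 | the one unbridgeable event; lowers vPID traceability only |
| `p_clerical_id1/2` | prob. / claim | 0 | transient one-off values; add spurious identifier instances |
| `twin_fraction` | fraction of citizens | 0 | shared ID1; lowers identifiability only |
| `p_garbage` | prob. / claim | 0 | shared sentinel ID2; lowers identifiability only |
| `digest` (linkage) | flag | off | hex vPIDs for compactness; partition unchanged |

## Known limitations

- Consolidation is deterministic and transitive: one shared garbage value
  merges *all* citizens that ever carried it into a single component, so a
  small garbage rate produces a disproportionate identifiability loss —
  the motivation for pre-filtering erroneous claims upstream.
- A citizen with no claims cannot be consolidated at all; scores condition
  on having claims.
- The simulator's i.i.d. event model cannot reproduce the overdispersed
  churn of real populations (e.g. a published case where a *lower* average
  instance count coexists with *higher* traceability); presets match
  first-moment statistics only.
- Incremental consolidation across data deliveries and linkage across
  heterogeneously anonymized databases are out of scope.
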