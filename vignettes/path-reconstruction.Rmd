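---
title: "Reconstructing distribution paths from dyadic shipping records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing distribution paths from dyadic shipping records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtrace)
```

## The problem and the model

Shipment registers for controlled pharmaceuticals record dyadic
transactions — date, sender, receiver, product, quantity — but not the
journey of individual packages. Reconstructing complete distribution
paths from such records requires deciding, at every shipment, *which*
units in the sender's stock fill the order. That decision is the single
degree of freedom of the method; everything else (timing, quantities,
counterparties) is fixed by the data.

The model is an inventory bookkeeping process. Each manufacturer or
distributor holds, per product, an ordered stock of batches; a batch
carries the partial path and date chronology of its units. Transactions
are processed chronologically (same-day transactions in input order —
administrative data carry no finer timestamp, and a fixed order makes the
whole computation deterministic). A shipment of quantity $q$ draws $q$
units from the sender's stock under the stock-management policy:

* **FIFO** — oldest batches first. The default, because the goods are
  perishable and first-expiry dispatch is recommended practice.
* **LIFO** — newest batches first, the natural alternative assumption.

A draw may split a batch (partial consumption; the batch keeps its
arrival position, since age is arrival time, not remaining size) or
combine several batches (one order filled from multiple provenances, each
allocation becoming its own path record). Allocations shipped to a
*final distributor* — any entity that is neither manufacturer nor
distributor, i.e. the terminal tier of pharmacies, hospitals,
practitioners and clinics — complete a path
$(\text{path}, \text{dates}, \text{quantity})$. Whatever remains in stock
at the end of the stream is in transit and is not emitted.

### Origins and the exogenous flag

When a sender ships more units than its recorded inflow, the shortfall
must originate somewhere. The package creates an *origin batch* rooted at
the sender. For a manufacturer this is the normal case — production is
not part of the shipment record, so every path begins exactly this way.
For any other sender it means provenance is genuinely unknown (typically
stock predating the observation window, or dirty typing such as shipments
*by* terminal-tier entities); those origin batches and every path
descending from them carry `exogenous_origin = TRUE`. The flag preserves
unit conservation while letting users exclude unreliable paths instead of
silently mixing them. Self-loop transactions (sender equals receiver)
carry no path information and are skipped and counted; repeated visits to
the same entity across distinct steps are recorded as-is. Transactions
whose sender or receiver type cannot be resolved are skipped and counted
by default (`on_unknown_entity = "error"` makes them fatal).

Because transactions are processed in chronological order, a batch can
never be drawn on a date earlier than its last recorded step, so emitted
chronologies are nondecreasing by construction; the
`on_date_regression` setting exists as a guard for callers who bypass the
loader's ordering.

### Memory contract

Batch splitting makes naive path copies quadratic: at production scale
(hundreds of millions of paths) per-batch copies are infeasible, and even
at desk scale the correct contract matters. Paths are therefore stored as
a reversed tree of immutable nodes (`path_arena()`): a batch holds a node
id; extension allocates one node referencing the shared prefix;
sequences are materialized only on emission. Memory is proportional to
nodes created, which the tests assert directly.

## Conservation laws

Two invariants hold for every reconstruction and every simulation, and
are checked in the test suite:

* per (entity, product): inflow − outflow = residual stock ≥ 0, with
  origin batches counting as inflow at creation;
* globally: units delivered along completed paths + residual units =
  manufacturer-origin units + exogenous units.

## Validation statistics

Path identity for all similarity comparisons is the entity-ID sequence
only. Dates and quantities are excluded deliberately: comparisons across
policies or across years ask whether the same *routes* are used, and any
date-sensitive identity would make similarity trivially near zero. Under
that identity the unique Jaccard index compares distinct route sets and
the weighted index weights routes by multiplicity (record count by
default; delivered-unit weighting is available via `weight =
"quantity"` — both are reported by `run_validate()` since either reading
of "multiplicity" is defensible). Two empty collections compare as
identical (similarity 1), consistent with the identity property.

Descriptive statistics follow the field's conventions: path length is the
number of distribution steps (entities minus one); days in transit is
last minus first shipping date; travel distance sums haversine
great-circle legs on the IUGG mean sphere (radius 6371.0088 km, fixed so
distance numbers are reproducible); step 1 of the per-step distance
profile is the manufacturer-to-first-distributor leg. CCDFs are empirical
step functions, $P(X > x)$. Entry/exit rates use the previous year's
active set as denominator — the standard turnover convention, stated
explicitly because plotted rates are meaningless without it — and demand
consecutive years. `yearly_activity()` accepts any entity subset, since
turnover can reasonably be computed for all entities or for mid-chain
distributors only.

## The synthetic generator

`simulate_distribution()` forward-simulates the process the
reconstruction assumes: manufacturers inject batches (Poisson arrivals
per manufacturer-day, uniform batch sizes), distributors hold them in
policy-ordered stocks, and each arrival schedules an onward dispatch
after a repacking delay; dispatches may split across several receivers
and reach the terminal tier with fixed probability. Ground truth is
tracked per allocated unit group with fully materialized journeys —
independent of the engine's shared-prefix machinery — so "the true path
of every delivered quantity" is well defined and the defining oracle test
is exact multiset equality between ledger and reconstruction under the
matching policy.

Default parameters describe a desk-scale regional market chosen once as
plausible for the domain: 3 manufacturers, 8 distributors, 40 final
distributors (an order of magnitude per tier, mirroring the strongly
bottom-heavy composition of real registrant populations), 2 products, a
120-day horizon, 0.6 injected batches per manufacturer-day of 50–200
units, 1–7 day repacking delays, dispatches split across up to 3
receivers, terminal probability 0.35, and 90% of each arrival forwarded
(the 10% residue builds up aged stock). Entity coordinates are drawn
uniformly in a bounding box spanning roughly the contiguous US. A run of
the default configuration is a few thousand transactions and takes well
under a second; the test suite's largest scenarios stay near $10^4$
transactions so the whole suite runs in about a minute and a half.

The policy never consumes random numbers — it only reorders which
physical units fill a shipment, and shipment quantities depend on stock
*totals*, which are policy-invariant. Hence `perturb_policy()` implements
a common-random-numbers pairing: same seed, both policies, identical
transaction streams, and any FIFO/LIFO difference in the ground truth is
attributable to the policy alone. Two scripted, randomness-free scenarios
round out the generator: `worked_example()` (the five-transaction
batch-splitting chronology) and `shortfall_example()` (one order filled
from two batches: FIFO takes 4 from the older then 1 from the newer;
LIFO takes 2 from the newer then 3 from the older).

```{r}
wx <- worked_example()
res <- reconstruct(wx$transactions, wx$entities, policy = "fifo")
tidy(res)
res$residual_stocks
```

### What the simulator does and does not emulate

It reproduces the structural features the reconstruction relies on:
chronological dyadic records, batch splitting and combination, multi-tier
forwarding, stocks deep enough for FIFO and LIFO to diverge, and aging
residue. It is *not* calibrated to any real market: no real geography or
market shares, no seasonality, no double-entry bookkeeping, no reporting
errors. Passing the recovery oracle therefore demonstrates algorithmic
correctness under the stated stock-management assumption — not that real
distribution systems follow FIFO, which on real data remains an
assumption whose sensitivity the FIFO/LIFO comparison quantifies.

With full forwarding and clustered arrivals, the paired comparison
reproduces the expected qualitative contrast: LIFO delivers most packages
faster (lower median transit) while a small right tail — the units that
kept being pushed to the bottom of the stock — waits far longer than
anything under FIFO, and the two policies coincide exactly whenever no
stock ever holds more than one batch.

## Numerical and design choices

* Dates are ISO-8601 by default with a configurable format; loading is a
  stable sort on date only, so within-day input order is preserved and
  reruns are byte-identical.
* Malformed rows are collected and reported, not fatal (strict mode
  available): administrative extracts contain dirt, and a hard failure on
  row 400 million helps no one.
* Business-activity strings map to the three tiers by configurable
  regular expressions, with final distributor as the default tier —
  matching the umbrella definition of the terminal tier.
* JSONL output fixes key order (`path`, `dates`, `quantity`) for
  diff-stable files; the `exogenous_origin` key is written only when
  `TRUE`, so ordinary records keep the minimal three-key schema while the
  round trip stays lossless.
* Stocks are keyed by (entity, NDC): units of different products never
  mix, matching the per-product organisation of published path datasets.
* FIFO ties among batches arriving the same day are broken by the
  creating transaction's input-order index — a total order is required
  for reproducibility.

## Limitations

* Path reliability near the start of the observation window is limited by
  unknown initial stocks; the exogenous flag marks exactly those paths.
* The stock-management policy is an assumption about the world, not an
  inference from it; only its two standard variants are implemented.
* Coordinates are caller-supplied; the package does no geocoding.
* The CCDF/histogram summaries describe delivered paths only; in-transit
  residue is reported as stock totals, not as censored paths.
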