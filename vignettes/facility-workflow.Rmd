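---
title: "The seqfab workflow model: planning, dosing, scoring and access control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seqfab workflow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfab)
```

seqfab models the day-to-day operation of a Sanger sequencing core
facility as a small, fully scriptable workflow engine. This vignette is
the package's own account of that model: the lifecycle and its
assumptions, the dosing chemistry and its parameters, how reads are
scored, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## The four-stage lifecycle

A facility operator's work on a plate passes through exactly four
stages: a customer's **new order**, a **planned run** (a plate map
assigning samples to wells), an **awaiting-results run** (chemistry
fixed, plate on or headed to the instrument) and a **completed run**
(results uploaded and handed back). Two rules carry most of the
correctness weight:

* *Orders freeze when planned.* Editing a sample after an operator has
  placed it on a plate would desynchronise the plate map, the robot
  worklist and the instrument sheet; so planning locks every member
  order, and only abandoning the (still unplanned-in-the-lab) run
  unlocks them. Once the instrument set-up sheet has been exported the
  run can never go back — the physical plate may already exist.
* *No silent no-ops.* Every (state, event) pair either transitions or
  raises a state-violation error; `lifecycle_transition()` exposes the
  full table and the test suite enumerates all of it.

A run is exactly one plate. The planner answers "how many plates do I
need" (`count_plates()`), which presumes plate-sized units; a run
spanning several physical plates would also break the one-worklist-
per-run correspondence the robots need. One *order* may however straddle
two runs when it crosses a plate boundary: plates are pooled across
customers precisely so that wells are not wasted, and `plan_runs(...,
split_orders = FALSE)` preserves the stricter alternative for facilities
that never split.

## Identifiers

Three identifier families are minted by the store and never reused:
order ids (`ORD-00001`, a readable monotonic token, familiar from online
shopping), run names (a configurable series letter plus counter, e.g.
`A726`; abandoned names are retired so a run name always denotes one
physical plate attempt), and sample references (`S000001`), minted at
submission and independent of any run. The sample reference is the pivot
of the whole system: it appears on the instrument sheet, in the
sequencer's file names, and in every export header, which is what lets
results be linked back automatically.

## Dosing chemistry

Each well holds four liquids summing to the total reaction volume
(default 10 µL, configurable): template, primer, a fixed volume of
pre-made reaction mix (4 µL), and water. Two dosing modes exist because
facilities trade robot speed against reaction quality:

* **FIXED** — template and primer volumes constant (1 µL each by
  default); the robot runs a time-optimised program.
* **VARIABLE** — template volume = target mass / concentration (100 ng
  per standard reaction), primer volume = target amount / concentration
  (5 pmol); each rounded **half-up** to the pipetting increment (0.1 µL,
  the resolution of the facility's smallest tips) and clamped into
  [one increment, total − mix]. Every clamp is reported as a warning
  naming the well. If the liquids would still overflow the well, the
  template then the primer are reduced to fit (again warned): water can
  reach zero but a well can never exceed its volume.

Degenerate inputs: a zero (or missing) template concentration in
VARIABLE mode is an error, not a clamp — there is no volume that doses
mass from nothing. A facility-stock primer has no customer-supplied
concentration, so it is dosed at the fixed primer volume in either mode;
the facility controls its stock concentrations, so a constant is the
honest choice.

The **order confirmation** (minimal volumes the customer must provide)
sums the per-reaction variable-mode demands per distinct template (and
per customer primer), multiplies by a safety factor (1.5 — pipetting
dead volume and the occasional repeat) and rounds **up** to a coarser
supply increment (0.5 µL): customers measure with benchtop pipettes, not
robot tips, and a supply volume must never round down below demand.
These are two deliberately separate increments in the configuration.

All of these numbers — limits, targets, increments, factors — live in a
YAML configuration (`default_config()`), never in code. The shipped
defaults (template 20–200 ng/µL, ≥ 10 µL supplied; primer 1–100 pmol/µL)
are ordinary working ranges for plasmid sequencing on capillary
instruments; a facility is expected to edit them.

## Plate layout and packing

Wells are traversed column-major (A1, B1, …, H1, A2, …) by default
because capillary sequencers inject by column groups; row-major is a
configuration switch. Samples are placed in FIFO submission order,
orders contiguous, samples within an order in listed order — the layout
an operator can predict without reading the map. Controls (one reaction
control, one instrument control by default; counts configurable down to
zero) sit in the last wells of the traversal, so the sample block always
starts at A1.

Packing is greedy: fill each plate to its usable capacity (96 minus
control wells) and start the next. With capacity as the only
constraint, the greedy count equals the exact minimum ⌈n / usable⌉ —
the test suite checks this against a brute-force oracle over random
queues (200 queues of up to 300 samples; sizes chosen to keep the
default suite around a hundred seconds) — so no cleverer packer is
warranted. Only the final plate of a batch can contain empty wells.

## Worklists and sheets

Three robot CSV dialects are defined by this package (the deck layouts
of real liquid handlers differ, but their vendors' column names are not
ours to reproduce): `FIXED_DECK_A` (constant volumes, deck-slot
addressed, valid only for FIXED-mode plans), `VARIABLE` (per-well
volumes), and `DECK_B` (the same data re-ordered for a second deck).
Conventions across all sheets: RFC 4180, CRLF endings, header always
present, volumes at one decimal, wells `A1`–`H12` unpadded. Exports are
pure functions of the run, so re-exports are byte-identical and the
dialect formats are frozen by golden-file tests.

The **manual-processing sheet** is a single-worksheet SpreadsheetML XML
document (it opens in Excel and is still plain text that this package
can parse back); it maps all 96 wells (empty ones marked) and scales
volumes by a manual multiplier (default 2.0 — hand pipetting works
comfortably at larger volumes). The **amended-volume importer** accepts
an edited VARIABLE CSV or manual sheet, requires the well set and
per-well names to match the run exactly (and the worksheet name for the
manual sheet), divides the manual multiplier back out, and logs every
changed cell as an amendment event. A recipe that no longer sums to the
reaction volume is a *warning*, not an error: the operator edited it on
purpose.

The **instrument set-up sheet** (well, `template_primer` display name,
run name, sample reference) is the hand-off point: its first export
fires the `PLANNED → AWAITING_RESULTS` transition; re-exports re-emit
identical bytes without a second transition.

## Scoring and trimming

The sequencer's text output for a sample is scored as follows. The
*readable length* is defined as the length remaining after trimming the
maximal terminal runs of ambiguity codes — any IUPAC letter outside
A/C/G/T, case-insensitively, with U counted as unambiguous so
RNA-alphabet text is not mangled. Interior ambiguities are untouched:
they are readable positions that happened to be uncertain.

* `%Read` = 100 × readable / requested, **uncapped** — 114 % is
  information (the reaction over-delivered), not an error.
* `%Amb` is computed on the **raw** sequence, not the trimmed one: it
  measures the quality of the upload as delivered. This was an open
  choice; raw was picked and is stated here prominently because the two
  definitions differ exactly when trimming removes a lot.
* Status is OK iff readable ≥ requested — equivalently iff
  `%Read ≥ 100`, an invariant the property tests assert.

Manual operator overrides of the status outrank any later automatic
re-scoring: the operator has seen the chromatogram, the scorer has not.
Chromatogram files (`.ab1`, `.scf`) are stored and served as opaque
bytes; base-calling and Phred-style quality are explicitly out of scope,
so scoring uses sequence text alone.

## Visibility and the event log

Two roles exist: operators see everything; users see orders belonging to
groups they are in or groups that granted theirs VIEW access. On top of
group scope, two redactions apply to non-operators everywhere (views,
searches, FASTA and archive exports): files of FAILED samples, and
PRIVATE notes. Planned runs are operator-only machinery — customers see
their orders and results, never the plate internals. There is no
authentication layer: callers assert an identity and the store enforces
what that identity may do, which is the part worth testing.

Customer notification is modelled as an append-only event log
(`order_confirmed`, `order_completed`, plus processing events like
`volumes_amended` and `status_overridden`) with a pluggable notifier
hook; actual transport (email) is out of scope. Log timestamps are
clamped to be non-decreasing so the log is always replayable in order.

Persistence is a single-file JSON snapshot of the store
(`store_save()` / `store_open()`), serialized at 17 significant digits
so every double survives exactly, with timestamps kept at whole-second
resolution for the same reason; the round trip is tested as full-store
equality. A desk-scale facility does not need a database server, and the
store layer is a narrow enough interface that one could be substituted.

## The synthetic-data generator

`fixture_spec()` + `generate_orders()` + `generate_sequencer_output()`
emulate the two external actors — customers and the sequencer — so the
entire pipeline runs with no real instrument. Order sheets draw
concentrations and volumes uniformly from configurable ranges (defaults
match the shipped validation limits); an error fraction can deliberately
breach limits to exercise rejection. Sequencer output draws, per sample:
failure with probability `fail_p` (a read of 0–50 % of the requested
length), otherwise a read of `mean_read_fraction ± 0.15` times the
requested length (default 1.2, so successful reads score OK with
margin); terminal `N` runs of Poisson length (mean 5) at both ends; and
interior ambiguities at a per-base rate (default 0.01), kept off the
core's boundary positions so the intended failed fraction is exact.

All randomness flows through one explicit seeded generator that swaps
its own `.Random.seed` in and out, so fixtures never perturb the
session's RNG and the same spec reproduces the same bytes — the
end-to-end demo (`run_demo()`) is tested to produce byte-identical
exports across two full executions, which the fixed-timestamp,
store-only ZIP writer makes possible.

What the generator does **not** emulate, and what green tests therefore
do not show: real chromatograms (traces are labelled `FIXTURE-` blobs),
Phred-like position-dependent quality decay, the correlation between
submitted DNA concentration/quality and read success, vector or adapter
sequence, and sequencer file-naming quirks beyond the
`<sample_ref>.<ext>` contract this package imposes. Results on real
instrument output depend on that naming contract being met.

## Numerical and testing choices

* Rounding is half-up at the pipetting increment; recipe closure is
  asserted to 0.01 µL (an order of magnitude below the increment).
* Volume equality on amended-sheet import uses a 10⁻⁶ µL tolerance —
  text round trips of one-decimal volumes are exact, so anything larger
  is a real edit.
* Suite sizes: 10 000 random IUPAC strings against a
  character-by-character scoring oracle, 200 random queues for packing,
  1 000 randomized visibility checks, two full demo executions for
  determinism. These sizes make the default suite complete in about two
  minutes on one core while keeping each property's coverage dense.

## Known limitations

Concurrency is out of scope: the store is a single in-memory state with
whole-file persistence, suitable for one operator session at a time.
Plate packing optimises capacity only — it will not group wells by
primer to save robot tips, nor schedule across instruments. Spreadsheet
import accepts CSV and XLSX but the manual sheet is emitted as
SpreadsheetML rather than native XLSX. And scoring is text-only by
design: a facility wanting Phred-aware trimming should plug a
base-caller in upstream and feed the resulting text through unchanged.
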