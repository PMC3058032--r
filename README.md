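# seqfab

A headless workflow engine for Sanger DNA-sequencing core facilities,
written in R. It covers the full service loop such a facility runs every
day: customers submit orders of templates and primers, the facility pools
them onto 96-well plates, liquid-handling robots and the capillary
sequencer are driven from generated worklists, the sequencer's output is
ingested, scored and trimmed, and results flow back to each customer —
with group-based access control the whole way. Everything is scriptable:
the package's functions (and a thin `seqfab` command-line front end) do
what the original facility systems did through a web UI.

It is aimed at facility operators and at anyone building or testing LIMS
tooling for low-throughput sequencing who needs a complete, deterministic,
self-contained reference pipeline.

## The model in brief

**Lifecycle.** Work moves through four stages, and only forward:

```
NEW ORDER  →  PLANNED RUN  →  AWAITING-RESULTS RUN  →  COMPLETED RUN
                  │
                  └── plan abandoned → orders revert to NEW
```

An order is frozen (`LOCKED`) the moment a plan places it on a plate and
becomes editable again only if that plan is abandoned. A run is one
96-well plate (8 rows × 12 columns), possibly holding samples from
several customers' orders plus reaction/instrument control wells.

**Dosing.** Each well receives template, primer, pre-made reaction mix
and water summing to the configured reaction volume *V* (default 10 µL).
In *variable* mode the template volume delivers a target mass at the
sample's concentration,

    v_template = m_target / c_template ,   v_primer = a_target / c_primer ,

rounded half-up to the pipetting increment (0.1 µL) and clamped into
[increment, V − v_mix]; water closes the balance. *Fixed* mode uses
constant volumes for a time-optimised robot program.

**Scoring.** For a read *s* with requested length *L*: the readable
length *r* is the length after trimming the maximal runs of ambiguous
letters (any IUPAC code outside A/C/G/T, case-insensitive; U counts as
unambiguous) from both ends. Then

    %Read = 100 · r / L       (not capped at 100)
    %Amb  = 100 · (# ambiguous letters) / |s|     (on the raw read)

and the status is **OK** iff *r* ≥ *L*, else **FAILED** (**IN_PROCESS**
until something is uploaded). Failed samples can be tagged `Rj`
(re-inject) or `Rp` (re-process) and resubmitted as a fresh order in one
call. Per-order upload progress is summarised as a traffic light: green =
all results uploaded, yellow = some, red = none.

## Worked example

```r
library(seqfab)
store <- new_store(default_config())
add_principal(store, "ana", "Ana", groups = "membrane-lab", role = "USER")
add_principal(store, "op1", "Operator", groups = "facility", role = "OPERATOR")

res <- create_order(store, "ana", list(
  list(template_name = "pET28-insulin", primer_name = "T7",
       primer_source = "facility", template_concentration = 50,
       template_volume_supplied = 15, requested_read_length = 700,
       sequencing_type = "standard"),
  list(template_name = "pET28-insulin", primer_name = "revB",
       primer_source = "customer", template_concentration = 50,
       template_volume_supplied = 15, primer_concentration = 10,
       primer_volume_supplied = 20, requested_read_length = 700,
       sequencing_type = "standard")))
res$order$order_id
#> [1] "ORD-00001"
res$confirmation$templates
#>            name n_reactions min_volume_ul
#> 1 pET28-insulin           2             6
```

The confirmation tells Ana to hand in 6 µL of `pET28-insulin`: two
reactions of 2 µL each (100 ng at 50 ng/µL), times the 1.5 safety
factor, rounded up to the 0.5 µL supply increment. The facility-stock
`T7` primer is absent; her own `revB` is listed with 1 µL.

```r
run <- plan_run(store, res$order$order_id, mode = "VARIABLE")
cat(write_robot_sheet(store, run$run_name, "VARIABLE"))
#> well,template_name,primer_name,template_vol_ul,primer_vol_ul,mix_vol_ul,water_vol_ul
#> A1,pET28-insulin,T7,2.0,1.0,4.0,3.0
#> B1,pET28-insulin,revB,2.0,0.5,4.0,3.5
#> G12,R.Control,,1.0,1.0,4.0,4.0
#> H12,I.Control,,1.0,1.0,4.0,4.0

write_instrument_sheet(store, run$run_name)   # run -> AWAITING_RESULTS
```

After the sequencer finishes, its files (named by sample reference) are
uploaded as one ZIP; each sample is linked, scored and trimmed:

```r
rep <- ingest_results_zip(store, run$run_name, "A1_results.zip")
names(rep$matched)
#> [1] "S000001" "S000002"
for (ref in names(rep$matched)) {
  x <- store$results[[ref]]
  cat(sprintf("%s  %%read %.1f  %%amb %.1f  %s\n",
              ref, x$pct_read, x$pct_amb, x$status))
}
#> S000001  %read 108.6  %amb 1.3  OK
#> S000002  %read 68.6  %amb 0.0  FAILED
complete_run(store, run$run_name)
order_traffic_light(store, res$order$order_id)
#> [1] "GREEN"
cat(export_fasta(store, res$order$order_id, "op1", "trimmed"))
#> >S000001 pET28-insulin_T7
#> ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
#> ...
```

Sample 1 read 760 clean bases of the 700 requested (OK, 108.6 %); sample
2 trimmed to 480 (FAILED) and its files are hidden from Ana while the
operator can still see, tag and resubmit it. The whole pipeline, run on
synthetic data end to end, is one call: `run_demo(seed, dir)`.

A command-line front end wrapping the same functions ships at
`inst/cli/seqfab` (`seqfab --store store.json --as ana order create
--sheet samples.csv`, `seqfab run plan ...`, etc.).

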