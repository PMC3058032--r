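# Deterministic synthetic data: customer order sheets with configurable
# concentration distributions, and sequencer output archives with
# controllable read lengths and ambiguity structure. Everything is driven
# by one explicit seeded generator, so the same spec reproduces the same
# bytes; nothing touches the global RNG state of the session.

# An explicit RNG handle: holds its own .Random.seed and swaps it in and
# out around each draw, leaving the caller's RNG untouched.
make_rng <- function(seed) {
  rng <- new.env(parent = emptyenv())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  rng$state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  rng
}

with_rng <- function(rng, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Describe a synthetic workload
#'
#' Captures everything the generators draw from: how many orders with
#' how many samples, the concentration ranges customers submit, and the
#' read-quality profile of the emulated sequencer — probability a
#' reaction fails outright, how long a successful read is relative to the
#' request, the mean length of the unresolved (ambiguous) runs at either
#' end of a read, and the rate of interior ambiguous calls.
#'
#' @param seed Integer seed; the same spec is byte-reproducible.
#' @param n_orders Number of orders to generate.
#' @param samples_per_order Inclusive range, at most 96.
#' @param template_conc,primer_conc,template_vol,primer_vol Uniform
#'   ranges for submitted concentrations (ng/uL, pmol/uL) and volumes (uL).
#' @param fail_p Probability a sample's sequencing fails (read shorter
#'   than requested).
#' @param mean_read_fraction Mean successful read length as a fraction of
#'   the requested length (successful reads draw from +/- 0.15 around it;
#'   keep it >= 1.2 if every non-failed read should score OK).
#' @param terminal_amb_mean Mean (Poisson) length of the ambiguity run at
#'   each end of a read.
#' @param internal_amb_rate Per-base probability of an interior ambiguous
#'   call.
#' @return A `seqfab_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_orders = 3L,
                         samples_per_order = c(8L, 16L),
                         template_conc = c(20, 200), primer_conc = c(5, 50),
                         template_vol = c(10, 30), primer_vol = c(10, 30),
                         fail_p = 0.1, mean_read_fraction = 1.2,
                         terminal_amb_mean = 5, internal_amb_rate = 0.01) {
  stopifnot(fail_p >= 0, fail_p <= 1,
            internal_amb_rate >= 0, internal_amb_rate <= 1,
            samples_per_order[1] >= 1, samples_per_order[2] <= 96,
            terminal_amb_mean >= 0)
  structure(list(seed = as.integer(seed), n_orders = as.integer(n_orders),
                 samples_per_order = as.integer(samples_per_order),
                 template_conc = template_conc, primer_conc = primer_conc,
                 template_vol = template_vol, primer_vol = primer_vol,
                 fail_p = fail_p, mean_read_fraction = mean_read_fraction,
                 terminal_amb_mean = terminal_amb_mean,
                 internal_amb_rate = internal_amb_rate),
            class = "seqfab_fixture_spec")
}

# one synthetic sheet row; bad rows breach the template-concentration or
# minimum-volume limit so validate_sample() is guaranteed to object
draw_sheet_row <- function(spec, config, order_i, row_i, bad = FALSE) {
  facility <- config$facility_primers %||% c("T7", "M13F")
  use_facility <- stats::runif(1) < 0.5
  primer <- if (use_facility) sample(facility, 1L) else
    sprintf("primer_G%02d_%02d", order_i, sample.int(6L, 1L))
  st <- sample(names(config$sequencing_types), 1L,
               prob = c(0.8, rep(0.2 / max(1, length(config$sequencing_types) - 1L),
                                 length(config$sequencing_types) - 1L)))
  tc <- stats::runif(1, spec$template_conc[1], spec$template_conc[2])
  tv <- stats::runif(1, spec$template_vol[1], spec$template_vol[2])
  if (bad) {
    if (stats::runif(1) < 0.5) {
      tc <- config$limits$template_concentration$min * stats::runif(1, 0.1, 0.9)
    } else {
      tv <- config$limits$min_template_volume * stats::runif(1, 0.1, 0.9)
    }
  }
  list(template_name = sprintf("pCON%02d-insert%02d", order_i, row_i),
       primer_name = primer,
       primer_source = if (use_facility) "facility" else "customer",
       template_conc_ng_ul = round(tc, 1),
       template_vol_ul = round(tv, 1),
       primer_conc_pmol_ul = if (use_facility) "" else
         round(stats::runif(1, spec$primer_conc[1], spec$primer_conc[2]), 1),
       primer_vol_ul = if (use_facility) "" else
         round(stats::runif(1, spec$primer_vol[1], spec$primer_vol[2]), 1),
       read_length_bp = config$sequencing_types[[st]]$default_read_length,
       seq_type = st)
}

#' Generate synthetic order sheets and a user roster
#'
#' Writes one CSV sample sheet per order (valid against
#' [import_sample_sheet()]) plus a roster of one customer per order, each
#' in their own group, and one facility operator. With `error_fraction >
#' 0`, that fraction of rows (in expectation) deliberately breaches a
#' validation limit, for exercising rejection paths.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @param config Facility configuration the sheets must satisfy.
#' @param error_fraction Probability that a row violates the limits.
#' @return List with `sheets` (CSV paths, one per order) and `roster`
#'   (data frame user_id / display_name / group / role).
#' @export
generate_orders <- function(spec, dir, config = default_config(),
                            error_fraction = 0) {
  stopifnot(error_fraction >= 0, error_fraction <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- make_rng(spec$seed)
  sheets <- character(spec$n_orders)
  with_rng(rng, {
    for (oi in seq_len(spec$n_orders)) {
      choices <- seq(spec$samples_per_order[1], spec$samples_per_order[2])
      n <- choices[[sample.int(length(choices), 1L)]]  # safe for length 1
      bad <- stats::runif(n) < error_fraction
      rows <- lapply(seq_len(n), function(ri)
        draw_sheet_row(spec, config, oi, ri, bad = bad[ri]))
      tab <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
      names(tab) <- SHEET_COLUMNS
      path <- file.path(dir, sprintf("order_sheet_%02d.csv", oi))
      utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
      sheets[oi] <- path
    }
  })
  roster <- rbind(
    data.frame(user_id = sprintf("user%02d", seq_len(spec$n_orders)),
               display_name = sprintf("Customer %02d", seq_len(spec$n_orders)),
               group = sprintf("G%02d", seq_len(spec$n_orders)),
               role = "USER", stringsAsFactors = FALSE),
    data.frame(user_id = "op1", display_name = "Facility Operator",
               group = "FACILITY", role = "OPERATOR",
               stringsAsFactors = FALSE))
  utils::write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE,
                   quote = FALSE)
  list(sheets = sheets, roster = roster)
}

AMBIGUITY_CODES <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

draw_read <- function(spec, requested) {
  failed <- stats::runif(1) < spec$fail_p
  frac <- if (failed) stats::runif(1, 0, 0.5) else
    stats::runif(1, spec$mean_read_fraction - 0.15,
                 spec$mean_read_fraction + 0.15)
  core_len <- max(0L, as.integer(round(frac * requested)))
  core <- sample(c("A", "C", "G", "T"), core_len, replace = TRUE)
  if (spec$internal_amb_rate > 0 && core_len > 2L) {
    # interior only: ambiguity at the core boundary would change the
    # trimmed length and blur the intended failed fraction
    hit <- which(stats::runif(core_len) < spec$internal_amb_rate)
    hit <- hit[hit > 1L & hit < core_len]
    if (length(hit))
      core[hit] <- sample(AMBIGUITY_CODES, length(hit), replace = TRUE)
  }
  lead <- stats::rpois(1, spec$terminal_amb_mean)
  tail_ <- stats::rpois(1, spec$terminal_amb_mean)
  paste0(strrep("N", lead), paste(core, collapse = ""), strrep("N", tail_))
}

#' Generate a synthetic sequencer output archive for a run
#'
#' Emulates the per-sample file set the sequencer writes: for every
#' sample well of a run awaiting results, a `.seq` text file (the read,
#' drawn from the spec's quality profile) plus dummy `.ab1` and `.scf`
#' blobs, all named `<sample_ref>.<ext>` and packed into one ZIP. The
#' trace blobs carry the magic prefixes `FIXTURE-AB1` / `FIXTURE-SCF`:
#' they are opaque stand-ins, and tests can assert nothing ever parses
#' them. Samples listed in `omit_refs` get no files at all (to exercise
#' partial uploads). Byte-identical for the same spec and run.
#'
#' @param store A facility store.
#' @param run_name A run in state `AWAITING_RESULTS`.
#' @param spec A [fixture_spec()].
#' @param path Output ZIP path.
#' @param omit_refs Sample refs to leave out of the archive.
#' @return `path`, invisibly.
#' @export
generate_sequencer_output <- function(store, run_name, spec, path,
                                      omit_refs = character()) {
  run <- get_run(store, run_name)
  if (run$state != "AWAITING_RESULTS")
    stop_seqfab(sprintf(
      "run %s is %s; the sequencer only processes AWAITING_RESULTS runs",
      run_name, run$state), "seqfab_state_error")
  refs <- setdiff(run_sample_refs(run), omit_refs)
  rng <- make_rng(spec$seed + 7919L)  # distinct stream from the order sheets
  members <- list()
  with_rng(rng, {
    for (ref in refs) {
      s <- get_sample(store, ref)
      read <- draw_read(spec, s$requested_read_length)
      members[[paste0(ref, ".seq")]] <- charToRaw(paste0(read, "\n"))
      members[[paste0(ref, ".ab1")]] <- c(
        charToRaw(paste0("FIXTURE-AB1:", ref, ":")),
        as.raw(sample(0:255, 64L, replace = TRUE)))
      members[[paste0(ref, ".scf")]] <- c(
        charToRaw(paste0("FIXTURE-SCF:", ref, ":")),
        as.raw(sample(0:255, 64L, replace = TRUE)))
    }
  })
  write_zip_archive(members, path)
}

#' Run the whole pipeline end to end on synthetic data
#'
#' The demonstration workflow, driven entirely by one seed: generate
#' order sheets and a roster, register the principals, submit every
#' sheet as an order, plan the runs (variable dosing), export the robot
#' worklist and the instrument set-up sheet for each run, generate and
#' ingest synthetic sequencer output, complete the runs, and export the
#' plain FASTA, trimmed FASTA and results archive for every order. All
#' artefacts land in `dir`. Because every byte of every export is a pure
#' function of the seed, two invocations with the same seed produce
#' identical files — which is how the pipeline's determinism is tested.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param spec Optional [fixture_spec()] (defaults to `fixture_spec(seed)`).
#' @return List with the `store`, the fixture `spec`, `run_names`,
#'   `order_ids`, and `exports` (character vector of file paths).
#' @export
run_demo <- function(seed, dir, spec = NULL) {
  spec <- spec %||% fixture_spec(seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- default_config()
  store <- new_store(config)
  fx <- generate_orders(spec, file.path(dir, "orders"), config)
  for (i in seq_len(nrow(fx$roster))) {
    r <- fx$roster[i, ]
    add_principal(store, r$user_id, r$display_name, r$group, r$role)
  }
  order_ids <- character()
  for (i in seq_along(fx$sheets)) {
    records <- import_sample_sheet(fx$sheets[[i]], config)
    created <- create_order(store, fx$roster$user_id[[i]], records)
    order_ids <- c(order_ids, created$order$order_id)
  }
  runs <- plan_runs(store, order_ids, mode = "VARIABLE")
  exports <- character()
  for (run in runs) {
    rn <- run$run_name
    p_robot <- file.path(dir, paste0(rn, "_robot_variable.csv"))
    write_robot_sheet(store, rn, "VARIABLE", path = p_robot)
    p_instr <- file.path(dir, paste0(rn, "_instrument.csv"))
    write_instrument_sheet(store, rn, path = p_instr)  # -> AWAITING_RESULTS
    p_zip <- file.path(dir, paste0(rn, "_sequencer.zip"))
    generate_sequencer_output(store, rn, spec, p_zip)
    ingest_results_zip(store, rn, p_zip)
    complete_run(store, rn)
    exports <- c(exports, p_robot, p_instr, p_zip)
  }
  for (oid in order_ids) {
    p_fa <- file.path(dir, paste0(oid, ".fasta"))
    export_fasta(store, oid, "op1", "plain", path = p_fa)
    p_tr <- file.path(dir, paste0(oid, "_trimmed.fasta"))
    export_fasta(store, oid, "op1", "trimmed", path = p_tr)
    p_ar <- file.path(dir, paste0(oid, "_archive.zip"))
    export_archive(store, oid, "op1", p_ar)
    exports <- c(exports, p_fa, p_tr, p_ar)
  }
  list(store = store, spec = spec, run_names = vapply(runs, `[[`,
                                                      character(1), "run_name"),
       order_ids = order_ids, exports = exports)
}
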