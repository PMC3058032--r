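# Domain types and the order/run state machines.
#
# The processing lifecycle has exactly four stages, mirroring how a
# sequencing facility operator works through a plate:
#
#   NEW_ORDER -> PLANNED_RUN -> AWAITING_RESULTS_RUN -> COMPLETED_RUN
#
# Orders carry their own state (NEW / LOCKED / COMPLETED): an order is
# LOCKED the moment it is placed on a planned run and reverts to NEW only
# if that plan is abandoned. Runs move strictly forward once their
# instrument set-up sheet has been exported.

ORDER_STATES <- c("NEW", "LOCKED", "COMPLETED")
RUN_STATES <- c("PLANNED", "AWAITING_RESULTS", "COMPLETED")

#' The four-stage processing lifecycle
#'
#' `lifecycle_stages()` returns the four stages a piece of work moves
#' through, from the customer's new order to the completed run.
#' `lifecycle_events()` returns every event the state machine knows, and
#' `lifecycle_transition()` resolves a (stage, event) pair to the next
#' stage, or `NA` when the event is illegal in that stage. Every pair
#' resolves to exactly one of the two: there are no silent no-ops.
#'
#' @param stage One of `lifecycle_stages()`.
#' @param event One of `lifecycle_events()`.
#' @return `lifecycle_transition()`: the successor stage, or `NA_character_`
#'   for an illegal (stage, event) pair.
#' @export
#' @examples
#' lifecycle_transition("PLANNED_RUN", "setup_sheet_exported")
lifecycle_stages <- function() {
  c("NEW_ORDER", "PLANNED_RUN", "AWAITING_RESULTS_RUN", "COMPLETED_RUN")
}

#' @rdname lifecycle_stages
#' @export
lifecycle_events <- function() {
  c("run_planned", "plan_abandoned", "setup_sheet_exported", "results_completed")
}

#' @rdname lifecycle_stages
#' @export
lifecycle_transition <- function(stage, event) {
  stopifnot(stage %in% lifecycle_stages(), event %in% lifecycle_events())
  switch(paste(stage, event, sep = "+"),
    "NEW_ORDER+run_planned"                      = "PLANNED_RUN",
    "PLANNED_RUN+plan_abandoned"                 = "NEW_ORDER",
    "PLANNED_RUN+setup_sheet_exported"           = "AWAITING_RESULTS_RUN",
    "AWAITING_RESULTS_RUN+results_completed"     = "COMPLETED_RUN",
    NA_character_
  )
}

#' Mint a run name from a letter series and counter
#'
#' Runs are named by a single uppercase series letter followed by a plain
#' decimal counter, e.g. `"A726"`. The counter is persisted per series by
#' the store and never reused, so abandoned run names are retired forever.
#'
#' @param series Single uppercase letter.
#' @param counter Non-negative integer.
#' @return The run name token.
#' @export
#' @examples
#' next_run_name("A", 726)
next_run_name <- function(series, counter) {
  if (!is.character(series) || length(series) != 1L || !grepl("^[A-Z]$", series))
    stop_seqfab("run series must be a single uppercase letter",
                "seqfab_identifier_error")
  counter <- as.integer(counter)
  if (is.na(counter) || counter < 0L)
    stop_seqfab("run counter must be a non-negative integer",
                "seqfab_identifier_error")
  paste0(series, counter)
}

# ---- entity constructors -------------------------------------------------

new_sample <- function(sample_ref, template_name, primer_name, primer_source,
                       template_concentration, template_volume_supplied,
                       primer_concentration, primer_volume_supplied,
                       requested_read_length, sequencing_type,
                       resubmitted_from = NULL) {
  structure(list(
    sample_ref = sample_ref,
    template_name = template_name,
    primer_name = primer_name,
    primer_source = primer_source,
    template_concentration = template_concentration,
    template_volume_supplied = template_volume_supplied,
    primer_concentration = primer_concentration,
    primer_volume_supplied = primer_volume_supplied,
    requested_read_length = requested_read_length,
    sequencing_type = sequencing_type,
    resubmitted_from = resubmitted_from
  ), class = "seqfab_sample")
}

new_order <- function(order_id, owner, group, account, samples) {
  stopifnot(length(samples) >= 1L)
  names(samples) <- vapply(samples, `[[`, character(1), "sample_ref")
  structure(list(
    order_id = order_id,
    owner = owner,
    group = group,
    account = account,
    samples = samples,
    state = "NEW",
    created_at = utc_now()
  ), class = "seqfab_order")
}

new_well_recipe <- function(template_volume, primer_volume, mix_volume,
                            water_volume) {
  r <- structure(list(
    template_volume = template_volume,
    primer_volume = primer_volume,
    mix_volume = mix_volume,
    water_volume = water_volume
  ), class = "seqfab_well_recipe")
  stopifnot(all(unlist(r) >= -1e-9))
  r
}

recipe_total <- function(recipe) {
  recipe$template_volume + recipe$primer_volume +
    recipe$mix_volume + recipe$water_volume
}

WELL_KINDS <- c("SAMPLE", "REACTION_CONTROL", "INSTRUMENT_CONTROL")
CONTROL_LABELS <- c(REACTION_CONTROL = "R.Control",
                    INSTRUMENT_CONTROL = "I.Control")

new_well_content <- function(kind, recipe, sample_ref = NULL) {
  kind <- match.arg(kind, WELL_KINDS)
  if ((kind == "SAMPLE") != !is.null(sample_ref))
    stop_seqfab("sample_ref present iff the well holds a sample",
                "seqfab_model_error")
  structure(list(kind = kind, sample_ref = sample_ref, recipe = recipe),
            class = "seqfab_well_content")
}

new_planned_run <- function(run_name, wells, order_ids, mode,
                            rows = 8L, cols = 12L) {
  if (length(wells) > rows * cols)
    stop_seqfab("more wells than plate positions", "seqfab_model_error")
  if (anyDuplicated(names(wells)))
    stop_seqfab("duplicate well position", "seqfab_model_error")
  refs <- unlist(lapply(wells, function(w) w$sample_ref))
  if (anyDuplicated(refs))
    stop_seqfab("a sample occupies more than one well", "seqfab_model_error")
  structure(list(
    run_name = run_name,
    state = "PLANNED",
    wells = wells,
    order_ids = order_ids,
    mode = mode,
    plate_rows = rows,
    plate_cols = cols,
    created_at = utc_now()
  ), class = "seqfab_planned_run")
}

run_sample_refs <- function(run) {
  unlist(lapply(run$wells, function(w) w$sample_ref), use.names = FALSE) %||%
    character()
}

#' Advance a run through its state machine
#'
#' Applies one lifecycle event to a planned run. Only the forward path
#' `PLANNED -> AWAITING_RESULTS -> COMPLETED` exists, plus abandonment of
#' a still-`PLANNED` run (handled at the store level, where the member
#' orders revert to `NEW`). Any other (state, event) pair is rejected.
#'
#' @param run A planned run.
#' @param event One of `"setup_sheet_exported"`, `"results_completed"`,
#'   `"abandoned"`.
#' @return The run with its state advanced.
#' @export
run_transition <- function(run, event) {
  event <- match.arg(event,
                     c("setup_sheet_exported", "results_completed", "abandoned"))
  new_state <- switch(paste(run$state, event, sep = "+"),
    "PLANNED+setup_sheet_exported"        = "AWAITING_RESULTS",
    "AWAITING_RESULTS+results_completed"  = "COMPLETED",
    "PLANNED+abandoned"                   = "ABANDONED",
    stop_seqfab(sprintf("run %s: event '%s' is illegal in state %s",
                        run$run_name, event, run$state),
                "seqfab_state_error")
  )
  run$state <- new_state
  run
}

new_note <- function(author, text, visibility) {
  visibility <- match.arg(visibility, c("PRIVATE", "PUBLIC"))
  if (!nzchar(trimws(text)))
    stop_seqfab("note text must be non-empty", "seqfab_model_error")
  structure(list(author = author, created_at = utc_now(), text = text,
                 visibility = visibility), class = "seqfab_note")
}

RESULT_STATUSES <- c("OK", "FAILED", "IN_PROCESS")
SAMPLE_TAGS <- c("Rp", "Rj")

# A result starts IN_PROCESS with no uploaded data; pct_read / pct_amb stay
# undefined (NA) until something is ingested.
new_result <- function(sample_ref) {
  structure(list(
    sample_ref = sample_ref,
    sequence_text = NULL,
    attachments = list(),
    pct_read = NA_real_,
    pct_amb = NA_real_,
    status = "IN_PROCESS",
    manual_status = FALSE,
    uploaded = FALSE,
    tags = character(),
    notes = list()
  ), class = "seqfab_result")
}
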