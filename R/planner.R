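# Run planning: pool NEW orders into 96-well plate runs in FIFO order,
# assign wells along the configured traversal, dose each well, and lock
# the member orders.

#' Count samples and plates needed for a set of orders
#'
#' A run is one plate; each plate loses the configured number of control
#' wells, so the plate count is `ceiling(total / (96 - controls))`. Greedy
#' FIFO consolidation across orders achieves exactly this bound (capacity
#' is the only packing constraint), which is what keeps plates free of
#' empty wells.
#'
#' @param store A facility store.
#' @param order_ids Orders to pool; all must be in state `NEW`.
#' @param config Optional config override (defaults to the store's).
#' @return A list with `total_samples` and `plates_needed`.
#' @export
count_plates <- function(store, order_ids, config = NULL) {
  config <- config %||% store$config
  if (length(order_ids) == 0L)
    return(list(total_samples = 0L, plates_needed = 0L))
  orders <- lapply(order_ids, get_order, store = store)
  for (o in orders)
    if (o$state != "NEW")
      stop_seqfab(sprintf("order %s is not NEW", o$order_id),
                  "seqfab_state_error")
  total <- sum(vapply(orders, function(o) length(o$samples), integer(1)))
  list(total_samples = as.integer(total),
       plates_needed = as.integer(ceiling(total / usable_wells(config))))
}

#' Compute the liquid recipe for one well
#'
#' Every well receives four liquids summing to the configured total
#' reaction volume: template, primer, pre-made reaction mix (fixed
#' volume), and water to close the balance. In `FIXED` dosing mode the
#' template and primer volumes come verbatim from the configuration (the
#' fast path: every well identical, time-optimised robot program). In
#' `VARIABLE` mode the template volume delivers the configured target
#' mass at the sample's concentration (`mass / concentration`) and the
#' primer volume the target amount in pmol; both are rounded half-up to
#' the pipetting increment and clamped into `[increment, total - mix]`,
#' with a warning for each clamp. A facility-stock primer has no
#' customer-supplied concentration, so it is dosed at the fixed primer
#' volume in either mode. If the four liquids would overflow the well,
#' template then primer are reduced to fit, again with a warning.
#'
#' @param sample A sample record (list with at least
#'   `template_concentration`, `primer_concentration`, `primer_source`,
#'   `sequencing_type`).
#' @param config A `seqfab_config`.
#' @param mode `"FIXED"` or `"VARIABLE"`.
#' @return A list with `recipe` (a `seqfab_well_recipe`) and `warnings`
#'   (character vector, possibly empty).
#' @export
#' @examples
#' cfg <- default_config()
#' s <- list(template_name = "pUC19", primer_name = "M13F",
#'           primer_source = "facility", template_concentration = 50,
#'           primer_concentration = NA, sequencing_type = "standard")
#' compute_well_recipe(s, cfg, "VARIABLE")$recipe
compute_well_recipe <- function(sample, config, mode = c("FIXED", "VARIABLE")) {
  mode <- match.arg(mode)
  ch <- config$chemistry
  total <- ch$total_reaction_volume
  mix <- ch$mix_volume
  inc <- ch$pipetting_increment
  warnings <- character()
  who <- sample$sample_ref %||% sample$template_name %||% "well"

  if (mode == "FIXED") {
    tv <- ch$fixed_template_volume
    pv <- ch$fixed_primer_volume
  } else {
    conc <- sample$template_concentration
    if (is.null(conc) || is.na(conc) || conc <= 0)
      stop_seqfab(sprintf("%s: cannot dose zero-concentration template", who),
                  "seqfab_planning_error")
    mass <- target_template_mass(config, sample$sequencing_type %||% "standard")
    tv <- round_to_increment(mass / conc, inc)
    hi <- total - mix
    if (tv < inc) {
      warnings <- c(warnings, sprintf(
        "%s: template volume %.3f uL below one increment, raised to %.1f",
        who, mass / conc, inc))
      tv <- inc
    } else if (tv > hi) {
      warnings <- c(warnings, sprintf(
        "%s: template volume %.1f uL exceeds %.1f uL available, clamped",
        who, tv, hi))
      tv <- round(hi, 6)
    }
    if (identical(sample$primer_source, "customer") &&
        !is.null(sample$primer_concentration) &&
        !is.na(sample$primer_concentration) &&
        sample$primer_concentration > 0) {
      pv <- round_to_increment(
        ch$target_primer_amount / sample$primer_concentration, inc)
      if (pv < inc) {
        warnings <- c(warnings, sprintf(
          "%s: primer volume below one increment, raised to %.1f", who, inc))
        pv <- inc
      } else if (pv > hi) {
        warnings <- c(warnings, sprintf(
          "%s: primer volume %.1f uL exceeds %.1f uL available, clamped",
          who, pv, hi))
        pv <- round(hi, 6)
      }
    } else {
      pv <- ch$fixed_primer_volume  # facility stock: no concentration known
    }
  }

  water <- round(total - tv - pv - mix, 6)
  if (water < -1e-9) {
    # overflow: shrink template first, then primer, keeping >= 1 increment
    give <- -water
    t_cut <- min(give, max(0, tv - inc))
    tv <- round(tv - t_cut, 6)
    give <- round(give - t_cut, 6)
    if (give > 1e-9) {
      p_cut <- min(give, max(0, pv - inc))
      pv <- round(pv - p_cut, 6)
      give <- round(give - p_cut, 6)
    }
    water <- round(total - tv - pv - mix, 6)
    warnings <- c(warnings, sprintf(
      "%s: liquids exceeded the %.1f uL reaction volume; template/primer reduced to fit",
      who, total))
  }
  if (water < 0) water <- 0
  list(recipe = new_well_recipe(tv, pv, mix, water), warnings = warnings)
}

control_wells_for <- function(config, traversal_positions, n_samples) {
  n_rc <- config$plate$reaction_controls %||% 0L
  n_ic <- config$plate$instrument_controls %||% 0L
  n <- n_rc + n_ic
  if (n == 0L) return(character())
  placement <- config$plate$control_placement %||% "plate_tail"
  pos <- if (placement == "after_samples") {
    traversal_positions[n_samples + seq_len(n)]
  } else {
    utils::tail(traversal_positions, n)
  }
  stats::setNames(pos, c(rep("REACTION_CONTROL", n_rc),
                         rep("INSTRUMENT_CONTROL", n_ic)))
}

#' Plan one sequencing run from NEW orders
#'
#' Places the pooled samples on a plate along the configured traversal:
#' orders stay contiguous and in the given (FIFO) order, samples within
#' an order keep their listed order, and empty wells can only trail the
#' samples. Control wells (reaction and instrument controls) are placed
#' per the configured rule — by default in the last wells of the
#' traversal. Every well gets a dosing recipe ([compute_well_recipe()]) in
#' the chosen mode; controls are dosed at the fixed volumes. All member
#' orders transition `NEW -> LOCKED` and can no longer be amended.
#'
#' @param store A facility store.
#' @param order_ids Orders to place, in FIFO order; all `NEW`.
#' @param mode Dosing mode, `"FIXED"` or `"VARIABLE"`.
#' @param series Optional run-name series letter override.
#' @return The new `seqfab_planned_run` (also stored), with attribute
#'   `"warnings"` carrying any dosing warnings.
#' @export
plan_run <- function(store, order_ids, mode = c("FIXED", "VARIABLE"),
                     series = NULL) {
  mode <- match.arg(mode)
  config <- store$config
  orders <- lapply(order_ids, get_order, store = store)
  for (o in orders)
    if (o$state != "NEW")
      stop_seqfab(sprintf("order %s is not NEW", o$order_id),
                  "seqfab_state_error")
  samples <- unlist(lapply(orders, function(o) unname(o$samples)),
                    recursive = FALSE)
  n_controls <- controls_per_plate(config)
  cap <- plate_size(config)
  if (length(samples) + n_controls > cap)
    stop_seqfab(sprintf(
      "plate capacity exceeded: %d samples + %d controls = %d wells > %d (%d over)",
      length(samples), n_controls, length(samples) + n_controls, cap,
      length(samples) + n_controls - cap),
      "seqfab_planning_error")
  trav <- well_positions(config$plate$traversal %||% "column",
                         config$plate$rows, config$plate$cols)
  ctrl <- control_wells_for(config, trav, length(samples))
  sample_pos <- setdiff(trav, ctrl)[seq_along(samples)]

  warnings <- character()
  wells <- list()
  for (i in seq_along(samples)) {
    wr <- compute_well_recipe(samples[[i]], config, mode)
    warnings <- c(warnings, wr$warnings)
    wells[[sample_pos[[i]]]] <-
      new_well_content("SAMPLE", wr$recipe, samples[[i]]$sample_ref)
  }
  ctrl_recipe <- new_well_recipe(
    config$chemistry$fixed_template_volume, config$chemistry$fixed_primer_volume,
    config$chemistry$mix_volume,
    round(config$chemistry$total_reaction_volume -
            config$chemistry$fixed_template_volume -
            config$chemistry$fixed_primer_volume -
            config$chemistry$mix_volume, 6))
  for (i in seq_along(ctrl)) {
    wells[[ctrl[[i]]]] <- new_well_content(names(ctrl)[[i]], ctrl_recipe)
  }
  run_name <- mint_run_name(store, series)
  run <- new_planned_run(run_name, wells,
                         vapply(orders, `[[`, character(1), "order_id"),
                         mode, config$plate$rows, config$plate$cols)
  store$runs[[run_name]] <- run
  for (o in orders) {
    o$state <- "LOCKED"
    store$orders[[o$order_id]] <- o
  }
  append_event(store, "run_planned", "operator",
               list(run_name = run_name, order_ids = run$order_ids,
                    n_samples = length(samples)))
  attr(run, "warnings") <- warnings
  run
}

#' Plan as many runs as the queue needs
#'
#' Convenience wrapper over [plan_run()]: fills plates greedily along the
#' FIFO order queue. By default an order may straddle a plate boundary
#' (the facility pools "samples, possibly from different customers'
#' orders" to avoid empty wells); with `split_orders = FALSE` an order
#' that does not fit the current plate starts the next one. When
#' splitting is allowed the number of runs equals
#' `count_plates()$plates_needed`, the provable minimum; only the final
#' run can contain empty wells.
#'
#' An order split across runs is locked once, when its first chunk is
#' placed; chunk membership is recorded per run.
#'
#' @inheritParams plan_run
#' @param split_orders Allow one order's samples to span two plates.
#' @return A list of `seqfab_planned_run`s.
#' @export
plan_runs <- function(store, order_ids, mode = c("FIXED", "VARIABLE"),
                      split_orders = TRUE, series = NULL) {
  mode <- match.arg(mode)
  config <- store$config
  usable <- usable_wells(config)
  orders <- lapply(order_ids, get_order, store = store)
  for (o in orders)
    if (o$state != "NEW")
      stop_seqfab(sprintf("order %s is not NEW", o$order_id),
                  "seqfab_state_error")
  # expand to (order_id, sample) units, then cut into plates
  units <- list()
  for (o in orders)
    for (s in o$samples)
      units[[length(units) + 1L]] <- list(order_id = o$order_id, sample = s)
  if (length(units) == 0L) return(list())

  chunks <- list()   # each: list of units for one plate
  if (split_orders) {
    idx <- split(seq_along(units),
                 ceiling(seq_along(units) / usable))
    chunks <- lapply(idx, function(ii) units[ii])
  } else {
    cur <- list(); cur_n <- 0L
    sizes <- vapply(orders, function(o) length(o$samples), integer(1))
    for (k in seq_along(orders)) {
      if (sizes[[k]] > usable)
        stop_seqfab(sprintf(
          "order %s (%d samples) cannot fit one plate without splitting",
          orders[[k]]$order_id, sizes[[k]]), "seqfab_planning_error")
      if (cur_n + sizes[[k]] > usable) {
        chunks[[length(chunks) + 1L]] <- cur
        cur <- list(); cur_n <- 0L
      }
      for (s in orders[[k]]$samples)
        cur[[length(cur) + 1L]] <- list(order_id = orders[[k]]$order_id,
                                        sample = s)
      cur_n <- cur_n + sizes[[k]]
    }
    if (cur_n > 0L) chunks[[length(chunks) + 1L]] <- cur
  }

  runs <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    chunk <- chunks[[ci]]
    trav <- well_positions(config$plate$traversal %||% "column",
                           config$plate$rows, config$plate$cols)
    ctrl <- control_wells_for(config, trav, length(chunk))
    sample_pos <- setdiff(trav, ctrl)[seq_along(chunk)]
    wells <- list()
    for (i in seq_along(chunk)) {
      wr <- compute_well_recipe(chunk[[i]]$sample, config, mode)
      wells[[sample_pos[[i]]]] <-
        new_well_content("SAMPLE", wr$recipe, chunk[[i]]$sample$sample_ref)
    }
    ctrl_recipe <- new_well_recipe(
      config$chemistry$fixed_template_volume,
      config$chemistry$fixed_primer_volume, config$chemistry$mix_volume,
      round(config$chemistry$total_reaction_volume -
              config$chemistry$fixed_template_volume -
              config$chemistry$fixed_primer_volume -
              config$chemistry$mix_volume, 6))
    for (i in seq_along(ctrl))
      wells[[ctrl[[i]]]] <- new_well_content(names(ctrl)[[i]], ctrl_recipe)
    run_name <- mint_run_name(store, series)
    oid <- unique(vapply(chunk, `[[`, character(1), "order_id"))
    run <- new_planned_run(run_name, wells, oid, mode,
                           config$plate$rows, config$plate$cols)
    store$runs[[run_name]] <- run
    runs[[ci]] <- run
    append_event(store, "run_planned", "operator",
                 list(run_name = run_name, order_ids = oid,
                      n_samples = length(chunk)))
  }
  for (o in orders) {
    o$state <- "LOCKED"
    store$orders[[o$order_id]] <- o
  }
  runs
}

#' Abandon a planned run
#'
#' A run that is still only a plan can be scrapped: the run is deleted,
#' its name retired forever (the per-series counter never rewinds), and
#' every member order reverts to `NEW`, becoming amendable again. Once
#' the instrument set-up sheet has been exported the run is past
#' `PLANNED` and can no longer be abandoned.
#'
#' @param store A facility store.
#' @param run_name The planned run to abandon.
#' @return Invisibly, the ids of the unlocked orders.
#' @export
abandon_plan <- function(store, run_name) {
  run <- get_run(store, run_name)
  run_transition(run, "abandoned")  # validates state, errors past PLANNED
  member_orders <- run$order_ids
  store$runs[[run_name]] <- NULL
  store$retired_runs <- c(store$retired_runs, run_name)
  for (oid in member_orders) {
    # an order split across runs stays LOCKED while another live run holds it
    still_held <- any(vapply(store$runs, function(r)
      oid %in% r$order_ids, logical(1)))
    if (!still_held) {
      o <- store$orders[[oid]]
      o$state <- "NEW"
      store$orders[[oid]] <- o
    }
  }
  append_event(store, "plan_abandoned", "operator",
               list(run_name = run_name, order_ids = member_orders))
  invisible(member_orders)
}
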