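# Order submission: validate sample records against the facility limits,
# import sample sheets (CSV or XLSX), create/amend orders, and compute the
# confirmation telling the customer how much of each template and primer
# to hand in with the physical samples.

SHEET_COLUMNS <- c("template_name", "primer_name", "primer_source",
                   "template_conc_ng_ul", "template_vol_ul",
                   "primer_conc_pmol_ul", "primer_vol_ul",
                   "read_length_bp", "seq_type")

# sheet column -> internal sample field
SHEET_FIELD_MAP <- c(
  template_conc_ng_ul = "template_concentration",
  template_vol_ul = "template_volume_supplied",
  primer_conc_pmol_ul = "primer_concentration",
  primer_vol_ul = "primer_volume_supplied",
  read_length_bp = "requested_read_length",
  seq_type = "sequencing_type"
)

#' Validate one sample record against the facility limits
#'
#' Checks that template/primer concentrations and supplied volumes lie
#' within the configured limits, that the sequencing type is known, and
#' that the requested read length is positive (and below the configured
#' ceiling). Concentration/volume checks for the primer are skipped when
#' the primer comes from facility stock (the customer supplies nothing).
#' Violations are returned as values, one row per breached field, never
#' raised as errors; an empty result means the record is valid.
#'
#' @param record A named list with fields `template_name`, `primer_name`,
#'   `primer_source` ("customer" or "facility"), `template_concentration`
#'   (ng/uL), `template_volume_supplied` (uL), `primer_concentration`
#'   (pmol/uL), `primer_volume_supplied` (uL), `requested_read_length`
#'   (bases; defaulted from the sequencing type if missing),
#'   `sequencing_type`.
#' @param config A `seqfab_config`; its `limits` section is used.
#' @return A data frame with columns `field`, `value`, `constraint`,
#'   `message`; zero rows iff valid.
#' @export
#' @examples
#' cfg <- default_config()
#' rec <- list(template_name = "pUC19", primer_name = "M13F",
#'             primer_source = "facility", template_concentration = 80,
#'             template_volume_supplied = 15, primer_concentration = NA,
#'             primer_volume_supplied = NA, requested_read_length = 700,
#'             sequencing_type = "standard")
#' validate_sample(rec, cfg)
validate_sample <- function(record, config) {
  lim <- config$limits
  v <- list()
  bad <- function(field, value, constraint) {
    v[[length(v) + 1L]] <<- data.frame(
      field = field,
      value = if (is.null(value) || length(value) == 0L) NA_character_ else
        as.character(value),
      constraint = constraint,
      message = sprintf("%s: %s (got %s)", field, constraint,
                        if (is.null(value) || length(value) == 0L ||
                            all(is.na(value))) "nothing" else
                          as.character(value)),
      stringsAsFactors = FALSE)
  }
  missing_num <- function(x) is.null(x) || length(x) == 0L || is.na(x)
  missing_chr <- function(x) is.null(x) || length(x) == 0L || is.na(x) ||
    !nzchar(trimws(x))

  if (missing_chr(record$template_name))
    bad("template_name", record$template_name, "required, non-empty")
  if (missing_chr(record$primer_name))
    bad("primer_name", record$primer_name, "required, non-empty")

  src <- record$primer_source
  if (missing_chr(src)) {
    # infer from the facility-stock catalogue when the column is absent
    src <- if (!missing_chr(record$primer_name) &&
               is_facility_primer(config, record$primer_name))
      "facility" else "customer"
  }
  if (!src %in% c("customer", "facility"))
    bad("primer_source", record$primer_source, "one of customer|facility")

  tc <- record$template_concentration
  if (missing_num(tc)) {
    bad("template_concentration", tc, "required")
  } else if (tc < lim$template_concentration$min ||
             tc > lim$template_concentration$max) {
    bad("template_concentration", tc,
        sprintf("within [%g, %g] ng/uL", lim$template_concentration$min,
                lim$template_concentration$max))
  }
  tv <- record$template_volume_supplied
  if (missing_num(tv)) {
    bad("template_volume_supplied", tv, "required")
  } else if (tv < lim$min_template_volume) {
    bad("template_volume_supplied", tv,
        sprintf(">= %g uL", lim$min_template_volume))
  }

  if (identical(src, "customer")) {
    pc <- record$primer_concentration
    if (missing_num(pc)) {
      bad("primer_concentration", pc, "required for customer primers")
    } else if (pc < lim$primer_concentration$min ||
               pc > lim$primer_concentration$max) {
      bad("primer_concentration", pc,
          sprintf("within [%g, %g] pmol/uL", lim$primer_concentration$min,
                  lim$primer_concentration$max))
    }
    pv <- record$primer_volume_supplied
    if (missing_num(pv)) {
      bad("primer_volume_supplied", pv, "required for customer primers")
    } else if (pv < lim$min_primer_volume) {
      bad("primer_volume_supplied", pv,
          sprintf(">= %g uL", lim$min_primer_volume))
    }
  }

  st <- record$sequencing_type
  if (missing_chr(st)) {
    bad("sequencing_type", st, "required")
  } else if (!st %in% names(config$sequencing_types)) {
    bad("sequencing_type", st,
        sprintf("one of %s", paste(names(config$sequencing_types),
                                   collapse = "|")))
  }

  rl <- record$requested_read_length
  if (!missing_num(rl)) {
    if (rl <= 0) {
      bad("requested_read_length", rl, "> 0 bases")
    } else if (!is.null(lim$max_requested_read_length) &&
               rl > lim$max_requested_read_length) {
      bad("requested_read_length", rl,
          sprintf("<= %g bases", lim$max_requested_read_length))
    }
  }
  # a missing read length is filled from the type default, so not a violation
  if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), value = character(),
               constraint = character(), message = character(),
               stringsAsFactors = FALSE)
}

# Normalise one sheet row / raw record into the internal field set,
# filling primer_source and the per-type default read length.
normalise_record <- function(record, config) {
  rec <- record[intersect(names(record), c("template_name", "primer_name",
                                           "primer_source",
                                           names(SHEET_FIELD_MAP),
                                           unname(SHEET_FIELD_MAP)))]
  for (col in names(SHEET_FIELD_MAP)) {
    if (!is.null(record[[col]])) rec[[SHEET_FIELD_MAP[[col]]]] <- record[[col]]
  }
  num <- function(x) if (is.null(x) || all(is.na(x))) NA_real_ else
    suppressWarnings(as.numeric(x))
  chr <- function(x) if (is.null(x) || all(is.na(x))) NA_character_ else
    as.character(x)
  src <- chr(rec$primer_source)
  if (is.na(src) || !nzchar(trimws(src))) {
    src <- if (!is.na(chr(rec$primer_name)) &&
               is_facility_primer(config, chr(rec$primer_name)))
      "facility" else "customer"
  }
  out <- list(
    template_name = chr(rec$template_name),
    primer_name = chr(rec$primer_name),
    primer_source = src,
    template_concentration = num(rec$template_concentration),
    template_volume_supplied = num(rec$template_volume_supplied),
    primer_concentration = num(rec$primer_concentration),
    primer_volume_supplied = num(rec$primer_volume_supplied),
    requested_read_length = num(rec$requested_read_length),
    sequencing_type = chr(rec$sequencing_type)
  )
  if (is.na(out$requested_read_length) && !is.na(out$sequencing_type) &&
      out$sequencing_type %in% names(config$sequencing_types)) {
    out$requested_read_length <-
      config$sequencing_types[[out$sequencing_type]]$default_read_length
  }
  if (identical(out$primer_source, "facility")) {
    out$primer_concentration <- NA_real_
    out$primer_volume_supplied <- NA_real_
  }
  if (!is.null(record$resubmitted_from))
    out$resubmitted_from <- record$resubmitted_from
  out
}

#' Import a sample sheet (CSV or XLSX)
#'
#' Reads one-row-per-sample sheets with the documented column schema:
#' `template_name, primer_name, primer_source, template_conc_ng_ul,
#' template_vol_ul, primer_conc_pmol_ul, primer_vol_ul, read_length_bp,
#' seq_type`. The whole file is rejected on any problem — more than 96
#' data rows (one plate's worth), no rows, unknown or missing columns, or
#' any row failing [validate_sample()] — so the accepted order always
#' corresponds line-for-line to the file. Row numbers in error messages
#' are 1-based data-row numbers.
#'
#' @param path Path to a `.csv` or `.xlsx` sample sheet.
#' @param config A `seqfab_config`.
#' @return A list of validated, normalised sample records in file order.
#' @export
import_sample_sheet <- function(path, config) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  }
  unknown <- setdiff(names(tab), SHEET_COLUMNS)
  missing <- setdiff(SHEET_COLUMNS, names(tab))
  if (length(unknown) || length(missing))
    stop_seqfab(paste0(
      "sample sheet column schema mismatch",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")),
      if (length(unknown)) paste0("; unknown: ",
                                  paste(unknown, collapse = ", "))),
      "seqfab_sheet_error")
  if (nrow(tab) == 0L)
    stop_seqfab("sample sheet holds no samples", "seqfab_sheet_error")
  if (nrow(tab) > 96L)
    stop_seqfab(sprintf(
      "plate capacity exceeded: %d rows, a sheet may hold at most 96",
      nrow(tab)), "seqfab_sheet_error")
  records <- lapply(seq_len(nrow(tab)), function(i)
    normalise_record(as.list(tab[i, , drop = FALSE]), config))
  problems <- character()
  for (i in seq_along(records)) {
    viol <- validate_sample(records[[i]], config)
    if (nrow(viol))
      problems <- c(problems,
                    sprintf("row %d: %s", i,
                            paste(viol$message, collapse = "; ")))
  }
  if (length(problems))
    stop_seqfab(paste0("sample sheet rejected:\n",
                       paste(problems, collapse = "\n")),
                "seqfab_sheet_error", problems = problems)
  records
}

#' Create a sequencing order
#'
#' Validates every sample record (the whole order is rejected if any
#' record fails, with all violations listed), mints an order id and one
#' unique sample reference per sample, stores the order in state `NEW`,
#' computes the order confirmation, and appends an `order_confirmed`
#' event carrying it (the notification surrogate).
#'
#' @param store A facility store.
#' @param owner User id of the submitting customer.
#' @param group Group id the order belongs to (defaults to the owner's
#'   first group).
#' @param account Free-text charge account.
#' @param samples A list of sample records (see [validate_sample()]), or
#'   the result of [import_sample_sheet()].
#' @return A list with `order` and `confirmation`.
#' @export
create_order <- function(store, owner, samples, group = NULL, account = "") {
  p <- get_principal(store, owner)
  group <- group %||% p$groups[[1L]]
  if (length(samples) == 0L)
    stop_seqfab("empty order: at least one sample is required",
                "seqfab_submission_error")
  records <- lapply(samples, normalise_record, config = store$config)
  problems <- character()
  for (i in seq_along(records)) {
    viol <- validate_sample(records[[i]], store$config)
    if (nrow(viol))
      problems <- c(problems, sprintf("sample %d: %s", i,
                                      paste(viol$message, collapse = "; ")))
  }
  if (length(problems))
    stop_seqfab(paste0("order rejected:\n", paste(problems, collapse = "\n")),
                "seqfab_submission_error", problems = problems)
  order_id <- mint_order_id(store)
  samples <- lapply(records, function(rec) {
    new_sample(mint_sample_ref(store), rec$template_name, rec$primer_name,
               rec$primer_source, rec$template_concentration,
               rec$template_volume_supplied, rec$primer_concentration,
               rec$primer_volume_supplied, rec$requested_read_length,
               rec$sequencing_type,
               resubmitted_from = rec$resubmitted_from)
  })
  order <- new_order(order_id, owner, group, account, samples)
  store$orders[[order_id]] <- order
  for (s in samples) {
    store$sample_index[[s$sample_ref]] <- order_id
    store$results[[s$sample_ref]] <- new_result(s$sample_ref)
  }
  confirmation <- compute_confirmation(store, order_id)
  append_event(store, "order_confirmed", owner,
               list(order_id = order_id, confirmation = confirmation))
  list(order = store$orders[[order_id]], confirmation = confirmation)
}

#' Amend a NEW order
#'
#' Orders can be edited only while no operator has started processing
#' them, i.e. while they are still in state `NEW`; once a planned run
#' locks them the edit is rejected. Supported edits: add a sample
#' (validated, gets a fresh sample reference), remove a sample (never the
#' last one — an order holds at least one sample), or replace a sample's
#' user-entered fields in place (same reference).
#'
#' @param store A facility store.
#' @param order_id The order to edit.
#' @param action `"add"`, `"remove"` or `"replace"`.
#' @param sample_ref The target sample for remove/replace.
#' @param record A sample record for add/replace.
#' @return The amended order, invisibly.
#' @export
amend_order <- function(store, order_id,
                        action = c("add", "remove", "replace"),
                        sample_ref = NULL, record = NULL) {
  action <- match.arg(action)
  order <- get_order(store, order_id)
  if (order$state != "NEW")
    stop_seqfab(sprintf("order %s is locked by run planning", order_id),
                "seqfab_state_error")
  if (action %in% c("remove", "replace")) {
    if (is.null(sample_ref) || !sample_ref %in% names(order$samples))
      stop_seqfab("sample_ref does not belong to this order",
                  "seqfab_lookup_error")
  }
  if (action %in% c("add", "replace")) {
    rec <- normalise_record(record, store$config)
    viol <- validate_sample(rec, store$config)
    if (nrow(viol))
      stop_seqfab(paste0("amendment rejected: ",
                         paste(viol$message, collapse = "; ")),
                  "seqfab_submission_error")
  }
  if (action == "remove") {
    if (length(order$samples) == 1L)
      stop_seqfab("cannot remove the last sample: an order holds >= 1 sample",
                  "seqfab_submission_error")
    order$samples[[sample_ref]] <- NULL
    store$sample_index[[sample_ref]] <- NULL
    store$results[[sample_ref]] <- NULL
  } else if (action == "add") {
    s <- new_sample(mint_sample_ref(store), rec$template_name,
                    rec$primer_name, rec$primer_source,
                    rec$template_concentration, rec$template_volume_supplied,
                    rec$primer_concentration, rec$primer_volume_supplied,
                    rec$requested_read_length, rec$sequencing_type)
    order$samples[[s$sample_ref]] <- s
    store$sample_index[[s$sample_ref]] <- order_id
    store$results[[s$sample_ref]] <- new_result(s$sample_ref)
  } else {
    old <- order$samples[[sample_ref]]
    s <- new_sample(old$sample_ref, rec$template_name, rec$primer_name,
                    rec$primer_source, rec$template_concentration,
                    rec$template_volume_supplied, rec$primer_concentration,
                    rec$primer_volume_supplied, rec$requested_read_length,
                    rec$sequencing_type, resubmitted_from = old$resubmitted_from)
    order$samples[[sample_ref]] <- s
  }
  store$orders[[order_id]] <- order
  invisible(order)
}

#' Compute the order confirmation (minimal volumes to provide)
#'
#' For every distinct template in the order, the minimal volume the
#' customer must hand in is the sum over that template's reactions of the
#' per-reaction template volume (variable dosing at the sample's own
#' concentration), multiplied by the configured safety factor and rounded
#' up to the supply increment. Customer-supplied primers are treated the
#' same way via the per-reaction primer volume; facility-stock primers
#' are excluded (nothing to provide). Line items are sorted by name.
#'
#' @param store A facility store.
#' @param order_id The order.
#' @return A `seqfab_confirmation`: list with `order_id`, `templates` and
#'   `primers` data frames (`name`, `n_reactions`, `min_volume_ul`).
#' @export
compute_confirmation <- function(store, order_id) {
  order <- get_order(store, order_id)
  cfg <- store$config
  sf <- cfg$confirmation$safety_factor
  inc <- cfg$confirmation$supply_increment
  t_need <- list()  # name -> c(demand, n)
  p_need <- list()
  for (s in order$samples) {
    wr <- compute_well_recipe(s, cfg, mode = "VARIABLE")
    tn <- s$template_name
    t_prev <- t_need[[tn]] %||% c(0, 0)
    t_need[[tn]] <- c(t_prev[1] + wr$recipe$template_volume, t_prev[2] + 1)
    if (identical(s$primer_source, "customer")) {
      pn <- s$primer_name
      p_prev <- p_need[[pn]] %||% c(0, 0)
      p_need[[pn]] <- c(p_prev[1] + wr$recipe$primer_volume, p_prev[2] + 1)
    }
  }
  as_items <- function(need) {
    nm <- sort(names(need))
    data.frame(
      name = nm,
      n_reactions = vapply(need[nm], function(x) as.integer(x[2]), integer(1)),
      min_volume_ul = vapply(need[nm], function(x)
        ceiling_to_increment(x[1] * sf, inc), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(order_id = order_id,
                 templates = as_items(t_need),
                 primers = as_items(p_need)),
            class = "seqfab_confirmation")
}
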