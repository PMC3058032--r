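# The facility store: one mutable environment holding every order, run,
# result, principal, group policy and event, with identifier counters.
# Persistence is a single-file JSON snapshot of that state; the store layer
# is the only thing that touches it, so a server-backed implementation
# could be swapped in behind the same functions.
#
# Snapshot schema (top-level keys of the serialized list):
#   config      facility configuration in force when saved
#   principals  user_id -> {display_name, groups, role}
#   policies    group_id -> {other_group -> rights subset of VIEW/MODIFY/DELETE}
#   orders      order_id -> order (incl. samples, state, owner, group)
#   runs        run_name -> planned run (wells, state, mode)
#   results     sample_ref -> result (sequence, attachments, scores, notes)
#   sample_index sample_ref -> order_id
#   events      append-only event list
#   counters    order / sample counters, run counter per series
#   retired_runs run names that may never be reused

#' Create or reopen a facility store
#'
#' `new_store()` creates an empty in-memory store under a given facility
#' configuration. `store_save()` snapshots the full state to a single JSON
#' file and `store_open()` restores it; the round trip preserves every
#' entity, state, note, tag and event.
#'
#' @param config A `seqfab_config`, e.g. [default_config()].
#' @param store A facility store.
#' @param path File path for the JSON snapshot.
#' @return `new_store()` and `store_open()` return a store environment.
#' @export
#' @examples
#' store <- new_store(default_config())
#' f <- tempfile(fileext = ".json")
#' store_save(store, f)
#' reopened <- store_open(f)
new_store <- function(config = default_config()) {
  store <- new.env(parent = emptyenv())
  store$config <- config
  store$principals <- list()
  store$policies <- list()
  store$orders <- list()
  store$runs <- list()
  store$results <- list()
  store$sample_index <- list()
  store$events <- list()
  store$counters <- list(order = 0L, sample = 0L, run = list())
  store$retired_runs <- character()
  store$notifier <- NULL
  class(store) <- c("seqfab_store", "environment")
  store
}

STORE_FIELDS <- c("config", "principals", "policies", "orders", "runs",
                  "results", "sample_index", "events", "counters",
                  "retired_runs")

#' @rdname new_store
#' @export
store_save <- function(store, path) {
  snapshot <- mget(STORE_FIELDS, envir = store)
  # I(17): 17 *significant* digits, enough to reproduce any double exactly
  writeLines(jsonlite::serializeJSON(snapshot, digits = I(17)), path)
  invisible(path)
}

#' @rdname new_store
#' @export
store_open <- function(path) {
  snapshot <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  store <- new_store(snapshot$config)
  for (fld in STORE_FIELDS) assign(fld, snapshot[[fld]], envir = store)
  store
}

# ---- principals and group policy ----------------------------------------

#' Register users and group-to-group grants
#'
#' The facility has two roles: `USER` (a customer, sees only data their
#' groups may see) and `OPERATOR` (facility staff, sees everything).
#' Groups are opaque ids; `grant_access()` lets one group open its data to
#' another with any subset of VIEW/MODIFY/DELETE rights. Absence of a
#' grant means no access.
#'
#' @param store A facility store.
#' @param user_id,display_name Identity of the principal.
#' @param groups Character vector of group ids (at least one).
#' @param role `"USER"` or `"OPERATOR"`.
#' @param owner_group,other_group Granting and receiving group ids.
#' @param rights Subset of `c("VIEW", "MODIFY", "DELETE")`.
#' @return The principal record, invisibly.
#' @export
add_principal <- function(store, user_id, display_name = user_id,
                          groups, role = c("USER", "OPERATOR")) {
  role <- match.arg(role)
  if (length(groups) < 1L)
    stop_seqfab("a principal belongs to at least one group",
                "seqfab_model_error")
  p <- list(user_id = user_id, display_name = display_name,
            groups = as.character(groups), role = role)
  store$principals[[user_id]] <- p
  invisible(p)
}

#' @rdname add_principal
#' @export
grant_access <- function(store, owner_group, other_group,
                         rights = "VIEW") {
  stopifnot(all(rights %in% c("VIEW", "MODIFY", "DELETE")))
  pol <- store$policies[[owner_group]] %||% list()
  pol[[other_group]] <- unique(rights)
  store$policies[[owner_group]] <- pol
  invisible(NULL)
}

get_principal <- function(store, user_id) {
  p <- store$principals[[user_id]]
  if (is.null(p))
    stop_seqfab(sprintf("unknown principal '%s'", user_id),
                "seqfab_auth_error")
  p
}

is_operator <- function(store, user_id) {
  identical(get_principal(store, user_id)$role, "OPERATOR")
}

# Groups whose data this principal may VIEW: their own groups plus any
# group that granted VIEW to one of them.
viewable_groups <- function(store, principal) {
  own <- principal$groups
  granted <- names(Filter(function(pol) {
    any(vapply(own, function(g) "VIEW" %in% (pol[[g]] %||% character()),
               logical(1)))
  }, store$policies))
  unique(c(own, granted))
}

# ---- visibility ----------------------------------------------------------

#' Decide whether a principal may see an entity
#'
#' Operators see everything. Ordinary users see an order (or one of its
#' samples or notes) only when the order's group is one of their own or
#' one that granted them VIEW. Planned runs are operator-only machinery:
#' users are shielded from the processing details. Two refinements apply
#' on top of group scope: files of a FAILED sample are hidden from
#' non-operators, and PRIVATE notes are visible to operators only.
#'
#' @param store A facility store.
#' @param user_id The viewing principal.
#' @param entity An order, run, sample ref (character), or note.
#' @return `TRUE` or `FALSE`.
#' @export
visible <- function(store, user_id, entity) {
  p <- get_principal(store, user_id)
  if (p$role == "OPERATOR") return(TRUE)
  if (inherits(entity, "seqfab_planned_run")) return(FALSE)
  if (inherits(entity, "seqfab_note"))
    return(identical(entity$visibility, "PUBLIC"))
  order <- if (inherits(entity, "seqfab_order")) {
    entity
  } else if (is.character(entity) && length(entity) == 1L) {
    oid <- store$sample_index[[entity]]
    if (is.null(oid)) return(FALSE)
    store$orders[[oid]]
  } else if (inherits(entity, "seqfab_sample")) {
    oid <- store$sample_index[[entity$sample_ref]]
    if (is.null(oid)) return(FALSE)
    store$orders[[oid]]
  } else {
    return(FALSE)
  }
  order$group %in% viewable_groups(store, p)
}

# May this viewer see the FILES/sequence of this sample's result?
# Group visibility plus the FAILED-hiding rule.
result_files_visible <- function(store, user_id, sample_ref) {
  if (!visible(store, user_id, sample_ref)) return(FALSE)
  if (is_operator(store, user_id)) return(TRUE)
  res <- store$results[[sample_ref]]
  is.null(res) || !identical(res$status, "FAILED")
}

# Notes of a sample as a given viewer sees them.
visible_notes <- function(store, user_id, sample_ref) {
  res <- store$results[[sample_ref]]
  if (is.null(res)) return(list())
  if (is_operator(store, user_id)) return(res$notes)
  if (!visible(store, user_id, sample_ref)) return(list())
  Filter(function(n) identical(n$visibility, "PUBLIC"), res$notes)
}

# ---- event log -----------------------------------------------------------

append_event <- function(store, kind, actor, payload = list()) {
  ts <- utc_now()
  n <- length(store$events)
  if (n > 0L) {
    last <- store$events[[n]]$timestamp
    if (ts < last) ts <- last  # clock never runs backwards in the log
  }
  ev <- list(kind = kind, timestamp = ts, actor = actor, payload = payload)
  store$events[[n + 1L]] <- ev
  if (!is.null(store$notifier) &&
      kind %in% c("order_confirmed", "order_completed")) {
    store$notifier(ev)
  }
  invisible(ev)
}

#' Read the append-only event log
#'
#' Every notification-worthy action (order confirmation, volume
#' amendments, status overrides, order completion) appends an event. The
#' log is the delivery surrogate for customer notification: a notifier
#' hook (`store$notifier`, a function of one event) can forward
#' `order_confirmed` / `order_completed` events to any transport.
#'
#' @param store A facility store.
#' @param kind Optional filter on event kind.
#' @return A list of events, oldest first.
#' @export
event_log <- function(store, kind = NULL) {
  evs <- store$events
  if (!is.null(kind)) evs <- Filter(function(e) e$kind == kind, evs)
  evs
}

# ---- counters ------------------------------------------------------------

mint_order_id <- function(store) {
  store$counters$order <- store$counters$order + 1L
  sprintf("ORD-%05d", store$counters$order)
}

mint_sample_ref <- function(store) {
  store$counters$sample <- store$counters$sample + 1L
  sprintf("S%06d", store$counters$sample)
}

mint_run_name <- function(store, series = NULL) {
  series <- series %||% (store$config$run_series %||% "A")
  counter <- (store$counters$run[[series]] %||% 0L) + 1L
  store$counters$run[[series]] <- counter
  next_run_name(series, counter)
}

# ---- search and dashboards ----------------------------------------------

#' Search orders and samples
#'
#' A bare token is matched (case-insensitively, substring) against order
#' ids, sample references, template names, primer names and user names; a
#' named query like `c(template_name = "pUC19")` restricts to one field.
#' Results honour [visible()] for the searching principal, are ordered
#' newest first (ties broken by id) and paginated.
#'
#' @param store A facility store.
#' @param user_id The searching principal.
#' @param query A single bare token, or a named character vector of
#'   field = value pairs (fields: order_id, sample_ref, template_name,
#'   primer_name, user).
#' @param page 1-based page number.
#' @param page_size Rows per page (default from config, 20).
#' @return A data frame of matches (order_id, sample_ref, template_name,
#'   primer_name, owner, created_at) with attributes `page` and `total`.
#' @export
search_store <- function(store, user_id, query, page = 1L, page_size = NULL) {
  page_size <- page_size %||% (store$config$pagination %||% 20L)
  rows <- list()
  for (order in store$orders) {
    if (!visible(store, user_id, order)) next
    owner_name <- store$principals[[order$owner]]$display_name %||% order$owner
    for (s in order$samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        order_id = order$order_id, sample_ref = s$sample_ref,
        template_name = s$template_name, primer_name = s$primer_name,
        owner = order$owner, owner_name = owner_name,
        created_at = order$created_at, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(order_id = character(), sample_ref = character(),
               template_name = character(), primer_name = character(),
               owner = character(), owner_name = character(),
               created_at = as.POSIXct(character()))
  keep <- if (length(query) == 1L && is.null(names(query))) {
    pat <- tolower(query)
    Reduce(`|`, lapply(hits[c("order_id", "sample_ref", "template_name",
                              "primer_name", "owner", "owner_name")],
                       function(col) grepl(pat, tolower(col), fixed = TRUE)))
  } else {
    stopifnot(all(names(query) %in% c("order_id", "sample_ref",
                                      "template_name", "primer_name", "user")))
    cond <- rep(TRUE, nrow(hits))
    for (fld in names(query)) {
      col <- if (fld == "user") hits$owner else hits[[fld]]
      cond <- cond & (tolower(col) == tolower(query[[fld]]))
    }
    cond
  }
  hits <- hits[which(keep), , drop = FALSE]
  hits <- hits[order(hits$created_at, hits$order_id, hits$sample_ref,
                     decreasing = c(TRUE, FALSE, FALSE), method = "radix"), ,
               drop = FALSE]
  total <- nrow(hits)
  from <- (page - 1L) * page_size + 1L
  to <- min(total, page * page_size)
  pg <- if (from > total) hits[0, , drop = FALSE] else
    hits[from:to, , drop = FALSE]
  rownames(pg) <- NULL
  attr(pg, "page") <- page
  attr(pg, "total") <- total
  pg
}

#' Operator and user dashboards
#'
#' For an operator: how many orders/runs sit at each of the four
#' processing stages, and how long each pending (not yet completed) order
#' has been in the queue. For a user: their own orders from the last 7
#' days (the weekly widget) and from the last 30 days.
#'
#' @param store A facility store.
#' @param user_id The principal asking.
#' @param now Reference time for queue ages (defaults to the current UTC
#'   time; injectable for reproducible reports).
#' @return A list; for operators `stage_counts` (named integer vector over
#'   the four stages) and `queue_age` (data frame order_id / age_days),
#'   for users `last_week` and `last_month` data frames.
#' @export
dashboard <- function(store, user_id, now = utc_now()) {
  p <- get_principal(store, user_id)
  if (p$role == "OPERATOR") {
    new_orders <- sum(vapply(store$orders, function(o) o$state == "NEW",
                             logical(1)))
    run_states <- vapply(store$runs, `[[`, character(1), "state")
    counts <- c(
      NEW_ORDER = as.integer(new_orders),
      PLANNED_RUN = sum(run_states == "PLANNED"),
      AWAITING_RESULTS_RUN = sum(run_states == "AWAITING_RESULTS"),
      COMPLETED_RUN = sum(run_states == "COMPLETED")
    )
    pending <- Filter(function(o) o$state != "COMPLETED", store$orders)
    queue_age <- data.frame(
      order_id = vapply(pending, `[[`, character(1), "order_id"),
      age_days = vapply(pending, function(o)
        as.numeric(difftime(now, o$created_at, units = "days")), numeric(1)),
      stringsAsFactors = FALSE)
    rownames(queue_age) <- NULL
    list(stage_counts = counts, queue_age = queue_age)
  } else {
    own <- Filter(function(o) o$owner == p$user_id, store$orders)
    frame <- function(days) {
      keep <- Filter(function(o)
        as.numeric(difftime(now, o$created_at, units = "days")) <= days, own)
      data.frame(
        order_id = vapply(keep, `[[`, character(1), "order_id") %||% character(),
        state = vapply(keep, `[[`, character(1), "state") %||% character(),
        n_samples = vapply(keep, function(o) length(o$samples), integer(1)) %||%
          integer(),
        stringsAsFactors = FALSE)
    }
    list(last_week = frame(7), last_month = frame(30))
  }
}

get_order <- function(store, order_id) {
  o <- store$orders[[order_id]]
  if (is.null(o))
    stop_seqfab(sprintf("unknown order '%s'", order_id), "seqfab_lookup_error")
  o
}

get_run <- function(store, run_name) {
  r <- store$runs[[run_name]]
  if (is.null(r))
    stop_seqfab(sprintf("unknown run '%s'", run_name), "seqfab_lookup_error")
  r
}

get_sample <- function(store, sample_ref) {
  oid <- store$sample_index[[sample_ref]]
  if (is.null(oid))
    stop_seqfab(sprintf("unknown sample '%s'", sample_ref),
                "seqfab_lookup_error")
  store$orders[[oid]]$samples[[sample_ref]]
}

require_operator <- function(store, user_id, what) {
  if (!is_operator(store, user_id))
    stop_seqfab(sprintf("%s requires the OPERATOR role", what),
                "seqfab_auth_error")
  invisible(TRUE)
}
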