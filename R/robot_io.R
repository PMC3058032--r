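# Machine-readable artefacts: worklist CSVs for the liquid-handling
# robots, the spreadsheet for manual processing, the instrument set-up
# sheet for the sequencer, and re-absorption of operator-amended volume
# files.
#
# Conventions for all sheets: RFC 4180 CSV, CRLF line endings, header row
# always present, no quoting unless a field needs it, volumes printed with
# one decimal place, well positions "A1".."H12" (no zero padding).

ROBOT_DIALECTS <- c("FIXED_DECK_A", "VARIABLE", "DECK_B")

#' Supported robot worklist dialects
#'
#' The facility drives three liquid-handling deck layouts, each wanting
#' its own CSV shape:
#' * `FIXED_DECK_A` — the fast path: constant template/primer volumes on
#'   every row, sources addressed by deck slot
#'   (`well,template_slot,primer_slot,template_vol_ul,primer_vol_ul`).
#' * `VARIABLE` — per-well volumes
#'   (`well,template_name,primer_name,template_vol_ul,primer_vol_ul,mix_vol_ul,water_vol_ul`).
#' * `DECK_B` — the `VARIABLE` columns reordered for the second deck
#'   (`template_name,well,template_vol_ul,primer_name,primer_vol_ul,mix_vol_ul,water_vol_ul`).
#'
#' @return Character vector of the three dialect identifiers.
#' @export
robot_dialects <- function() ROBOT_DIALECTS

# Non-empty wells of a run in traversal order, as a list of
# (position, content) pairs.
run_rows <- function(store, run) {
  trav <- well_positions(store$config$plate$traversal %||% "column",
                         run$plate_rows, run$plate_cols)
  pos <- trav[trav %in% names(run$wells)]
  lapply(pos, function(p) list(position = p, content = run$wells[[p]]))
}

row_names_for <- function(store, content) {
  if (content$kind == "SAMPLE") {
    s <- get_sample(store, content$sample_ref)
    list(template = s$template_name, primer = s$primer_name)
  } else {
    list(template = CONTROL_LABELS[[content$kind]], primer = "")
  }
}

#' Write a robot worklist CSV for a planned run
#'
#' Emits the worklist in one of the three supported dialects (see
#' [robot_dialects()]), one row per non-empty well in traversal order.
#' `FIXED_DECK_A` is only valid for runs planned in `FIXED` dosing mode
#' (its deck program assumes identical volumes everywhere); deck slots
#' are assigned `T1..Tn` per source tube in well order and `P1..Pk` per
#' distinct primer in order of first appearance, with control wells
#' drawing from the reserved slot `P0`. Output is deterministic for a
#' given run, so re-exports are byte-identical.
#'
#' @param store A facility store.
#' @param run_name A run in state `PLANNED`.
#' @param dialect One of [robot_dialects()].
#' @param path Optional file to write to.
#' @return The CSV document as a single string (CRLF line endings),
#'   invisibly when `path` is given.
#' @export
write_robot_sheet <- function(store, run_name, dialect, path = NULL) {
  run <- get_run(store, run_name)
  if (!dialect %in% ROBOT_DIALECTS)
    stop_seqfab(sprintf("unknown robot dialect '%s' (supported: %s)",
                        dialect, paste(ROBOT_DIALECTS, collapse = ", ")),
                "seqfab_io_error")
  if (run$state != "PLANNED")
    stop_seqfab(sprintf("run %s is %s; worklists are exported from PLANNED",
                        run_name, run$state), "seqfab_state_error")
  rows <- run_rows(store, run)
  n_samples <- sum(vapply(rows, function(r) r$content$kind == "SAMPLE",
                          logical(1)))
  if (n_samples == 0L)
    stop_seqfab(sprintf("run %s has no sample wells", run_name),
                "seqfab_io_error")
  if (dialect == "FIXED_DECK_A" && run$mode != "FIXED")
    stop_seqfab("FIXED_DECK_A requires a run planned in FIXED dosing mode",
                "seqfab_io_error")
  dec <- store$config$robot$volume_decimals %||% 1L
  fv <- function(x) format_volume(x, dec)

  if (dialect == "FIXED_DECK_A") {
    primer_slots <- character()  # primer name -> slot
    out <- vector("list", length(rows))
    for (i in seq_along(rows)) {
      ct <- rows[[i]]$content
      nm <- row_names_for(store, ct)
      pslot <- if (ct$kind == "SAMPLE") {
        if (is.na(match(nm$primer, names(primer_slots))))
          primer_slots[nm$primer] <- paste0("P", length(primer_slots) + 1L)
        primer_slots[[nm$primer]]
      } else "P0"
      out[[i]] <- c(rows[[i]]$position, paste0("T", i), pslot,
                    fv(ct$recipe$template_volume), fv(ct$recipe$primer_volume))
    }
    doc <- csv_document(c("well", "template_slot", "primer_slot",
                          "template_vol_ul", "primer_vol_ul"), out)
  } else {
    out <- lapply(rows, function(r) {
      ct <- r$content
      nm <- row_names_for(store, ct)
      vols <- c(fv(ct$recipe$template_volume), fv(ct$recipe$primer_volume),
                fv(ct$recipe$mix_volume), fv(ct$recipe$water_volume))
      if (dialect == "VARIABLE")
        c(r$position, nm$template, nm$primer, vols)
      else  # DECK_B: template first, primer after its volume
        c(nm$template, r$position, vols[[1]], nm$primer, vols[[2]],
          vols[[3]], vols[[4]])
    })
    header <- if (dialect == "VARIABLE")
      c("well", "template_name", "primer_name", "template_vol_ul",
        "primer_vol_ul", "mix_vol_ul", "water_vol_ul")
    else
      c("template_name", "well", "template_vol_ul", "primer_name",
        "primer_vol_ul", "mix_vol_ul", "water_vol_ul")
    doc <- csv_document(header, out)
  }
  if (!is.null(path)) {
    writeChar(doc, path, eos = NULL, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Write the manual-processing spreadsheet
#'
#' For runs prepared by hand rather than by robot: a single-worksheet
#' SpreadsheetML (XML) document, readable by Excel, whose worksheet is
#' named after the run. All 96 wells appear, empty wells marked `EMPTY`,
#' so the sheet doubles as a plate map. Manual pipetting works at larger
#' volumes than the robots, so every volume is scaled by the configured
#' manual multiplier; the amended-file importer divides it back out.
#' Columns are the `VARIABLE` worklist columns plus a free-text `notes`
#' column for the bench.
#'
#' @param store A facility store.
#' @param run_name A run in state `PLANNED`.
#' @param path Optional file to write to (conventionally `.xml`).
#' @return The XML document as a single string, invisibly when `path` is
#'   given.
#' @export
write_manual_sheet <- function(store, run_name, path = NULL) {
  run <- get_run(store, run_name)
  if (run$state != "PLANNED")
    stop_seqfab(sprintf("run %s is %s; the manual sheet is exported from PLANNED",
                        run_name, run$state), "seqfab_state_error")
  mult <- store$config$manual$volume_multiplier %||% 1
  dec <- store$config$robot$volume_decimals %||% 1L
  trav <- well_positions(store$config$plate$traversal %||% "column",
                         run$plate_rows, run$plate_cols)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell_s <- function(x) sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
                                esc(x))
  cell_n <- function(x) sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
                                format_volume(x, dec))
  header <- c("well", "template_name", "primer_name", "template_vol_ul",
              "primer_vol_ul", "mix_vol_ul", "water_vol_ul", "notes")
  rows <- vapply(trav, function(p) {
    ct <- run$wells[[p]]
    cells <- if (is.null(ct)) {
      c(cell_s(p), cell_s("EMPTY"), cell_s(""), cell_s(""), cell_s(""),
        cell_s(""), cell_s(""), cell_s(""))
    } else {
      nm <- row_names_for(store, ct)
      c(cell_s(p), cell_s(nm$template), cell_s(nm$primer),
        cell_n(ct$recipe$template_volume * mult),
        cell_n(ct$recipe$primer_volume * mult),
        cell_n(ct$recipe$mix_volume * mult),
        cell_n(ct$recipe$water_volume * mult),
        cell_s(""))
    }
    paste0("  <Row>", paste(cells, collapse = ""), "</Row>")
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0"?>\n',
    '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">\n',
    sprintf(' <Worksheet ss:Name="%s">\n <Table>\n', esc(run_name)),
    "  <Row>", paste(vapply(header, cell_s, character(1)), collapse = ""),
    "</Row>\n",
    paste(rows, collapse = "\n"), "\n",
    " </Table>\n </Worksheet>\n</Workbook>\n")
  if (!is.null(path)) {
    writeChar(doc, path, eos = NULL, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

# Parse a worklist CSV (text or path) into a data frame.
parse_csv_sheet <- function(document) {
  txt <- if (file.exists(document %||% "")) {
    readChar(document, file.info(document)$size, useBytes = TRUE)
  } else document
  utils::read.csv(text = txt, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
}

# Parse the manual SpreadsheetML sheet back into (run_name, data frame).
parse_manual_sheet <- function(document) {
  doc <- if (file.exists(document %||% "")) xml2::read_xml(document) else
    xml2::read_xml(document)
  ns <- c(ss = "urn:schemas-microsoft-com:office:spreadsheet")
  ws <- xml2::xml_find_first(doc, ".//ss:Worksheet", ns)
  sheet_name <- xml2::xml_attr(ws, "Name")
  rows <- xml2::xml_find_all(ws, ".//ss:Row", ns)
  cells <- lapply(rows, function(r)
    xml2::xml_text(xml2::xml_find_all(r, ".//ss:Data", ns)))
  header <- cells[[1L]]
  body <- cells[-1L]
  tab <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(tab) <- header
  list(run_name = sheet_name, table = tab)
}

#' Re-absorb an operator-amended volume file
#'
#' The variable-volume worklist CSV and the manual sheet can be edited at
#' the bench when DNA or primer quality demands different volumes; the
#' edited file is uploaded back so the alterations are on record. The
#' document must correspond to the run exactly — same well set, same
#' template/primer names per well (and, for the manual sheet, the
#' worksheet must be named after the run) — otherwise it is rejected.
#' Every changed volume cell is logged as part of one `volumes_amended`
#' event (well, field, old, new, operator); re-uploading an unmodified
#' export therefore records nothing. Manual-sheet volumes are divided by
#' the manual multiplier before comparison. A recipe that no longer sums
#' to the reaction volume is accepted with a warning: the operator
#' override wins.
#'
#' @param store A facility store.
#' @param run_name A run in state `PLANNED`.
#' @param document Path to (or text of) the amended `VARIABLE` CSV or
#'   manual `.xml` sheet.
#' @param operator The operator uploading the amendment.
#' @param format `"auto"` (by file extension), `"variable_csv"` or
#'   `"manual_xml"`.
#' @return Data frame of amendments (well, field, old, new); zero rows if
#'   the file matches the stored plan.
#' @export
load_amended_volumes <- function(store, run_name, document, operator,
                                 format = c("auto", "variable_csv",
                                            "manual_xml")) {
  format <- match.arg(format)
  require_operator(store, operator, "volume amendment")
  run <- get_run(store, run_name)
  if (run$state != "PLANNED")
    stop_seqfab(sprintf("run %s is %s; volumes can only be amended while PLANNED",
                        run_name, run$state), "seqfab_state_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(document %||% ""))
    format <- if (ext == "xml") "manual_xml" else "variable_csv"
  }
  mult <- 1
  if (format == "manual_xml") {
    parsed <- parse_manual_sheet(document)
    if (!identical(parsed$run_name, run_name))
      stop_seqfab(sprintf(
        "sheet does not match run: worksheet '%s', expected '%s'",
        parsed$run_name, run_name), "seqfab_io_error")
    tab <- parsed$table
    tab <- tab[tab$template_name != "EMPTY", , drop = FALSE]
    mult <- store$config$manual$volume_multiplier %||% 1
  } else {
    tab <- parse_csv_sheet(document)
    need <- c("well", "template_name", "primer_name", "template_vol_ul",
              "primer_vol_ul", "mix_vol_ul", "water_vol_ul")
    if (!all(need %in% names(tab)))
      stop_seqfab("sheet does not match run: expected the VARIABLE worklist columns",
                  "seqfab_io_error")
  }
  if (!setequal(tab$well, names(run$wells)))
    stop_seqfab("sheet does not match run: well set differs",
                "seqfab_io_error")
  if (anyDuplicated(tab$well))
    stop_seqfab("sheet does not match run: duplicated well rows",
                "seqfab_io_error")

  fields <- c(template_vol_ul = "template_volume",
              primer_vol_ul = "primer_volume",
              mix_vol_ul = "mix_volume",
              water_vol_ul = "water_volume")
  total <- store$config$chemistry$total_reaction_volume
  amendments <- list()
  for (i in seq_len(nrow(tab))) {
    pos <- tab$well[[i]]
    ct <- run$wells[[pos]]
    nm <- row_names_for(store, ct)
    if (!identical(tab$template_name[[i]], nm$template) ||
        !identical(tab$primer_name[[i]], nm$primer))
      stop_seqfab(sprintf(
        "sheet does not match run: well %s names '%s'/'%s', run has '%s'/'%s'",
        pos, tab$template_name[[i]], tab$primer_name[[i]],
        nm$template, nm$primer), "seqfab_io_error")
    for (col in names(fields)) {
      raw_val <- tab[[col]][[i]]
      val <- suppressWarnings(as.numeric(raw_val))
      if (is.na(val))
        stop_seqfab(sprintf("row %d (well %s): unparseable %s value '%s'",
                            i, pos, col, raw_val), "seqfab_io_error")
      val <- val / mult
      old <- ct$recipe[[fields[[col]]]]
      if (abs(val - old) > 1e-6) {
        amendments[[length(amendments) + 1L]] <- data.frame(
          well = pos, field = fields[[col]], old = old, new = val,
          stringsAsFactors = FALSE)
        ct$recipe[[fields[[col]]]] <- val
      }
    }
    if (abs(recipe_total(ct$recipe) - total) > 0.01)
      warning(sprintf(
        "well %s: amended volumes sum to %.2f uL, not the %.1f uL reaction volume (operator override accepted)",
        pos, recipe_total(ct$recipe), total), call. = FALSE)
    run$wells[[pos]] <- ct
  }
  changes <- if (length(amendments)) do.call(rbind, amendments) else
    data.frame(well = character(), field = character(), old = numeric(),
               new = numeric(), stringsAsFactors = FALSE)
  store$runs[[run_name]] <- run
  if (nrow(changes))
    append_event(store, "volumes_amended", operator,
                 list(run_name = run_name, changes = changes))
  changes
}

#' Write the instrument set-up sheet and advance the run
#'
#' The task file loaded into the sequencer: one row per non-empty well
#' with the display name (template and primer names concatenated with an
#' underscore), the run name, and the unique sample reference that lets
#' results be matched back to wells. Control wells carry their control
#' label (`R.Control` / `I.Control`) as the display name and a blank
#' sample reference. Exporting the sheet is the moment the run leaves the
#' planning stage: the first export fires `PLANNED -> AWAITING_RESULTS`;
#' re-exporting an `AWAITING_RESULTS` run re-emits the identical sheet
#' without a second transition. A `COMPLETED` run cannot be exported.
#'
#' @param store A facility store.
#' @param run_name A run in state `PLANNED` or `AWAITING_RESULTS`.
#' @param path Optional file to write to.
#' @return The CSV document as a single string (CRLF line endings),
#'   invisibly when `path` is given.
#' @export
write_instrument_sheet <- function(store, run_name, path = NULL) {
  run <- get_run(store, run_name)
  if (run$state == "COMPLETED")
    stop_seqfab(sprintf("run %s is COMPLETED; its set-up sheet is final",
                        run_name), "seqfab_state_error")
  rows <- run_rows(store, run)
  out <- lapply(rows, function(r) {
    ct <- r$content
    if (ct$kind == "SAMPLE") {
      s <- get_sample(store, ct$sample_ref)
      c(r$position, paste0(s$template_name, "_", s$primer_name),
        run_name, ct$sample_ref)
    } else {
      c(r$position, CONTROL_LABELS[[ct$kind]], run_name, "")
    }
  })
  doc <- csv_document(c("well", "display_name", "run_name", "sample_ref"),
                      out)
  if (run$state == "PLANNED") {
    run <- run_transition(run, "setup_sheet_exported")
    store$runs[[run_name]] <- run
    append_event(store, "setup_sheet_exported", "operator",
                 list(run_name = run_name))
  }
  if (!is.null(path)) {
    writeChar(doc, path, eos = NULL, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
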