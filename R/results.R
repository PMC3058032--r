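# Sequencing results: ingest the sequencer's ZIP output, link files to
# samples, score and trim reads, manage statuses/tags/notes, complete
# runs, and export per-order results.

#' Trim unresolved sequence ends
#'
#' Removes the longest prefix and suffix made up solely of ambiguity
#' codes — any IUPAC nucleotide letter other than A, C, G, T (most
#' commonly N). Interior ambiguities are left untouched and case is
#' preserved. U is treated as unambiguous, so RNA-alphabet text survives.
#'
#' @param seq An IUPAC nucleotide string (case-insensitive), possibly
#'   empty.
#' @return The trimmed string.
#' @export
#' @examples
#' trim_sequence("NNNACGTNN")   # "ACGT"
#' trim_sequence("ACNNGT")      # interior ambiguity kept
trim_sequence <- function(seq) {
  if (length(seq) != 1L || is.na(seq)) return("")
  sub("[^ACGTUacgtu]*$", "", sub("^[^ACGTUacgtu]*", "", seq))
}

count_ambiguous <- function(seq) {
  nchar(seq) - nchar(gsub("[^ACGTUacgtu]", "", seq))
}

#' Score a sequencing result
#'
#' The readable length of a read is the length left after
#' [trim_sequence()] (interior ambiguities count as readable; only
#' unresolved ends are dropped). Two statistics summarize quality for the
#' customer:
#' * `pct_read` — readable length as a percentage of the requested read
#'   length, deliberately not capped at 100 (a 114% read says the
#'   reaction over-delivered);
#' * `pct_amb` — ambiguous letters as a percentage of the *raw* sequence
#'   length (0 for an empty sequence), so it measures the quality of the
#'   upload as delivered, before any trimming.
#'
#' Status is `OK` when the readable length meets or exceeds the request,
#' otherwise `FAILED`; `status = OK` is equivalent to `pct_read >= 100`.
#'
#' @param seq IUPAC nucleotide string (possibly empty).
#' @param requested_read_length Requested bases, > 0.
#' @return List with `pct_read`, `pct_amb`, `status`.
#' @export
#' @examples
#' score_result(strrep("A", 800), 700)  # ~114.3%, OK
score_result <- function(seq, requested_read_length) {
  if (is.null(requested_read_length) || is.na(requested_read_length) ||
      requested_read_length <= 0)
    stop_seqfab("requested_read_length must be > 0", "seqfab_scoring_error")
  seq <- if (length(seq) != 1L || is.na(seq)) "" else seq
  readable <- nchar(trim_sequence(seq))
  pct_read <- 100 * readable / requested_read_length
  pct_amb <- if (nchar(seq) == 0L) 0 else
    100 * count_ambiguous(seq) / nchar(seq)
  list(pct_read = pct_read, pct_amb = pct_amb,
       status = if (readable >= requested_read_length) "OK" else "FAILED")
}

# .seq members are either plain sequence text or a single-record FASTA;
# sniff the ">" and concatenate the remaining lines either way.
parse_seq_member <- function(bytes) {
  txt <- rawToChar(bytes)
  lines <- strsplit(txt, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return("")
  if (startsWith(lines[[1]], ">")) lines <- lines[-1L]
  gsub("[[:space:]]", "", paste(lines, collapse = ""))
}

# File <-> sample matching: the sample_ref must appear as a whole token in
# the file's base name (tokens split on any non-alphanumeric character).
# The fixture generator names files "<sample_ref>.<ext>".
match_member_to_sample <- function(member_name, sample_refs) {
  base <- basename(member_name)
  stem <- tools::file_path_sans_ext(base)
  tokens <- strsplit(stem, "[^A-Za-z0-9]+")[[1]]
  hit <- sample_refs[sample_refs %in% tokens]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Ingest a sequencer results archive
#'
#' Uploads the ZIP the sequencer produced for a run that is awaiting
#' results. Each member file is linked to a sample when the sample's
#' unique reference appears as a token in the file name; `.seq` members
#' additionally have their text parsed as the sequence (plain text or
#' single-record FASTA) and the sample is auto-scored with
#' [score_result()] — unless an operator has manually overridden the
#' status, in which case the manual status stands. Chromatogram members
#' (`.ab1`, `.scf`) are stored as opaque attachments, never parsed.
#' Repeated ingestion merges: later files overwrite same-named earlier
#' ones. Files matching no sample are reported, not fatal.
#'
#' @param store A facility store.
#' @param run_name A run in state `AWAITING_RESULTS`.
#' @param archive Path to the ZIP archive.
#' @return A linkage report: list with `matched` (sample_ref -> attached
#'   file names), `unmatched_files`, and `samples_without_results`.
#'   `matched` and `samples_without_results` partition the run's samples.
#' @export
ingest_results_zip <- function(store, run_name, archive) {
  run <- get_run(store, run_name)
  if (run$state != "AWAITING_RESULTS")
    stop_seqfab(sprintf("run %s is %s; results are ingested while AWAITING_RESULTS",
                        run_name, run$state), "seqfab_state_error")
  members <- read_zip_archive(archive)
  refs <- run_sample_refs(run)
  unmatched <- character()
  touched <- character()
  for (nm in names(members)) {
    ref <- match_member_to_sample(nm, refs)
    if (is.na(ref)) {
      unmatched <- c(unmatched, nm)
      next
    }
    res <- store$results[[ref]]
    res$attachments[[basename(nm)]] <- members[[nm]]
    res$uploaded <- TRUE
    if (tolower(tools::file_ext(nm)) == "seq") {
      res$sequence_text <- parse_seq_member(members[[nm]])
      s <- get_sample(store, ref)
      sc <- score_result(res$sequence_text, s$requested_read_length)
      res$pct_read <- sc$pct_read
      res$pct_amb <- sc$pct_amb
      if (!res$manual_status) res$status <- sc$status
    } else if (!res$manual_status && res$status == "IN_PROCESS" &&
               is.null(res$sequence_text)) {
      # traces without a .seq: uploaded but nothing scorable yet
      res$status <- "IN_PROCESS"
    }
    store$results[[ref]] <- res
    touched <- c(touched, ref)
  }
  matched_refs <- refs[vapply(refs, function(r)
    isTRUE(store$results[[r]]$uploaded), logical(1))]
  report <- list(
    matched = stats::setNames(
      lapply(matched_refs, function(r) names(store$results[[r]]$attachments)),
      matched_refs),
    unmatched_files = unmatched,
    samples_without_results = setdiff(refs, matched_refs))
  append_event(store, "results_ingested", "operator",
               list(run_name = run_name, n_matched = length(matched_refs),
                    n_unmatched_files = length(unmatched)))
  report
}

#' Override a sample's status
#'
#' The automatically assigned OK/FAILED status can be altered by a
#' facility operator — for instance to fail a read whose chromatogram
#' looks wrong despite sufficient length. Manual overrides are logged and
#' outrank any subsequent automatic re-scoring (operator intent wins).
#' Overriding to `FAILED` hides the sample's files from the owning user.
#'
#' @param store A facility store.
#' @param sample_ref The sample.
#' @param status `"OK"`, `"FAILED"` or `"IN_PROCESS"`.
#' @param operator The operator (role is enforced).
#' @export
set_status <- function(store, sample_ref, status, operator) {
  require_operator(store, operator, "status override")
  status <- match.arg(status, RESULT_STATUSES)
  res <- store$results[[sample_ref]]
  if (is.null(res))
    stop_seqfab(sprintf("unknown sample '%s'", sample_ref),
                "seqfab_lookup_error")
  old <- res$status
  res$status <- status
  res$manual_status <- TRUE
  if (status != "FAILED") res$tags <- character()
  store$results[[sample_ref]] <- res
  append_event(store, "status_overridden", operator,
               list(sample_ref = sample_ref, old = old, new = status))
  invisible(res)
}

#' Tag a failed sample for re-injection or re-processing
#'
#' Failed samples can be tagged `Rj` (re-inject: run the prepared
#' reaction through the sequencer again) or `Rp` (re-process: remake the
#' reaction from the sample, used when the cause of failure is unclear).
#' Tagging is idempotent and only legal on `FAILED` samples.
#'
#' @param store A facility store.
#' @param sample_ref The sample.
#' @param tag `"Rp"` or `"Rj"`.
#' @param operator The operator (role is enforced).
#' @export
tag_sample <- function(store, sample_ref, tag, operator) {
  require_operator(store, operator, "tagging")
  tag <- match.arg(tag, SAMPLE_TAGS)
  res <- store$results[[sample_ref]]
  if (is.null(res))
    stop_seqfab(sprintf("unknown sample '%s'", sample_ref),
                "seqfab_lookup_error")
  if (res$status != "FAILED")
    stop_seqfab(sprintf("sample %s is %s; tags apply to FAILED samples only",
                        sample_ref, res$status), "seqfab_state_error")
  res$tags <- union(res$tags, tag)
  store$results[[sample_ref]] <- res
  invisible(res)
}

#' Annotate a sample with a note
#'
#' Any number of notes can be attached to a sample; each bears its author
#' and creation time, immutable afterwards. `PRIVATE` notes are visible
#' to operators only; `PUBLIC` notes appear in the owner's result view
#' too.
#'
#' @param store A facility store.
#' @param sample_ref The sample.
#' @param text Non-empty note text.
#' @param author The writing principal.
#' @param visibility `"PRIVATE"` or `"PUBLIC"`.
#' @return The stored note, invisibly.
#' @export
add_note <- function(store, sample_ref, text, author,
                     visibility = c("PUBLIC", "PRIVATE")) {
  visibility <- match.arg(visibility)
  get_principal(store, author)
  res <- store$results[[sample_ref]]
  if (is.null(res))
    stop_seqfab(sprintf("unknown sample '%s'", sample_ref),
                "seqfab_lookup_error")
  note <- new_note(author, text, visibility)
  res$notes[[length(res$notes) + 1L]] <- note
  store$results[[sample_ref]] <- res
  invisible(note)
}

#' Complete a run and notify the affected orders
#'
#' When every result is uploaded and scored the plate is completed: the
#' run moves to `COMPLETED`, and every member order whose samples are all
#' resolved (no `IN_PROCESS` left, across all its runs) is completed
#' too, appending one `order_completed` event per order with a retrieval
#' locator — the notification surrogate for the customer email.
#' Samples still `IN_PROCESS` block completion unless `force = TRUE`
#' (they then simply stay `IN_PROCESS`).
#'
#' @param store A facility store.
#' @param run_name A run in state `AWAITING_RESULTS`.
#' @param force Complete even with unresolved samples.
#' @return Invisibly, the ids of the orders completed by this call.
#' @export
complete_run <- function(store, run_name, force = FALSE) {
  run <- get_run(store, run_name)
  if (run$state != "AWAITING_RESULTS")
    stop_seqfab(sprintf("run %s is %s; only AWAITING_RESULTS runs complete",
                        run_name, run$state), "seqfab_state_error")
  refs <- run_sample_refs(run)
  pending <- refs[vapply(refs, function(r)
    store$results[[r]]$status == "IN_PROCESS", logical(1))]
  if (length(pending) && !force)
    stop_seqfab(sprintf(
      "run %s has %d unresolved sample(s): %s (use force to complete anyway)",
      run_name, length(pending), paste(pending, collapse = ", ")),
      "seqfab_state_error")
  run <- run_transition(run, "results_completed")
  store$runs[[run_name]] <- run
  completed_orders <- character()
  for (oid in run$order_ids) {
    order <- store$orders[[oid]]
    statuses <- vapply(names(order$samples), function(r)
      store$results[[r]]$status, character(1))
    if (all(statuses != "IN_PROCESS")) {
      order$state <- "COMPLETED"
      store$orders[[oid]] <- order
      completed_orders <- c(completed_orders, oid)
      append_event(store, "order_completed", "operator",
                   list(order_id = oid,
                        locator = sprintf("order/%s/results", oid)))
    }
  }
  invisible(completed_orders)
}

#' Per-order upload traffic light
#'
#' The review page colours each order by upload progress: `GREEN` when a
#' result has been uploaded for every sample, `RED` when for none,
#' `YELLOW` otherwise. The light measures *upload*, not success — an
#' order whose reads all failed is still GREEN.
#'
#' @param store A facility store.
#' @param order_id The order.
#' @return `"GREEN"`, `"YELLOW"` or `"RED"`.
#' @export
order_traffic_light <- function(store, order_id) {
  order <- get_order(store, order_id)
  up <- vapply(names(order$samples), function(r)
    isTRUE(store$results[[r]]$uploaded), logical(1))
  if (all(up)) "GREEN" else if (!any(up)) "RED" else "YELLOW"
}

# Samples of an order whose FILES this viewer may see (FAILED hidden from
# non-operators), in order.
visible_result_samples <- function(store, order, viewer) {
  keep <- vapply(names(order$samples), function(r)
    result_files_visible(store, viewer, r), logical(1))
  order$samples[keep]
}

check_export_access <- function(store, order, viewer) {
  if (!visible(store, viewer, order))
    stop_seqfab(sprintf("%s may not access order %s", viewer, order$order_id),
                "seqfab_auth_error")
  if (order$state != "COMPLETED" && !is_operator(store, viewer))
    stop_seqfab(sprintf("order %s is not completed yet", order$order_id),
                "seqfab_state_error")
  invisible(TRUE)
}

#' Export an order's sequences as FASTA
#'
#' One record per sample that has a sequence, header
#' `>` + sample_ref + space + template_name `_` primer_name, wrapped at
#' 60 columns. The `trimmed` variant applies [trim_sequence()] to every
#' record. For non-operator viewers, FAILED samples are omitted (their
#' files are not shown to the user).
#'
#' @param store A facility store.
#' @param order_id The order (must be COMPLETED unless the viewer is an
#'   operator).
#' @param viewer The requesting principal.
#' @param variant `"plain"` or `"trimmed"`.
#' @param path Optional file to write to.
#' @return The FASTA text as one string, invisibly when `path` is given.
#' @export
export_fasta <- function(store, order_id, viewer,
                         variant = c("plain", "trimmed"), path = NULL) {
  variant <- match.arg(variant)
  order <- get_order(store, order_id)
  check_export_access(store, order, viewer)
  samples <- visible_result_samples(store, order, viewer)
  seqs <- character()
  for (s in samples) {
    res <- store$results[[s$sample_ref]]
    if (is.null(res$sequence_text)) next
    sq <- if (variant == "trimmed") trim_sequence(res$sequence_text) else
      res$sequence_text
    seqs[paste0(s$sample_ref, " ", s$template_name, "_", s$primer_name)] <- sq
  }
  dss <- Biostrings::DNAStringSet(seqs)
  tmp <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(dss, tmp, width = 60L)
  doc <- readChar(tmp, file.info(tmp)$size, useBytes = TRUE)
  unlink(tmp)
  if (!is.null(path)) {
    writeChar(doc, path, eos = NULL, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Export an order's full results archive
#'
#' A ZIP of every attachment (sequence text and chromatogram files, under
#' their original names) for the samples the viewer may see, plus the
#' plain FASTA of the order. FAILED samples' files are omitted for
#' non-operator viewers; an order with nothing visible to export is
#' rejected.
#'
#' @inheritParams export_fasta
#' @param path Output ZIP path.
#' @return `path`, invisibly.
#' @export
export_archive <- function(store, order_id, viewer, path) {
  order <- get_order(store, order_id)
  check_export_access(store, order, viewer)
  samples <- visible_result_samples(store, order, viewer)
  members <- list()
  for (s in samples) {
    res <- store$results[[s$sample_ref]]
    for (nm in names(res$attachments)) members[[nm]] <- res$attachments[[nm]]
  }
  if (length(members) == 0L)
    stop_seqfab(sprintf("nothing to export for order %s", order_id),
                "seqfab_io_error")
  members[[paste0(order_id, ".fasta")]] <-
    charToRaw(export_fasta(store, order_id, viewer, "plain"))
  write_zip_archive(members, path)
}

#' Resubmit a failed sample as a fresh order
#'
#' One-click re-processing: clones the failed sample's user-entered
#' fields into a new single-sample order for the same owner, with a
#' fresh sample reference and a provenance link back to the original.
#' Nothing has to be re-typed. Only `FAILED` samples qualify, and only
#' the order's owner or an operator may do it.
#'
#' @param store A facility store.
#' @param sample_ref The failed sample.
#' @param caller The requesting principal.
#' @return As [create_order()]: list with the new `order` and its
#'   `confirmation`.
#' @export
resubmit_failed <- function(store, sample_ref, caller) {
  res <- store$results[[sample_ref]]
  if (is.null(res))
    stop_seqfab(sprintf("unknown sample '%s'", sample_ref),
                "seqfab_lookup_error")
  if (res$status != "FAILED")
    stop_seqfab(sprintf("sample %s is %s; only FAILED samples are resubmitted",
                        sample_ref, res$status), "seqfab_state_error")
  oid <- store$sample_index[[sample_ref]]
  order <- store$orders[[oid]]
  if (!identical(order$owner, caller) && !is_operator(store, caller))
    stop_seqfab(sprintf("%s neither owns order %s nor is an operator",
                        caller, oid), "seqfab_auth_error")
  s <- order$samples[[sample_ref]]
  rec <- unclass(s)
  rec$sample_ref <- NULL
  rec$resubmitted_from <- sample_ref
  create_order(store, order$owner, list(rec), group = order$group,
               account = order$account)
}
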