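# A store with one planned+exported run of n samples, ready for ingest.
awaiting_run <- function(n = 4, read_length = 8) {
  store <- make_store()
  recs <- lapply(seq_len(n), function(i)
    make_record(template_name = sprintf("tpl%d", i),
                requested_read_length = read_length))
  oid <- create_order(store, "u1", recs)$order$order_id
  run <- plan_run(store, oid, mode = "FIXED")
  write_instrument_sheet(store, run$run_name)
  list(store = store, run_name = run$run_name, order_id = oid,
       refs = names(store$orders[[oid]]$samples))
}

zip_for <- function(refs, seqs, dir = NULL,
                    with_traces = TRUE, extras = list()) {
  if (is.null(dir)) {
    dir <- tempfile("zipfor_")
    dir.create(dir)
  }
  members <- list()
  for (i in seq_along(refs)) {
    members[[paste0(refs[i], ".seq")]] <- paste0(seqs[i], "\n")
    if (with_traces) {
      members[[paste0(refs[i], ".ab1")]] <- charToRaw("FIXTURE-AB1:x")
      members[[paste0(refs[i], ".scf")]] <- charToRaw("FIXTURE-SCF:x")
    }
  }
  for (nm in names(extras)) members[[nm]] <- extras[[nm]]
  path <- file.path(dir, "results.zip")
  write_zip_archive(members, path)
  path
}

test_that("trimming removes ambiguous ends only", {
  expect_identical(trim_sequence("NNNACGTNN"), "ACGT")
  expect_identical(trim_sequence("ACGT"), "ACGT")
  expect_identical(trim_sequence("ACNNGT"), "ACNNGT")
  expect_identical(trim_sequence("NNNN"), "")
  expect_identical(trim_sequence(""), "")
  expect_identical(trim_sequence("nracgtn"), "acgt")  # case preserved
  expect_identical(trim_sequence("NUUN"), "UU")       # U unambiguous
})

test_that("trim is idempotent and accounts for every terminal ambiguity", {
  set.seed(23)
  for (i in 1:300) {
    s <- random_iupac()
    t1 <- trim_sequence(s)
    expect_identical(trim_sequence(t1), t1)
    expect_true(grepl(t1, s, fixed = TRUE) || t1 == "")
    expect_identical(nchar(t1) + oracle_terminal_amb_count(s), nchar(s))
  }
})

test_that("scoring matches direct arithmetic and the brute-force oracle", {
  sc <- score_result(strrep("A", 800), 700)
  expect_equal(sc$pct_read, 100 * 800 / 700)
  expect_equal(sc$pct_amb, 0)
  expect_identical(sc$status, "OK")

  sc0 <- score_result("", 500)
  expect_equal(sc0$pct_read, 0)
  expect_equal(sc0$pct_amb, 0)
  expect_identical(sc0$status, "FAILED")

  sc2 <- score_result("NNNACGTACGTNNN", 8)
  expect_equal(sc2$pct_read, 100)
  expect_equal(sc2$pct_amb, 100 * 6 / 14)
  expect_identical(sc2$status, "OK")

  set.seed(29)
  for (i in 1:500) {
    s <- random_iupac()
    req <- sample(1:30, 1)
    got <- score_result(s, req)
    want <- oracle_score(s, req)
    expect_equal(got$pct_read, want$pct_read)
    expect_equal(got$pct_amb, want$pct_amb)
    expect_identical(got$status, want$status)
    expect_identical(got$status == "OK", got$pct_read >= 100)
  }
})

test_that("a complete archive scores every sample and partitions cleanly", {
  aw <- awaiting_run(4)
  path <- zip_for(aw$refs, c("ACGTACGTAA", "NNACGTNN", "acgtacgtACGT", "NNNN"))
  rep <- ingest_results_zip(aw$store, aw$run_name, path)
  expect_length(rep$matched, 4L)
  expect_length(rep$samples_without_results, 0L)
  expect_length(rep$unmatched_files, 0L)
  statuses <- vapply(aw$refs, function(r) aw$store$results[[r]]$status,
                     character(1))
  expect_setequal(unique(statuses), c("OK", "FAILED"))
  expect_identical(unname(statuses[1]), "OK")      # 10 >= 8
  expect_identical(unname(statuses[2]), "FAILED")  # trimmed to 4 < 8
  # partition invariant
  expect_setequal(c(names(rep$matched), rep$samples_without_results), aw$refs)
})

test_that("a partial archive leaves the missing samples IN_PROCESS", {
  aw <- awaiting_run(4)
  path <- zip_for(aw$refs[1:2], c("ACGTACGTAA", "ACGTACGTCC"))
  rep <- ingest_results_zip(aw$store, aw$run_name, path)
  expect_length(rep$matched, 2L)
  expect_setequal(rep$samples_without_results, aw$refs[3:4])
  expect_identical(aw$store$results[[aw$refs[3]]]$status, "IN_PROCESS")
  expect_true(is.na(aw$store$results[[aw$refs[3]]]$pct_read))
  expect_identical(order_traffic_light(aw$store, aw$order_id), "YELLOW")
})

test_that("unmatched members are reported, not fatal; ingest gates on state", {
  aw <- awaiting_run(2)
  path <- zip_for(aw$refs, c("ACGTACGTAA", "ACGTACGTCC"),
                  extras = list("misc_readme.txt" = "hello"))
  rep <- ingest_results_zip(aw$store, aw$run_name, path)
  expect_identical(rep$unmatched_files, "misc_readme.txt")

  store <- make_store()
  oid <- create_order(store, "u1", list(make_record()))$order$order_id
  run <- plan_run(store, oid)  # still PLANNED
  expect_error(ingest_results_zip(store, run$run_name, path),
               class = "seqfab_state_error")
  expect_error(ingest_results_zip(aw$store, aw$run_name,
                                  file.path(tempdir(), "nope.zip")),
               class = "seqfab_io_error")
})

test_that("re-ingesting merges, and trace blobs stay opaque", {
  aw <- awaiting_run(1)
  p1 <- zip_for(aw$refs, "NN")            # FAILED
  ingest_results_zip(aw$store, aw$run_name, p1)
  expect_identical(aw$store$results[[aw$refs[1]]]$status, "FAILED")
  p2 <- zip_for(aw$refs, "ACGTACGTAA")    # later file overwrites
  ingest_results_zip(aw$store, aw$run_name, p2)
  res <- aw$store$results[[aw$refs[1]]]
  expect_identical(res$status, "OK")
  expect_identical(res$sequence_text, "ACGTACGTAA")
  # the ab1 attachment is the fixture blob, byte for byte: nothing parsed it
  expect_identical(rawToChar(res$attachments[[paste0(aw$refs[1], ".ab1")]]),
                   "FIXTURE-AB1:x")
})

test_that("manual status overrides outrank later automatic scoring", {
  aw <- awaiting_run(1)
  path <- zip_for(aw$refs, "ACGTACGTAA")
  ingest_results_zip(aw$store, aw$run_name, path)
  expect_identical(aw$store$results[[aw$refs[1]]]$status, "OK")
  set_status(aw$store, aw$refs[1], "FAILED", "op")
  ingest_results_zip(aw$store, aw$run_name, path)  # same file again
  expect_identical(aw$store$results[[aw$refs[1]]]$status, "FAILED")
  expect_length(event_log(aw$store, "status_overridden"), 1L)
  # only operators may override
  expect_error(set_status(aw$store, aw$refs[1], "OK", "u1"),
               class = "seqfab_auth_error")
})

test_that("tags apply to FAILED samples only and are idempotent", {
  aw <- awaiting_run(2)
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs, c("ACGTACGTAA", "NN")))
  expect_error(tag_sample(aw$store, aw$refs[1], "Rp", "op"),
               class = "seqfab_state_error")
  tag_sample(aw$store, aw$refs[2], "Rj", "op")
  tag_sample(aw$store, aw$refs[2], "Rj", "op")
  tag_sample(aw$store, aw$refs[2], "Rp", "op")
  expect_setequal(aw$store$results[[aw$refs[2]]]$tags, c("Rj", "Rp"))
  expect_error(tag_sample(aw$store, aw$refs[2], "Rx", "op"))
})

test_that("notes keep author and order; private notes stay operator-side", {
  aw <- awaiting_run(1)
  add_note(aw$store, aw$refs[1], "weak signal", "op", "PRIVATE")
  add_note(aw$store, aw$refs[1], "please re-submit cleaner DNA", "op", "PUBLIC")
  notes_op <- seqfab:::visible_notes(aw$store, "op", aw$refs[1])
  notes_u1 <- seqfab:::visible_notes(aw$store, "u1", aw$refs[1])
  expect_length(notes_op, 2L)
  expect_length(notes_u1, 1L)
  expect_identical(notes_u1[[1]]$text, "please re-submit cleaner DNA")
  expect_identical(notes_op[[1]]$text, "weak signal")  # creation order kept
  expect_error(add_note(aw$store, aw$refs[1], "  ", "op", "PUBLIC"),
               class = "seqfab_model_error")
})

test_that("completion requires resolved samples unless forced", {
  aw <- awaiting_run(3)
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs[1:2], c("ACGTACGTAA", "NN")))
  expect_error(complete_run(aw$store, aw$run_name), aw$refs[3],
               class = "seqfab_state_error")
  done <- complete_run(aw$store, aw$run_name, force = TRUE)
  expect_identical(aw$store$runs[[aw$run_name]]$state, "COMPLETED")
  expect_identical(aw$store$results[[aw$refs[3]]]$status, "IN_PROCESS")
  # the order still has an unresolved sample: not completed, no event
  expect_length(done, 0L)
  expect_identical(aw$store$orders[[aw$order_id]]$state, "LOCKED")

  aw2 <- awaiting_run(2)
  ingest_results_zip(aw2$store, aw2$run_name,
                     zip_for(aw2$refs, c("ACGTACGTAA", "ACGTACGTCC")))
  done2 <- complete_run(aw2$store, aw2$run_name)
  expect_identical(done2, aw2$order_id)
  evs <- event_log(aw2$store, "order_completed")
  expect_length(evs, 1L)
  expect_match(evs[[1]]$payload$locator, aw2$order_id, fixed = TRUE)
})

test_that("traffic lights report uploads: all green, none red, some yellow", {
  aw <- awaiting_run(3)
  expect_identical(order_traffic_light(aw$store, aw$order_id), "RED")
  ingest_results_zip(aw$store, aw$run_name, zip_for(aw$refs[1], "NN"))
  expect_identical(order_traffic_light(aw$store, aw$order_id), "YELLOW")
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs[2:3], c("NN", "NN")))
  # all uploaded but all failed: still GREEN - the light measures upload
  expect_identical(order_traffic_light(aw$store, aw$order_id), "GREEN")
})

test_that("fasta exports honour variant and viewer visibility", {
  aw <- awaiting_run(2)
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs, c("NNACGTACGTAC", "NNACGTN")))
  complete_run(aw$store, aw$run_name)
  fa <- export_fasta(aw$store, aw$order_id, "op", "plain")
  expect_match(fa, sprintf(">%s tpl1_M13F", aw$refs[1]), fixed = TRUE)
  expect_match(fa, "NNACGTACGTAC", fixed = TRUE)
  tr <- export_fasta(aw$store, aw$order_id, "op", "trimmed")
  expect_match(tr, "\nACGT\n", fixed = TRUE)       # sample 2 trimmed
  expect_false(grepl("NNACGTN", tr, fixed = TRUE))
  # sample 2 FAILED (5 < 8): hidden from the user, shown to the operator
  fa_u <- export_fasta(aw$store, aw$order_id, "u1", "plain")
  expect_false(grepl(aw$refs[2], fa_u, fixed = TRUE))
  expect_match(fa, aw$refs[2], fixed = TRUE)
  # the export parses as valid FASTA with 60-column wrapping
  tmp <- tempfile(fileext = ".fasta")
  writeChar(fa, tmp, eos = NULL)
  parsed <- Biostrings::readDNAStringSet(tmp)
  expect_length(parsed, 2L)
  # cross-group viewer is rejected outright
  expect_error(export_fasta(aw$store, aw$order_id, "u2", "plain"),
               class = "seqfab_auth_error")
})

test_that("archive export bundles visible attachments plus the fasta", {
  aw <- awaiting_run(2)
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs, c("ACGTACGTAC", "NN")))
  complete_run(aw$store, aw$run_name)
  d <- withr::local_tempdir()
  p_op <- file.path(d, "op.zip")
  export_archive(aw$store, aw$order_id, "op", p_op)
  m_op <- seqfab:::read_zip_archive(p_op)
  expect_true(all(c(paste0(aw$refs[1], ".seq"), paste0(aw$refs[1], ".ab1"),
                    paste0(aw$refs[1], ".scf"),
                    paste0(aw$order_id, ".fasta")) %in% names(m_op)))
  expect_true(paste0(aw$refs[2], ".seq") %in% names(m_op))
  p_u <- file.path(d, "u.zip")
  export_archive(aw$store, aw$order_id, "u1", p_u)
  m_u <- seqfab:::read_zip_archive(p_u)
  expect_false(any(grepl(aw$refs[2], names(m_u), fixed = TRUE)))

  # nothing visible at all -> rejection
  set_status(aw$store, aw$refs[1], "FAILED", "op")
  expect_error(export_archive(aw$store, aw$order_id, "u1",
                              file.path(d, "none.zip")),
               "nothing to export", class = "seqfab_io_error")
})

test_that("failed samples resubmit as a fresh identical order", {
  aw <- awaiting_run(2)
  ingest_results_zip(aw$store, aw$run_name,
                     zip_for(aw$refs, c("ACGTACGTAC", "NN")))
  complete_run(aw$store, aw$run_name)
  expect_error(resubmit_failed(aw$store, aw$refs[1], "u1"),
               class = "seqfab_state_error")
  expect_error(resubmit_failed(aw$store, aw$refs[2], "u2"),
               class = "seqfab_auth_error")
  res <- resubmit_failed(aw$store, aw$refs[2], "u1")
  clone <- res$order$samples[[1]]
  orig <- get_sample(aw$store, aw$refs[2])
  expect_identical(res$order$state, "NEW")
  expect_false(identical(clone$sample_ref, orig$sample_ref))
  expect_identical(clone$resubmitted_from, orig$sample_ref)
  for (fld in c("template_name", "primer_name", "template_concentration",
                "requested_read_length", "sequencing_type"))
    expect_identical(clone[[fld]], orig[[fld]])
})
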