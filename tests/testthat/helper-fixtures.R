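# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive character-by-character / enumeration code, separate
# from the implementation they check.

# A valid sample record; override any field.
make_record <- function(...) {
  rec <- list(template_name = "pUC19", primer_name = "M13F",
              primer_source = "facility",
              template_concentration = 80, template_volume_supplied = 15,
              primer_concentration = NA, primer_volume_supplied = NA,
              requested_read_length = 700, sequencing_type = "standard")
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

make_customer_record <- function(...) {
  rec <- make_record(primer_name = "primF1", primer_source = "customer",
                     primer_concentration = 10, primer_volume_supplied = 20)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# Config with controls switched off (full 96 wells for samples).
config_no_controls <- function() {
  cfg <- default_config()
  cfg$plate$reaction_controls <- 0L
  cfg$plate$instrument_controls <- 0L
  cfg
}

# Store pre-loaded with one customer ("u1" in group "G1") and one
# operator ("op").
make_store <- function(config = default_config()) {
  store <- new_store(config)
  add_principal(store, "u1", "User One", "G1", "USER")
  add_principal(store, "u2", "User Two", "G2", "USER")
  add_principal(store, "op", "Operator", "FAC", "OPERATOR")
  store
}

# Fast path to a store holding orders of given sizes (one per element),
# bypassing sheet import; goes through create_order so ids/results exist.
store_with_orders <- function(sizes, config = default_config(),
                              owner = "u1") {
  store <- make_store(config)
  oids <- character(length(sizes))
  for (i in seq_along(sizes)) {
    recs <- replicate(sizes[[i]],
                      make_record(template_name = sprintf("t%d", i)),
                      simplify = FALSE)
    oids[i] <- create_order(store, owner, recs)$order$order_id
  }
  attr(store, "order_ids") <- oids
  store
}

# A fixed two-order, four-sample plan used for the golden worklist files;
# fully deterministic (no RNG, explicit concentrations).
golden_store <- function(mode = "FIXED") {
  store <- make_store()
  create_order(store, "u1", list(
    make_record(template_name = "pUC19", primer_name = "M13F",
                template_concentration = 50),
    make_record(template_name = "pET28a-his", primer_name = "T7",
                template_concentration = 100),
    make_customer_record(template_name = "gDNA-k12", primer_name = "primF1",
                         template_concentration = 25,
                         primer_concentration = 10)))
  create_order(store, "u2", list(
    make_customer_record(template_name = "pGEX-gst", primer_name = "primR9",
                         template_concentration = 125,
                         primer_concentration = 50)))
  run <- plan_run(store, names(store$orders), mode = mode)
  list(store = store, run_name = run$run_name)
}

read_file_bytes <- function(path) readBin(path, "raw", n = file.size(path))

# ---- oracles -------------------------------------------------------------

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K",
                   "M", "B", "D", "H", "V")

random_iupac <- function(max_len = 40L, amb_weight = 0.3) {
  n <- sample(0:max_len, 1L)
  if (n == 0L) return("")
  w <- c(rep((1 - amb_weight) / 5, 5), rep(amb_weight / 11, 11))
  letters_drawn <- sample(IUPAC_LETTERS, n, replace = TRUE, prob = w)
  flip <- runif(n) < 0.3
  letters_drawn[flip] <- tolower(letters_drawn[flip])
  paste(letters_drawn, collapse = "")
}

# Character-by-character scoring oracle. Ambiguity alphabet: anything
# outside {A,C,G,T,U}, case-insensitive (U unambiguous, RNA-safe).
oracle_is_amb <- function(chars) !(toupper(chars) %in% c("A", "C", "G", "T", "U"))

oracle_trim <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) return("")
  keep <- which(!oracle_is_amb(chars))
  if (length(keep) == 0L) return("")
  paste(chars[min(keep):max(keep)], collapse = "")
}

oracle_terminal_amb_count <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) return(0L)
  amb <- oracle_is_amb(chars)
  lead <- 0L
  for (a in amb) { if (!a) break; lead <- lead + 1L }
  if (lead == length(chars)) return(length(chars))
  tail_ <- 0L
  for (a in rev(amb)) { if (!a) break; tail_ <- tail_ + 1L }
  lead + tail_
}

oracle_score <- function(seq, requested) {
  chars <- strsplit(seq, "")[[1]]
  readable <- nchar(oracle_trim(seq))
  n_amb <- sum(oracle_is_amb(chars))
  list(pct_read = 100 * readable / requested,
       pct_amb = if (length(chars) == 0L) 0 else 100 * n_amb / length(chars),
       status = if (readable >= requested) "OK" else "FAILED")
}

# Brute-force minimum plate count: smallest k whose capacity covers n.
oracle_min_plates <- function(n, usable) {
  k <- 0L
  while (k * usable < n) k <- k + 1L
  k
}
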