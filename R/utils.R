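# Shared helpers: well geometry, rounding, CSV conventions.

#' Enumerate plate well positions in traversal order
#'
#' Well positions are written letter row (A-H) plus column number (1-12)
#' with no zero padding ("A1", not "A01"). Column-major traversal
#' (A1,B1,...,H1,A2,...) is the default because capillary sequencers
#' inject by column groups; row-major is available for plate readers
#' that scan by row.
#'
#' @param traversal "column" or "row".
#' @param rows,cols Plate geometry (default 8 x 12).
#' @return Character vector of `rows * cols` well positions.
#' @export
#' @examples
#' well_positions()[1:10]
well_positions <- function(traversal = c("column", "row"), rows = 8L, cols = 12L) {
  traversal <- match.arg(traversal)
  rl <- LETTERS[seq_len(rows)]
  if (traversal == "column") {
    as.vector(vapply(seq_len(cols), function(j) paste0(rl, j), character(rows)))
  } else {
    as.vector(t(vapply(seq_len(cols), function(j) paste0(rl, j), character(rows))))
  }
}

# Round half-up to a pipetting increment; guards against fp noise like
# 2.0000000001 from the division.
round_to_increment <- function(x, increment) {
  round(floor(x / increment + 0.5 + 1e-9) * increment, 6)
}

# Ceiling to an increment (supply volumes never round down).
ceiling_to_increment <- function(x, increment) {
  round(ceiling(x / increment - 1e-9) * increment, 6)
}

# Volumes printed with a fixed number of decimals in all sheets.
format_volume <- function(x, decimals = 1L) {
  formatC(x, format = "f", digits = decimals)
}

# RFC 4180-ish CSV line: quote only when a field contains comma, quote or
# newline; CRLF line endings are appended by the caller.
csv_line <- function(fields) {
  needs <- grepl('[",\r\n]', fields)
  fields[needs] <- paste0('"', gsub('"', '""', fields[needs]), '"')
  paste(fields, collapse = ",")
}

csv_document <- function(header, rows) {
  lines <- c(csv_line(header), vapply(rows, csv_line, character(1)))
  paste0(paste(lines, collapse = "\r\n"), "\r\n")
}

# UTC timestamps throughout, at whole-second resolution (they survive a
# text round trip exactly); display formatting is a presentation concern.
utc_now <- function() {
  as.POSIXct(floor(as.numeric(Sys.time())), origin = "1970-01-01", tz = "UTC")
}

stop_seqfab <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "seqfab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
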