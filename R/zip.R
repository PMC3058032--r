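# Minimal ZIP archive writer: stored (uncompressed) entries with fixed
# timestamps, so the same content always yields byte-identical archives.
# Reading ZIPs goes through utils::unzip (internal implementation).

# CRC-32 (IEEE 802.3), table-driven. R's bitwShiftR treats its argument
# as an unsigned 32-bit integer, which is exactly what the algorithm needs.
crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b[[i]]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# Fixed DOS timestamp (2009-07-01 00:00): archives depend on content only.
DOS_DATE <- bitwOr(bitwOr(bitwShiftL(2009L - 1980L, 9L), bitwShiftL(7L, 5L)), 1L)
DOS_TIME <- 0L

#' Write a ZIP archive from in-memory members
#'
#' Writes a stored (uncompressed) ZIP archive whose members are raw
#' vectors or character scalars (encoded as UTF-8). Member timestamps are
#' fixed, so archives are a pure function of their content — two exports
#' of the same data are byte-identical.
#'
#' @param members Named list; names are member file names, values raw
#'   vectors or single strings.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zip_archive <- function(members, path) {
  if (length(members) == 0L)
    stop_seqfab("refusing to write an empty archive", "seqfab_io_error")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop_seqfab("every archive member needs a name", "seqfab_io_error")
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  metas <- vector("list", length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    data <- members[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
    name <- charToRaw(enc2utf8(names(members)[[i]]))
    crc <- crc32(data)
    local_header <- c(
      u32(0x04034b50), u16(20L), u16(0L), u16(0L),   # sig, version, flags, method
      u16(DOS_TIME), u16(DOS_DATE), u32(crc),
      u32(length(data)), u32(length(data)),          # stored: sizes equal
      u16(length(name)), u16(0L))
    offsets[[i]] <- pos
    writeBin(c(local_header, name, data), con)
    pos <- pos + length(local_header) + length(name) + length(data)
    metas[[i]] <- list(name = name, crc = crc, size = length(data))
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(members)) {
    m <- metas[[i]]
    entry <- c(
      u32(0x02014b50), u16(20L), u16(20L), u16(0L), u16(0L),
      u16(DOS_TIME), u16(DOS_DATE), u32(m$crc), u32(m$size), u32(m$size),
      u16(length(m$name)), u16(0L), u16(0L), u16(0L), u16(0L),
      u32(0L), u32(offsets[[i]]))
    writeBin(c(entry, m$name), con)
    cd_len <- cd_len + length(entry) + length(m$name)
  }
  writeBin(c(u32(0x06054b50), u16(0L), u16(0L),
             u16(length(members)), u16(length(members)),
             u32(cd_len), u32(cd_start), u16(0L)), con)
  invisible(path)
}

# Read every member of a ZIP into named raw vectors (utils::unzip does the
# parsing; this just slurps the extracted files).
read_zip_archive <- function(path) {
  if (!file.exists(path))
    stop_seqfab(sprintf("archive '%s' does not exist", path),
                "seqfab_io_error")
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e)
                        stop_seqfab(sprintf("corrupt or unreadable archive: %s",
                                            conditionMessage(e)),
                                    "seqfab_io_error"))
  exdir <- tempfile("zip_read_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  utils::unzip(path, exdir = exdir)
  members <- list()
  for (nm in listing$Name) {
    if (grepl("/$", nm)) next  # directory entry
    f <- file.path(exdir, nm)
    members[[nm]] <- readBin(f, "raw", n = file.info(f)$size)
  }
  members
}
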