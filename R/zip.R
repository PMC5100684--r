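# Minimal ZIP archive writer (store method, no compression) used for NMX
# containers. Entries are written with correct CRC-32 checksums and a
# central directory, readable by any standard unzip implementation
# (reading uses utils::unzip).

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L              # 0xEDB88320 as signed 32-bit
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b[i]), 255L) + 1L],
                 bitwShiftR(c, 8L))
  bitwXor(c, -1L)
}

# entries: named list of raw vectors (or character, serialized as UTF-8)
write_zip_stored <- function(path, entries) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("all zip entries must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  dos_date <- 33L + 512L           # 1980-01-01 packed DOS date
  centrals <- list()
  for (name in names(entries)) {
    data <- entries[[name]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = "\n"))
    nameb <- charToRaw(name)
    offset <- seek(con)
    crc <- crc32(data)
    u32(67324752)                  # local file header signature
    u16(20); u16(0); u16(0)        # version, flags, method = stored
    u16(0); u16(dos_date)          # mod time/date
    u32(crc); u32(length(data)); u32(length(data))
    u16(length(nameb)); u16(0)
    writeBin(nameb, con)
    writeBin(data, con)
    centrals[[name]] <- list(crc = crc, size = length(data),
                             name = nameb, offset = offset,
                             date = dos_date)
  }
  cd_offset <- seek(con)
  for (e in centrals) {
    u32(33639248)                  # central directory signature
    u16(20); u16(20); u16(0); u16(0)
    u16(0); u16(e$date)
    u32(e$crc); u32(e$size); u32(e$size)
    u16(length(e$name)); u16(0); u16(0)
    u16(0); u16(0); u32(0)
    u32(e$offset)
    writeBin(e$name, con)
  }
  cd_size <- seek(con) - cd_offset
  u32(101010256)                   # end of central directory
  u16(0); u16(0)
  u16(length(centrals)); u16(length(centrals))
  u32(cd_size); u32(cd_offset); u16(0)
  invisible(path)
}
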