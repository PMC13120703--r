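# ---- minimal .npy / .npz support -------------------------------------------
# No installed R package reads the numpy serialization format, so the small
# subset needed for MedMNIST-style archives is implemented here: version 1.x
# headers, little-endian u1/i1/i2/i4/i8/f4/f8 dtypes, C or Fortran order.
# Archives are plain zip files; reading uses utils::unzip, writing emits
# stored (uncompressed) entries directly.

parse_npy_header <- function(con) {
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic), c(0x93L, 0x4eL, 0x55L, 0x4dL, 0x50L, 0x59L))) {
    stop("not a .npy file (bad magic)")
  }
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  hlen <- if (ver[1] >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  list(descr = descr, fortran = fortran, shape = shape)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- parse_npy_header(con)
  n <- if (length(h$shape) == 0L) 1L else prod(h$shape)
  d <- h$descr
  data <- switch(sub("^[<|=]", "", d),
    "u1" = readBin(con, "integer", n, size = 1, signed = FALSE),
    "i1" = readBin(con, "integer", n, size = 1, signed = TRUE),
    "i2" = readBin(con, "integer", n, size = 2, endian = "little"),
    "i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "i8" = {
      lo <- readBin(con, "raw", 8 * n)
      m <- matrix(as.integer(lo), nrow = 8)
      # exact for |value| < 2^53; labels and counts are far below that
      colSums(m * 2^(8 * (0:7)))
    },
    "f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "f8" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported npy dtype: ", d)
  )
  if (length(h$shape) <= 1L) return(data)
  if (h$fortran) {
    array(data, dim = h$shape)
  } else {
    aperm(array(data, dim = rev(h$shape)), rev(seq_along(h$shape)))
  }
}

npy_bytes <- function(x, dtype = NULL) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (is.null(dtype)) {
    dtype <- if (is.integer(x) || all(x == round(x))) {
      if (min(x) >= 0 && max(x) <= 255) "|u1" else "<i4"
    } else "<f8"
  }
  # serialize in C order
  xs <- if (length(d) > 1L) aperm(x, rev(seq_along(d))) else x
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    dtype,
                    if (length(d) == 1L) paste0(d, ",") else paste(d, collapse = ", "))
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- as.vector(xs)
  switch(dtype,
    "|u1" = writeBin(as.integer(v), con, size = 1),
    "<i4" = writeBin(as.integer(v), con, size = 4, endian = "little"),
    "<f8" = writeBin(as.numeric(v), con, size = 8, endian = "little"),
    stop("unsupported write dtype: ", dtype)
  )
  rawConnectionValue(con)
}

write_u16 <- function(con, x) writeBin(as.raw(c(x %% 256, x %/% 256)), con)
write_u32 <- function(con, x) {
  writeBin(as.raw(c(x %% 256, (x %/% 256) %% 256,
                    (x %/% 65536) %% 256, (x %/% 16777216) %% 256)), con)
}

# minimal zip writer: stored (uncompressed) entries only
write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  nm <- names(entries)
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    cr <- cpp_crc32(data)
    crcs[i] <- cr[1] + 65536 * cr[2]
    offsets[i] <- pos
    write_u32(con, 0x04034b50); write_u16(con, 20); write_u16(con, 0)
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u32(con, crcs[i]); write_u32(con, length(data))
    write_u32(con, length(data)); write_u16(con, nchar(nm[i])); write_u16(con, 0)
    writeChar(nm[i], con, eos = NULL)
    writeBin(data, con)
    pos <- pos + 30 + nchar(nm[i]) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    write_u32(con, 0x02014b50); write_u16(con, 20); write_u16(con, 20)
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u32(con, crcs[i]); write_u32(con, length(data))
    write_u32(con, length(data)); write_u16(con, nchar(nm[i]))
    write_u16(con, 0); write_u16(con, 0); write_u16(con, 0); write_u16(con, 0)
    write_u32(con, 0); write_u32(con, offsets[i])
    writeChar(nm[i], con, eos = NULL)
    pos <- pos + 46 + nchar(nm[i])
  }
  write_u32(con, 0x06054b50); write_u16(con, 0); write_u16(con, 0)
  write_u16(con, length(entries)); write_u16(con, length(entries))
  write_u32(con, pos - cd_start); write_u32(con, cd_start)
  write_u16(con, 0)
  invisible(path)
}
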