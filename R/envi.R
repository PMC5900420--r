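#' Write a hypercube as an ENVI image
#'
#' Writes the standard ENVI pair: an ASCII `.hdr` with the wavelength list
#' and a flat binary file in BIL interleave, little-endian 32-bit float.
#'
#' @param cube a [hypercube()].
#' @param path base path; `<path>.hdr` and `<path>.bil` are written.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  rows <- d[1]; cols <- d[2]; bands <- d[3]
  hdr <- c(
    "ENVI",
    "description = {shikimap hypercube}",
    sprintf("samples = %d", cols),
    sprintf("lines = %d", rows),
    sprintf("bands = %d", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(sprintf("%.6f", cube$wavelengths), collapse = ", "),
           " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL stream order: line slowest, then band, samples fastest
  v <- as.numeric(aperm(cube$data, c(2, 3, 1)))
  con <- file(paste0(path, ".bil"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an ENVI image into a hypercube
#'
#' Supports the subset of the format this package writes: BIL/BSQ/BIP
#' interleave, data type 4 (float32) or 5 (float64), byte order 0, with a
#' `wavelength` list in the header.
#'
#' @param path base path as given to [write_envi()], or the `.hdr` path.
#' @return A [hypercube()].
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  base <- sub("\\.hdr$", "", hdr_path)
  bin_path <- if (file.exists(paste0(base, ".bil"))) paste0(base, ".bil")
              else base
  if (!file.exists(hdr_path)) stop("header not found: ", hdr_path)
  if (!file.exists(bin_path)) stop("binary not found: ", bin_path)

  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- parse_envi_header(txt)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("header missing fields: ", paste(miss, collapse = ", "))

  cols <- as.integer(fields[["samples"]])
  rows <- as.integer(fields[["lines"]])
  bands <- as.integer(fields[["bands"]])
  dtype <- as.integer(fields[["data type"]])
  interleave <- tolower(fields[["interleave"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  wl <- if ("wavelength" %in% names(fields)) {
    as.numeric(strsplit(gsub("[{}]", "", fields[["wavelength"]]), ",")[[1]])
  } else seq_len(bands)

  n <- rows * cols * bands
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = size, endian = "little")
  if (length(v) != n) stop("binary shorter than header promises")

  arr <- array(NA_real_, c(rows, cols, bands))
  if (interleave == "bil") {
    # stream order: line, band, sample
    a <- array(v, c(cols, bands, rows))
    arr <- aperm(a, c(3, 1, 2))
  } else if (interleave == "bsq") {
    a <- array(v, c(cols, rows, bands))
    arr <- aperm(a, c(2, 1, 3))
  } else if (interleave == "bip") {
    a <- array(v, c(bands, cols, rows))
    arr <- aperm(a, c(3, 2, 1))
  } else stop("unsupported interleave: ", interleave)
  hypercube(arr, wl)
}

# parse "key = value" lines, honouring multi-line { ... } blocks
parse_envi_header <- function(txt) {
  txt <- gsub("\r", "", txt)
  # fold { ... } blocks onto one line
  out <- list()
  pat <- "(?s)([A-Za-z][A-Za-z0-9 ]*?)\\s*=\\s*(\\{.*?\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.vector(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*$", "", piece))
    val <- trimws(sub("^[^=]*=", "", gsub("\n", " ", piece)))
    out[[tolower(key)]] <- val
  }
  out
}
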