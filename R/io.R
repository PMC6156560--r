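#' Read and write hyperspectral cubes
#'
#' Two on-disk formats are supported.  `"envi"` is the generic exchange
#' format of hyperspectral software: an ASCII `.hdr` header next to a flat
#' binary payload (band-sequential float32, little-endian), with the
#' wavenumber axis in the `wavelength` block and the pixel size in
#' `pixel size`.  The tissue mask, which ENVI has no standard slot for, is
#' written as a plain-text 0/1 grid in a companion `.msk` file and read back
#' when present (missing mask = all tissue).  `"rds"` is R's native
#' serialization and round-trips bit-exactly; ENVI round-trips within
#' float32 quantization.
#'
#' @param path path of the binary payload (ENVI; header is `path + ".hdr"`)
#'   or of the `.rds` file.
#' @param format `"envi"` or `"rds"`.
#' @return `read_cube` returns an [ir_cube()]; `write_cube` returns `path`
#'   invisibly.
#' @name cube_io
NULL

#' @rdname cube_io
#' @param cube an `ir_cube` to write.
#' @export
write_cube <- function(cube, path, format = c("envi", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(cube, "ir_cube"))
  if (format == "rds") {
    saveRDS(unclass(cube), path)
    return(invisible(path))
  }
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {irdenoise hyperspectral cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("pixel size = {", cube$pixel_size, ", ", cube$pixel_size, "}"),
    "wavelength units = cm-1",
    paste0("wavelength = {",
           paste(format(cube$wavenumbers, trim = TRUE, digits = 12),
                 collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: per band, line-by-line (row-major)
  for (k in seq_len(d[3L]))
    writeBin(as.vector(t(cube$data[, , k])), con, size = 4L,
             endian = "little")
  if (!all(cube$mask))
    writeLines(apply(cube$mask * 1L, 1L, paste, collapse = " "),
               paste0(path, ".msk"))
  invisible(path)
}

#' @rdname cube_io
#' @export
read_cube <- function(path, format = c("envi", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    return(ir_cube(x$data, x$wavenumbers, x$mask, x$pixel_size))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  if (!file.exists(path)) stop("ENVI payload not found: ", path)
  h <- parse_envi_header(hdr_path)
  for (f in c("samples", "lines", "bands"))
    if (is.null(h[[f]]) || is.na(suppressWarnings(as.integer(h[[f]]))))
      stop("malformed ENVI header: missing or non-integer field `", f, "`")
  samples <- as.integer(h$samples)
  lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  if (!is.null(h$interleave) && tolower(h$interleave) != "bsq")
    stop("unsupported ENVI interleave `", h$interleave, "` (only bsq)")
  if (!is.null(h[["data type"]]) && as.integer(h[["data type"]]) != 4L)
    stop("unsupported ENVI data type `", h[["data type"]],
         "` (only 4 = float32)")
  if (is.null(h$wavelength))
    stop("malformed ENVI header: missing field `wavelength`")
  wn <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (anyNA(wn) || length(wn) != bands)
    stop("ENVI header field `wavelength` has ", length(wn),
         " entries but `bands` = ", bands)
  n <- samples * lines * bands
  payload_size <- file.info(path)$size
  if (payload_size < 4 * n)
    stop("ENVI payload holds ", payload_size %/% 4L,
         " float32 values but header field `bands` implies ", n)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  arr <- array(NA_real_, c(lines, samples, bands))
  per_band <- samples * lines
  for (k in seq_len(bands)) {
    band <- raw_vals[((k - 1L) * per_band + 1L):(k * per_band)]
    arr[, , k] <- t(matrix(band, samples, lines))
  }
  px <- 1.1
  if (!is.null(h[["pixel size"]]))
    px <- as.numeric(strsplit(h[["pixel size"]], ",")[[1]])[1L]
  mask <- NULL
  msk_path <- paste0(path, ".msk")
  if (file.exists(msk_path)) {
    mask <- as.matrix(utils::read.table(msk_path)) > 0
    dimnames(mask) <- NULL
  }
  ir_cube(arr, wn, mask, px)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  # brace-delimited fields (possibly multi-line)
  m <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1L] != -1L) {
    starts <- as.vector(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*", "", piece))
      val <- sub("^[^{]*\\{", "", piece)
      val <- sub("\\}\\s*$", "", val)
      out[[tolower(key)]] <- gsub("\n", " ", val)
    }
    txt <- gsub("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{[^}]*\\}", "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key)) out[[key]] <- val
  }
  out
}
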