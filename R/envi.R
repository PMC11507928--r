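#' Hyperspectral cube container
#'
#' A `hypercube` bundles a rows x cols x bands reflectance array with its
#' wavelength axis (nm), interleave tag and free-form header metadata. It is
#' the in-memory counterpart of an ENVI header/binary pair.
#'
#' @param data numeric array, dimensions rows x cols x bands.
#' @param wavelengths strictly increasing numeric vector (nm), one per band.
#' @param interleave storage order for on-disk serialization: `"bsq"`
#'   (band-sequential), `"bil"` (band-interleaved-by-line) or `"bip"`
#'   (band-interleaved-by-pixel).
#' @param meta named list of extra header pairs.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, interleave = "bil", meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("wavelength length (", length(wavelengths),
         ") does not match band count (", dim(data)[3L], ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths,
                 interleave = interleave, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              toupper(x$interleave)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# ENVI data type 4 = 32-bit IEEE float; the only type written and the only
# one accepted on read. Byte order 0 = little-endian.
.envi_dtype <- 4L

.envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (cand in c(base, paste0(base, ".raw"), paste0(base, ".dat"),
                 paste0(base, ".img"))) {
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  }
  paste0(base, ".raw")
}

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[1L]))
    stop("not an ENVI header (missing 'ENVI' magic line): ", header_path)
  txt <- paste(lines[-1L], collapse = "\n")
  fields <- list()
  # "key = value" items; values may be multi-line brace-delimited lists
  items <- regmatches(txt, gregexpr(
    "([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt,
    perl = TRUE))[[1L]]
  if (length(items) == 0L) stop("ill-formed ENVI header: ", header_path)
  for (it in items) {
    key <- trimws(sub("=.*$", "", it))
    val <- trimws(sub("^[^=]*=", "", it))
    fields[[tolower(key)]] <- val
  }
  fields
}

.envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header is missing required field '", key, "'")
  as.numeric(v)
}

#' Read an ENVI hyperspectral cube
#'
#' Parses an ENVI text header and its raw binary companion (same basename,
#' or `.raw`/`.dat`/`.img` extension) into a [hypercube]. Only 32-bit
#' little-endian float payloads (ENVI data type 4, byte order 0) are
#' supported, matching what [write_envi()] emits.
#'
#' @param header_path path to the `.hdr` file.
#' @return A [hypercube].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  f <- .parse_envi_header(header_path)
  ns <- as.integer(.envi_num(f, "samples"))  # columns
  nl <- as.integer(.envi_num(f, "lines"))    # rows
  nb <- as.integer(.envi_num(f, "bands"))
  dtype <- as.integer(.envi_num(f, "data type"))
  if (dtype != .envi_dtype)
    stop("unsupported ENVI data type ", dtype, " (only 4 = float32)")
  byte_order <- if (is.null(f[["byte order"]])) 0L else
    as.integer(.envi_num(f, "byte order"))
  if (byte_order != 0L) stop("unsupported ENVI byte order (must be 0)")
  interleave <- tolower(f[["interleave"]] %||% "bsq")
  wl_raw <- f[["wavelength"]]
  if (is.null(wl_raw))
    stop("ENVI header is missing required field 'wavelength'")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1L]])
  if (length(wl) != nb)
    stop("wavelength list length (", length(wl),
         ") disagrees with bands (", nb, ")")
  bin <- .envi_binary_path(header_path)
  if (!file.exists(bin)) stop("binary payload not found for ", header_path)
  n_expected <- as.double(ns) * nl * nb
  if (file.size(bin) != n_expected * 4)
    stop("binary size (", file.size(bin), " bytes) disagrees with header ",
         "dimensions (expected ", n_expected * 4, ")")
  raw <- readBin(bin, what = "numeric", n = n_expected, size = 4L,
                 endian = "little")
  cube <- array(NA_real_, c(nl, ns, nb))
  if (interleave == "bsq") {
    # [col fastest, then row, then band]
    cube <- aperm(array(raw, c(ns, nl, nb)), c(2L, 1L, 3L))
  } else if (interleave == "bil") {
    # col fastest, then band, then row
    cube <- aperm(array(raw, c(ns, nb, nl)), c(3L, 1L, 2L))
  } else if (interleave == "bip") {
    # band fastest, then col, then row
    cube <- aperm(array(raw, c(nb, ns, nl)), c(3L, 2L, 1L))
  } else stop("unknown interleave '", interleave, "'")
  hypercube(cube, wl, interleave = interleave,
            meta = f[setdiff(names(f), c("samples", "lines", "bands",
                                         "data type", "byte order",
                                         "interleave", "wavelength"))])
}

#' Write an ENVI hyperspectral cube
#'
#' Serializes a [hypercube] as an ENVI text header plus raw little-endian
#' 32-bit float binary (basename + `.raw`).
#'
#' @param cube a [hypercube].
#' @param header_path output path for the `.hdr` file.
#' @return Invisibly, the binary path written.
#' @export
write_envi <- function(cube, header_path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  bin <- paste0(sub("\\.hdr$", "", header_path), ".raw")
  x <- cube$data
  v <- switch(cube$interleave,
    bsq = as.vector(aperm(x, c(2L, 1L, 3L))),
    bil = as.vector(aperm(x, c(2L, 3L, 1L))),
    bip = as.vector(aperm(x, c(3L, 2L, 1L))))
  hdr <- c(
    "ENVI",
    "description = {hsigrade export}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", .envi_dtype),
    sprintf("interleave = %s", cube$interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, scientific = FALSE),
                  collapse = ", ")))
  con <- try(file(header_path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write header: ", header_path)
  writeLines(hdr, con); close(con)
  writeBin(as.numeric(v), bin, size = 4L, endian = "little")
  invisible(bin)
}
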