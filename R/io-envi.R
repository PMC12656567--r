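# ENVI-format cube I/O: flat binary payload (BSQ interleave) plus a text
# header carrying samples/lines/bands, data type, wavelengths, the no-data
# value and a simple map info record. Little-endian ("byte order = 0").

envi_data_types <- c(`2` = "int16", `4` = "float32", `5` = "float64")

write_envi_header <- function(hdr_path, d, data_type, cube) {
  wl <- paste(format(cube$wavelengths_nm, trim = TRUE, scientific = FALSE),
              collapse = ", ")
  lines <- c(
    "ENVI",
    "description = {grassunmix spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bsq",
    "byte order = 0",
    sprintf("data ignore value = %d", cube$sentinel),
    sprintf("reflectance scale factor = %d", cube$scale_factor),
    sprintf("map info = {Local, 1, 1, %.6f, %.6f, %.6f, %.6f, %s}",
            cube$origin_xy[1], cube$origin_xy[2], cube$pixel_size_m,
            cube$pixel_size_m, cube$crs_label),
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}", wl))
  writeLines(lines, hdr_path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get1 <- function(key, numeric = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key,
                                        "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    v <- trimws(m[2])
    if (numeric) as.numeric(v) else v
  }
  getbrace <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key,
                                        "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    trimws(strsplit(m[2], ",")[[1]])
  }
  list(samples = get1("samples"), lines = get1("lines"),
       bands = get1("bands"), data_type = get1("data type"),
       interleave = tolower(get1("interleave", numeric = FALSE) %||% "bsq"),
       byte_order = get1("byte order") %||% 0,
       ignore = get1("data ignore value"),
       scale = get1("reflectance scale factor"),
       map_info = getbrace("map info"),
       wavelength = suppressWarnings(as.numeric(getbrace("wavelength"))))
}

write_cube_envi <- function(cube, path) {
  d <- dim(cube$reflectance)
  hdr <- paste0(path, ".hdr")
  # store as scaled int16 with the sentinel written verbatim
  sc <- round(cube$reflectance * cube$scale_factor)
  sent_refl <- cube$sentinel / cube$scale_factor
  sc[abs(cube$reflectance - sent_refl) < 0.5 / cube$scale_factor] <-
    cube$sentinel
  sc[!is.finite(sc)] <- cube$sentinel
  sc <- pmax(pmin(sc, 32767), -32768)
  # BSQ: band-sequential, row-major within band (line by line)
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.integer(t(sc[, , b])), con, size = 2, endian = "little")
  write_envi_header(hdr, d, 2L, cube)
  path
}

read_cube_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(path)) stop("missing ENVI payload: ", path)
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$samples) || is.null(h$lines) || is.null(h$bands))
    stop("corrupt ENVI header: missing dimensions")
  if (!h$interleave %in% "bsq")
    stop("unsupported interleave: ", h$interleave)
  if (is.null(h$wavelength))
    stop("ENVI header carries no wavelength array and none was supplied")
  if (length(h$wavelength) != h$bands)
    stop("wavelength count (", length(h$wavelength),
         ") does not match declared bands (", h$bands, ")")
  bytes <- switch(as.character(h$data_type), `2` = 2L, `4` = 4L, `5` = 8L,
                  stop("unsupported ENVI data type: ", h$data_type))
  expected <- h$samples * h$lines * h$bands * bytes
  actual <- file.info(path)$size
  if (actual != expected)
    stop(sprintf(
      "ENVI payload size mismatch: header declares %d samples x %d lines x %d bands (%d bytes) but file has %d bytes",
      h$samples, h$lines, h$bands, expected, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  n <- h$samples * h$lines * h$bands
  raw_vals <- if (bytes == 2)
    readBin(con, integer(), n = n, size = 2, endian = "little")
  else readBin(con, numeric(), n = n, size = bytes, endian = "little")
  # payload is line-major within band; transpose back to R column-major
  arr <- array(NA_real_, c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    block <- raw_vals[((b - 1) * per_band + 1):(b * per_band)]
    arr[, , b] <- t(matrix(block, h$samples, h$lines))
  }
  scale <- h$scale %||% 1
  sentinel <- h$ignore %||% -9999
  pixel_valid <- !apply(arr == sentinel, c(1, 2), any)
  refl <- arr / scale
  mi <- h$map_info
  origin <- c(0, 0)
  px <- 1
  crs <- "local"
  if (!is.null(mi) && length(mi) >= 7) {
    origin <- as.numeric(mi[4:5])
    px <- as.numeric(mi[6])
    crs <- mi[length(mi)]
  }
  spectral_cube(refl, h$wavelength, pixel_valid = pixel_valid,
                pixel_size_m = px, origin_xy = origin, crs_label = crs,
                scale_factor = scale, sentinel = sentinel)
}
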