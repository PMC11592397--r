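#' Read a volume from an NRRD file
#'
#' Supports attached and detached headers, `raw` and `gzip` encodings,
#' little-endian scalar types (`uint8`, `int8`, `int16`, `uint16`, `int32`,
#' `float`, `double`), and geometry given either as `space directions` /
#' `space origin` or as `spacings`. Axis-aligned space directions only.
#'
#' @param path path to a `.nrrd` (attached) or `.nhdr` (detached) file.
#' @return a [pr_volume()].
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file (bad magic): ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed NRRD header: no blank line before data")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("malformed NRRD header line: ", line)
    hdr[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(f) {
    if (is.null(hdr[[f]])) stop("NRRD header missing required field: ", f)
    hdr[[f]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("only 3D NRRD supported (field 'dimension')")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- tolower(need("encoding"))
  tinfo <- switch(type,
    "uint8" = , "uchar" = , "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    "int8" = , "signed char" = list(what = "integer", size = 1, signed = TRUE),
    "int16" = , "short" = list(what = "integer", size = 2, signed = TRUE),
    "uint16" = , "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
    "int32" = , "int" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  endian <- tolower(hdr[["endian"]] %||% "little")
  if (tinfo$size > 1 && endian != "little")
    stop("unsupported NRRD endian: ", endian)
  n <- prod(sizes)
  if (!is.null(hdr[["data file"]]) || !is.null(hdr[["datafile"]])) {
    dfile <- hdr[["data file"]] %||% hdr[["datafile"]]
    dpath <- file.path(dirname(path), dfile)
    raw_data <- readBin(dpath, "raw", n = file.size(dpath))
  } else {
    raw_data <- readBin(con, "raw", n = file.size(path))
  }
  if (enc == "gzip" || enc == "gz") {
    raw_data <- memDecompress(raw_data, type = "gzip")
  } else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  vals <- readBin(raw_data, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = "little")
  if (length(vals) != n) stop("NRRD data truncated: expected ", n, " values")
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    if (length(vecs) != 3L) stop("malformed 'space directions'")
    dirs <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    offdiag <- dirs; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9)) stop("only axis-aligned 'space directions' supported")
    spacing <- abs(diag(dirs))
  } else if (!is.null(hdr[["spacings"]])) {
    spacing <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]), ",")[[1]])
  pr_volume(array(as.numeric(vals), sizes), spacing, origin)
}

#' Write a volume to an NRRD file
#'
#' Writes an attached-header NRRD0004 file with axis-aligned geometry.
#'
#' @param vol a [pr_volume()].
#' @param path output path.
#' @param type scalar type, `"double"` (default) or `"uint8"` (for 0/1 masks).
#' @param encoding `"gzip"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(vol, path, type = c("double", "uint8"),
                       encoding = c("gzip", "raw")) {
  stopifnot(inherits(vol, "pr_volume"))
  type <- match.arg(type); encoding <- match.arg(encoding)
  d <- dim(vol$values)
  if (type == "uint8" && !all(vol$values %in% c(0, 1)))
    stop("uint8 output requires a 0/1 mask volume")
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing_mm[1], vol$spacing_mm[2], vol$spacing_mm[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin_mm[1], vol$origin_mm[2], vol$origin_mm[3]),
    if (type != "uint8") "endian: little",
    sprintf("encoding: %s", encoding),
    "")
  payload <- if (type == "uint8") {
    as.raw(as.integer(vol$values))
  } else {
    writeBin(as.numeric(vol$values), raw(), size = 8, endian = "little")
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
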