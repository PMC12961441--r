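# PLY reader/writer for labeled clouds. Supported dialects: ASCII 1.0 and
# binary_little_endian 1.0, vertex properties x,y,z (float) with optional
# red,green,blue (uchar) and label (int). Unknown vertex properties are parsed
# and dropped; non-vertex elements (e.g. faces) are ignored on read.

.ply_type_info <- function(type) {
  switch(type,
    "char" = , "int8" = list(what = "integer", size = 1L, signed = TRUE),
    "uchar" = , "uint8" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4L, signed = TRUE),
    "uint" = , "uint32" = list(what = "integer", size = 4L, signed = TRUE),
    "float" = , "float32" = list(what = "numeric", size = 4L, signed = TRUE),
    "double" = , "float64" = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type)
  )
}

#' Read a labeled cloud from a PLY file
#'
#' Accepts ASCII and binary-little-endian PLY with vertex properties
#' \code{x,y,z} (required) and optional \code{red,green,blue} and
#' \code{label}. Missing colors default to (0,0,0); a missing label property
#' defaults to the ignore label \code{-1}.
#'
#' @param path path to a PLY file.
#' @param pot_id,timepoint metadata attached to the returned cloud; `pot_id`
#'   defaults to the file name without extension.
#' @return a [labeled_cloud()].
#' @export
read_ply <- function(path, pot_id = NULL, timepoint = NULL) {
  if (!file.exists(path)) stop("cannot read PLY file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  header_lines <- character()
  fmt <- NULL; nvert <- NULL
  props <- list()          # vertex property list: name -> type
  in_vertex <- FALSE
  data_start <- NULL
  last <- 0L
  for (pos in nl) {
    line <- rawToChar(raw[(last + 1L):(pos - 1L)])
    line <- sub("\r$", "", line)
    last <- pos
    header_lines <- c(header_lines, line)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- identical(tok[2], "vertex")
      if (in_vertex) nvert <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex) {
      if (identical(tok[2], "list")) stop("list properties on vertices are not supported")
      props[[tok[3]]] <- tok[2]
    }
    if (tok[1] == "end_header") { data_start <- pos; break }
  }
  if (!identical(header_lines[1], "ply")) stop("not a PLY file: ", path)
  if (is.null(fmt) || is.null(nvert) || is.null(data_start))
    stop("malformed PLY header in ", path)
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (!all(c("x", "y", "z") %in% names(props)))
    stop("PLY file lacks x/y/z vertex properties: ", path)

  nm <- names(props)
  if (fmt == "ascii") {
    txt <- rawToChar(raw[(data_start + 1L):length(raw)])
    vals <- scan(text = txt, what = numeric(), n = nvert * length(props), quiet = TRUE)
    m <- matrix(vals, nrow = nvert, ncol = length(props), byrow = TRUE)
    colnames(m) <- nm
  } else {
    sizes <- vapply(nm, function(p) .ply_type_info(props[[p]])$size, integer(1))
    rowbytes <- sum(sizes)
    body <- raw[(data_start + 1L):(data_start + rowbytes * nvert)]
    bm <- matrix(body, nrow = rowbytes, ncol = nvert)
    off <- cumsum(c(0L, sizes))
    m <- matrix(0, nvert, length(nm), dimnames = list(NULL, nm))
    for (i in seq_along(nm)) {
      ti <- .ply_type_info(props[[nm[i]]])
      bytes <- as.vector(bm[(off[i] + 1L):(off[i] + sizes[i]), , drop = FALSE])
      v <- readBin(bytes, ti$what, n = nvert, size = ti$size,
                   signed = if (ti$size < 4L) ti$signed else TRUE,
                   endian = "little")
      m[, i] <- as.numeric(v)
    }
  }
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  cols <- if (all(c("red", "green", "blue") %in% nm))
    m[, c("red", "green", "blue"), drop = FALSE] else NULL
  labs <- if ("label" %in% nm) as.integer(m[, "label"]) else NULL
  if (is.null(pot_id)) pot_id <- sub("\\.[Pp][Ll][Yy]$", "", basename(path))
  labeled_cloud(pts, cols, labs, pot_id = pot_id, timepoint = timepoint)
}

#' Write a labeled cloud to a PLY file
#'
#' Writes vertex properties x,y,z (float32), red,green,blue (uchar) and label
#' (int32). The binary-little-endian dialect is the default for compactness;
#' ASCII is available for interchange and inspection.
#'
#' @param cloud a [labeled_cloud()].
#' @param path output path.
#' @param binary write binary-little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment written by ptv2fr",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "property int label",
    "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    xyz <- writeBin(as.vector(t(cloud$points)), raw(), size = 4L, endian = "little")
    xyz <- matrix(xyz, nrow = 12L)                     # 12 bytes per point
    rgb <- matrix(as.raw(as.vector(t(cloud$colors))), nrow = 3L)
    lab <- writeBin(as.integer(cloud$labels), raw(), size = 4L, endian = "little")
    lab <- matrix(lab, nrow = 4L)
    writeBin(as.vector(rbind(xyz, rgb, lab)), con)
  } else {
    lines <- sprintf("%.9g %.9g %.9g %d %d %d %d",
                     cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                     cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3],
                     cloud$labels)
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  }
  invisible(path)
}
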