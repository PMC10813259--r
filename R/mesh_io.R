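# Bone-surface point input: minimal STL and PLY vertex readers (ASCII
# and binary little-endian). Only vertex coordinates are extracted --
# the geometry operations consume point sets, not connectivity.

#' Read vertex coordinates from an STL surface file
#'
#' Supports ASCII (`solid ... vertex x y z ...`) and binary STL. Returns
#' the raw triangle-soup vertices; pass `unique = TRUE` to deduplicate
#' shared corners.
#'
#' @param path STL file path.
#' @param unique drop duplicated vertices (default TRUE).
#' @return n x 3 numeric matrix of coordinates (mm).
#' @export
read_stl_points <- function(path, unique = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", 80L)
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid")
  if (is_ascii) {
    # some binary files start with "solid" too: verify by size
    ntri_raw <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    expected <- 80L + 4L + 50 * as.numeric(ntri_raw)
    if (!is.na(ntri_raw) && file.size(path) == expected) is_ascii <- FALSE
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vx) == 0L) stop("no vertices found in ASCII STL: ", path)
    parts <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"),
                                   function(p) as.numeric(p[2:4])))
    V <- parts
  } else {
    seek(con, 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (is.na(ntri) || ntri <= 0L) stop("invalid binary STL: ", path)
    rec <- readBin(con, "raw", 50L * ntri)
    # each 50-byte record: 12 floats (normal + 3 vertices) + 2 spare bytes
    idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L +
      rep(seq_len(48L), times = ntri)
    floats <- readBin(rec[idx], "numeric", n = 12L * ntri, size = 4L,
                      endian = "little")
    M <- matrix(floats, ncol = 12L, byrow = TRUE)
    V <- rbind(M[, 4:6, drop = FALSE], M[, 7:9, drop = FALSE],
               M[, 10:12, drop = FALSE])
  }
  colnames(V) <- c("x", "y", "z")
  if (unique) V <- base::unique(V)
  V
}

#' Read vertex coordinates from a PLY surface file
#'
#' Supports `format ascii` and `format binary_little_endian` PLY files
#' whose vertex element starts with float/double `x`, `y`, `z`
#' properties.
#'
#' @param path PLY file path.
#' @return n x 3 numeric matrix of coordinates (mm).
#' @export
read_ply_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  if (read_line() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; n_vert <- NULL
  vprops <- character(0); vtypes <- character(0)
  in_vertex <- FALSE
  repeat {
    ln <- read_line()
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "end_header") break
    if (tok[1L] == "format") fmt <- tok[2L]
    if (tok[1L] == "element") {
      in_vertex <- tok[2L] == "vertex"
      if (in_vertex) n_vert <- as.integer(tok[3L])
    }
    if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list") stop("list properties on vertices unsupported")
      vtypes <- c(vtypes, tok[2L]); vprops <- c(vprops, tok[3L])
    }
  }
  if (is.null(n_vert) || !all(c("x", "y", "z") %in% vprops))
    stop("PLY file lacks x/y/z vertex properties: ", path)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (identical(fmt, "ascii")) {
    vals <- matrix(NA_real_, n_vert, length(vprops))
    for (i in seq_len(n_vert))
      vals[i, ] <- as.numeric(strsplit(trimws(read_line()),
                                       "\\s+")[[1L]][seq_along(vprops)])
  } else if (identical(fmt, "binary_little_endian")) {
    sz <- sizes[vtypes]
    if (anyNA(sz)) stop("unsupported vertex property type in ", path)
    rec_len <- sum(sz)
    blob <- readBin(con, "raw", n_vert * rec_len)
    offs <- cumsum(c(0L, sz[-length(sz)]))
    vals <- matrix(NA_real_, n_vert, length(vprops))
    for (j in seq_along(vprops)) {
      idx <- rep((seq_len(n_vert) - 1L) * rec_len + offs[j],
                 each = sz[j]) + rep(seq_len(sz[j]), times = n_vert)
      what <- if (vtypes[j] %in% c("float", "float32", "double",
                                   "float64")) "numeric" else "integer"
      vals[, j] <- readBin(blob[idx], what, n = n_vert, size = sz[j],
                           endian = "little",
                           signed = !(vtypes[j] %in%
                                        c("uchar", "uint8", "ushort",
                                          "uint16")))
    }
  } else stop("unsupported PLY format: ", fmt)
  V <- vals[, match(c("x", "y", "z"), vprops), drop = FALSE]
  colnames(V) <- c("x", "y", "z")
  V
}
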