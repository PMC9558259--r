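#' Read a point cloud from PLY or PCD
#'
#' Supports ASCII PLY, binary little-endian PLY (vertex element with
#' `x`, `y`, `z` and optional `red`, `green`, `blue` properties) and ASCII
#' PCD (`FIELDS x y z [rgb]`, with `rgb` either float-packed or unsigned).
#'
#' @param path file path.
#' @param format `"auto"` (by extension, default), `"ply"` or `"pcd"`.
#' @param frame frame tag to stamp on the cloud (clouds straight from a
#'   top-view sensor are `"camera"`; see [to_world_frame()]).
#' @return a [point_cloud].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "pcd"),
                             frame = c("camera", "world")) {
  format <- match.arg(format)
  frame <- match.arg(frame)
  if (!file.exists(path)) stop("cannot open point-cloud file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (format == "ply") read_ply(path, frame) else read_pcd(path, frame)
}

#' Write a point cloud to PLY or PCD
#'
#' ASCII PLY is the canonical interchange dialect; ASCII PCD is also
#' offered. Color properties are written only when the cloud has colors.
#' Round-tripping through [read_point_cloud()] preserves point order and
#' colors exactly and positions to better than 1e-6 m.
#'
#' @param cloud a non-empty [point_cloud].
#' @param path output file path.
#' @param format `"ply"` (default) or `"pcd"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("ply", "pcd")) {
  format <- match.arg(format)
  if (!inherits(cloud, "point_cloud")) stop("cloud must be a point_cloud")
  if (n_points(cloud) == 0L) stop("refusing to write an empty cloud")
  if (format == "ply") write_ply(cloud, path) else write_pcd(cloud, path)
  invisible(path)
}

# ---------------------------------------------------------------------- PLY

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path, frame) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()  # name -> list(count, props = data.frame(name, type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header truncated in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format field: ", fmt)
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              names = character(0), types = character(0))
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        stop("unsupported PLY list property in element '", cur, "'")
      if (!tok[2] %in% names(ply_type_size))
        stop("unsupported PLY property type: ", tok[2])
      elements[[cur]]$names <- c(elements[[cur]]$names, tok[3])
      elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elements$vertex)) stop("PLY file has no vertex element")
  ve <- elements$vertex
  if (!all(c("x", "y", "z") %in% ve$names))
    stop("PLY vertex element lacks x/y/z properties")
  if (length(elements) > 1L && names(elements)[1] != "vertex")
    stop("unsupported PLY layout: vertex is not the first element")
  n <- ve$count
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * length(ve$names), quiet = TRUE)
    m <- matrix(vals, nrow = n, ncol = length(ve$names), byrow = TRUE)
  } else {
    sizes <- ply_type_size[ve$types]
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = n * rec)
    if (length(raw) < n * rec) stop("PLY binary payload truncated in ", path)
    m <- matrix(0, nrow = n, ncol = length(ve$names))
    off <- 0L
    for (j in seq_along(ve$names)) {
      sel <- as.vector(outer(seq_len(sizes[j]), (seq_len(n) - 1L) * rec,
                             function(a, b) a + b + off))
      bytes <- raw[sel]
      ty <- ve$types[j]
      m[, j] <- if (ty %in% c("float", "float32", "double", "float64")) {
        readBin(bytes, "double", n = n, size = sizes[j], endian = "little")
      } else {
        readBin(bytes, "integer", n = n, size = sizes[j], endian = "little",
                signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
      }
      off <- off + sizes[j]
    }
  }
  colnames(m) <- ve$names
  cols <- NULL
  if (all(c("red", "green", "blue") %in% ve$names))
    cols <- m[, c("red", "green", "blue"), drop = FALSE]
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], colors = cols, frame = frame)
}

write_ply <- function(cloud, path) {
  n <- n_points(cloud)
  hdr <- c("ply", "format ascii 1.0", paste("element vertex", n),
           "property float x", "property float y", "property float z")
  if (has_colors(cloud))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, "end_header")
  pos <- sprintf("%.9g", t(cloud$positions))
  body <- if (has_colors(cloud)) {
    m <- rbind(matrix(pos, nrow = 3), t(cloud$colors))
    apply(m, 2, paste, collapse = " ")
  } else {
    apply(matrix(pos, nrow = 3), 2, paste, collapse = " ")
  }
  writeLines(c(hdr, body), path)
}

# ---------------------------------------------------------------------- PCD

read_pcd <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  hend <- grep("^DATA\\b", lines)[1]
  if (is.na(hend)) stop("not an ASCII PCD file (no DATA line): ", path)
  hdr <- lines[seq_len(hend)]
  get <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(ln[1]), "\\s+")[[1]][-1]
  }
  if (!identical(tolower(get("DATA")), "ascii"))
    stop("unsupported PCD DATA encoding (only ascii)")
  fields <- get("FIELDS")
  types <- get("TYPE")
  if (is.null(fields) || !all(c("x", "y", "z") %in% fields))
    stop("PCD file lacks x/y/z fields")
  npts <- as.integer((get("POINTS") %||% get("WIDTH"))[1])
  body <- lines[-seq_len(hend)]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = body, what = numeric(), quiet = TRUE)
  m <- matrix(vals, ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  if (!is.na(npts) && nrow(m) != npts)
    stop("PCD point count mismatch: header says ", npts, ", body has ", nrow(m))
  cols <- NULL
  if ("rgb" %in% fields) {
    v <- m[, "rgb"]
    ty <- if (!is.null(types)) types[match("rgb", fields)] else "F"
    packed <- if (identical(ty, "F")) {
      readBin(writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
              "integer", n = length(v), size = 4L, endian = "little")
    } else as.integer(v)
    cols <- cbind(bitwAnd(bitwShiftR(packed, 16L), 255L),
                  bitwAnd(bitwShiftR(packed, 8L), 255L),
                  bitwAnd(packed, 255L))
  }
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], colors = cols, frame = frame)
}

write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  withc <- has_colors(cloud)
  fields <- if (withc) "x y z rgb" else "x y z"
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", fields),
           paste("SIZE", if (withc) "4 4 4 4" else "4 4 4"),
           paste("TYPE", if (withc) "F F F U" else "F F F"),
           paste("COUNT", if (withc) "1 1 1 1" else "1 1 1"),
           paste("WIDTH", n), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n), "DATA ascii")
  pos <- matrix(sprintf("%.9g", t(cloud$positions)), nrow = 3)
  body <- if (withc) {
    packed <- bitwShiftL(cloud$colors[, 1], 16L) +
      bitwShiftL(cloud$colors[, 2], 8L) + cloud$colors[, 3]
    paste(pos[1, ], pos[2, ], pos[3, ], packed)
  } else paste(pos[1, ], pos[2, ], pos[3, ])
  writeLines(c(hdr, body), path)
}
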