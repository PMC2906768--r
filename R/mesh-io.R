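#' Read a triangular mesh from STL, OBJ or PLY
#'
#' Format is inferred from the file extension unless given. STL (binary and
#' ASCII) is read as triangle soup and duplicate vertices are merged; OBJ and
#' PLY (ASCII, and binary little/big endian PLY) keep their vertex indexing.
#'
#' @param path file path.
#' @param format one of \code{"stl"}, \code{"obj"}, \code{"ply"}; default
#'   taken from the extension.
#' @return a \code{tc_mesh}.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         stl = read_stl(path),
         obj = read_obj(path),
         ply = read_ply(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangular mesh to STL, OBJ or PLY
#'
#' @param mesh a \code{tc_mesh}.
#' @param path output path.
#' @param format one of \code{"stl"}, \code{"obj"}, \code{"ply"}; default from
#'   the extension.
#' @param binary for STL: write the 50-byte-record binary layout (default);
#'   otherwise ASCII. PLY and OBJ are written as ASCII.
#' @param quality optional per-vertex scalar written as a PLY
#'   \code{quality} property (e.g. a curvature channel for color mapping).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE,
                       quality = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, quality = quality),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

is_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  if (length(header) < 80L) return(FALSE)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(ntri) == 0L) return(FALSE)
  expected <- 84 + 50 * as.numeric(ntri)
  # ASCII files start with "solid" and will not match the size equation.
  file.size(path) == expected
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", 50L * ntri)
    m <- matrix(rec, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                  n = 12L * ntri, endian = "little")
    fm <- matrix(fl, ncol = 12L, byrow = TRUE)  # normal xyz + 3 vertices
    v <- matrix(t(fm[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L) stop("no vertices found in ASCII STL: ", path)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    v <- do.call(rbind, nums)
    if (nrow(v) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
  }
  ntri <- nrow(v) / 3L
  tri <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  tc_mesh(v, tri)
}

write_stl <- function(mesh, path, binary = TRUE) {
  tn <- triangle_normals(mesh)$normals
  tri <- mesh$triangles
  V <- mesh$vertices
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
    for (t in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(tn[t, ], t(V[tri[t, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid toothcarve", con)
    for (t in seq_len(nrow(tri))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         tn[t, 1L], tn[t, 2L], tn[t, 3L]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- V[tri[t, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1L], p[2L], p[3L]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid toothcarve", con)
  }
  invisible(path)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  if (length(vl) == 0L || length(fl) == 0L) stop("empty or faceless OBJ: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x[-1L], "/"), `[[`, "", 1L))
    idx
  })
  tri <- do.call(rbind, lapply(faces, function(f) {
    if (length(f) < 3L) stop("OBJ face with fewer than 3 vertices")
    # fan-triangulate polygons
    cbind(f[1L], f[seq(2L, length(f) - 1L)], f[seq(3L, length(f))])
  }))
  tc_mesh(v, tri)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1L],
                     mesh$triangles[, 2L], mesh$triangles[, 3L]), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readBin(con, "raw", 1L)
    line <- raw(0)
    while (length(ln) == 1L && ln != as.raw(10L)) {
      line <- c(line, ln)
      ln <- readBin(con, "raw", 1L)
    }
    s <- rawToChar(line)
    s <- sub("\r$", "", s)
    header <- c(header, s)
    if (s == "end_header") break
    if (length(ln) == 0L) stop("PLY header not terminated")
  }
  fmt_line <- grep("^format ", header, value = TRUE)[1L]
  fmt <- strsplit(fmt_line, "\\s+")[[1L]][2L]
  elems <- grep("^element ", header)
  get_count <- function(name) {
    ln <- grep(paste0("^element ", name, " "), header, value = TRUE)
    if (length(ln) == 0L) return(0L)
    as.integer(strsplit(ln[1L], "\\s+")[[1L]][3L])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  if (nv == 0L || nf == 0L) stop("PLY without vertices or faces: ", path)
  # vertex property layout
  velem <- grep("^element vertex", header)
  vprops <- character(0)
  for (i in seq((velem + 1L), length(header))) {
    if (!startsWith(header[i], "property")) break
    vprops <- c(vprops, header[i])
  }
  pparts <- strsplit(vprops, "\\s+")
  ptypes <- vapply(pparts, `[[`, "", 2L)
  pnames <- vapply(pparts, function(x) x[[length(x)]], "")
  if (!all(c("x", "y", "z") %in% pnames)) stop("PLY vertex element lacks x/y/z")

  type_size <- function(t) switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                                  float = 4L, float32 = 4L,
                                  double = 8L, float64 = 8L,
                                  stop("unsupported PLY property type: ", t))
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    vlines <- rest[seq_len(nv)]
    flines <- rest[nv + seq_len(nf)]
    vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    v <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    tri <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
      n <- as.integer(x[1L])
      f <- as.integer(x[1L + seq_len(n)]) + 1L
      cbind(f[1L], f[seq(2L, n - 1L)], f[seq(3L, n)])
    }))
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    sizes <- vapply(ptypes, type_size, 0L)
    v <- matrix(0, nv, 3L)
    for (k in seq_len(nv)) {
      row <- numeric(length(ptypes))
      for (j in seq_along(ptypes)) {
        isfloat <- ptypes[j] %in% c("float", "float32", "double", "float64")
        row[j] <- if (isfloat) {
          readBin(con, "numeric", 1L, size = sizes[j], endian = endian)
        } else {
          readBin(con, "integer", 1L, size = sizes[j], endian = endian)
        }
      }
      v[k, ] <- row[match(c("x", "y", "z"), pnames)]
    }
    # face list property: assume "property list uchar int vertex_indices"
    fl <- grep("^element face", header)
    lprop <- strsplit(header[fl + 1L], "\\s+")[[1L]]
    cnt_size <- type_size(lprop[3L])
    idx_size <- type_size(lprop[4L])
    tris <- vector("list", nf)
    for (k in seq_len(nf)) {
      n <- readBin(con, "integer", 1L, size = cnt_size, endian = endian,
                   signed = cnt_size > 1L)
      f <- readBin(con, "integer", n, size = idx_size, endian = endian) + 1L
      tris[[k]] <- cbind(f[1L], f[seq(2L, n - 1L)], f[seq(3L, n)])
    }
    tri <- do.call(rbind, tris)
  }
  tc_mesh(v, tri)
}

write_ply <- function(mesh, path, quality = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("ply", "format ascii 1.0", "comment toothcarve",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z"), con)
  if (!is.null(quality)) {
    stopifnot(length(quality) == nv)
    writeLines("property float quality", con)
  }
  writeLines(c(sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (is.null(quality)) {
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %.9g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L], quality), con)
  }
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L), con)
  invisible(path)
}

# Canonical topology/geometry hash used in round-trip tests: sorted vertex
# coordinates plus sorted canonicalized triangle corner coordinates.
mesh_canonical_hash <- function(mesh, digits = 6L) {
  v <- round(mesh$vertices, digits)
  vkey <- sort(paste(v[, 1L], v[, 2L], v[, 3L]))
  tri <- mesh$triangles
  tkey <- apply(tri, 1L, function(t) {
    pts <- round(mesh$vertices[t, , drop = FALSE], digits)
    paste(sort(paste(pts[, 1L], pts[, 2L], pts[, 3L])), collapse = "|")
  })
  paste(c(vkey, sort(tkey)), collapse = ";")
}
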