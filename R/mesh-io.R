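# Mesh file I/O: Wavefront OBJ (v/f/g lines, groups carry region labels),
# ascii PLY, and STL (ascii + binary). Readers tolerate comments and blank
# lines; OBJ indices are converted between the format's 1-based convention
# and the in-memory representation at this boundary.

#' Load a triangle mesh from OBJ, PLY or STL
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default guesses from the
#'   file extension.
#' @return a [trimesh()]; OBJ group (`g`) lines populate `face_labels`.
#'   STL facets are welded on exact coordinate equality.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read mesh file '%s'", path))
  format <- match.arg(tolower(format %||% tools::file_ext(path)),
                      c("obj", "ply", "stl"))
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Save a triangle mesh to OBJ, PLY or STL
#'
#' Vertex order is preserved for OBJ and PLY (round-trip identity up to
#' float formatting). OBJ output emits one `g` group per region label when
#' labels are present. STL stores independent facets; re-importing welds
#' vertices on exact coordinate equality.
#'
#' @param mesh a `trimesh`.
#' @param path output path.
#' @param format `"obj"`, `"ply"` or `"stl"` (default from extension).
#' @param binary for STL only: write the binary layout (default `FALSE`).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  validate_trimesh(mesh)
  format <- match.arg(tolower(format %||% tools::file_ext(path)),
                      c("obj", "ply", "stl"))
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path, binary = binary))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  verts <- list(); faces <- list(); labels <- character(0)
  group <- NA_character_
  for (k in seq_along(lines)) {
    toks <- strsplit(lines[[k]], "[[:space:]]+")[[1L]]
    tag <- toks[1L]
    if (tag == "v") {
      xyz <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(xyz)) stop(sprintf("OBJ line %d: malformed vertex record", k))
      verts[[length(verts) + 1L]] <- xyz
    } else if (tag == "f") {
      idx <- toks[-1L]
      if (length(idx) != 3L)
        stop(sprintf("OBJ line %d: non-triangular face (%d vertices)", k, length(idx)))
      # tolerate v/vt/vn references; only the vertex index is used
      iv <- suppressWarnings(as.integer(sub("/.*$", "", idx)))
      if (anyNA(iv)) stop(sprintf("OBJ line %d: malformed face record", k))
      faces[[length(faces) + 1L]] <- iv
      labels <- c(labels, group)
    } else if (tag == "g") {
      group <- if (length(toks) > 1L) toks[2L] else NA_character_
    }
    # o, s, usemtl, mtllib, vn, vt are ignored
  }
  v <- do.call(rbind, verts) %||% matrix(numeric(0), 0L, 3L)
  f <- do.call(rbind, faces) %||% matrix(integer(0), 0L, 3L)
  if (nrow(f) > 0L && (any(f < 1L) || any(f > nrow(v))))
    stop(sprintf("OBJ face %d references out-of-range vertex index",
                 which(apply(f < 1L | f > nrow(v), 1L, any))[1L]))
  trimesh(v, f, face_labels = if (any(!is.na(labels))) labels)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %s %s %s",
                     fmt_num(mesh$vertices[, 1L]),
                     fmt_num(mesh$vertices[, 2L]),
                     fmt_num(mesh$vertices[, 3L])), con)
  f <- mesh$faces
  lab <- mesh$face_labels
  if (is.null(lab)) {
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else {
    # one group per region, faces grouped; unlabelled faces written first
    lab2 <- ifelse(is.na(lab), "", lab)
    for (g in unique(lab2)) {
      if (nzchar(g)) writeLines(sprintf("g %s", g), con)
      sel <- which(lab2 == g)
      writeLines(sprintf("f %d %d %d", f[sel, 1L], f[sel, 2L], f[sel, 3L]), con)
    }
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") stop("not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format[[:space:]]+ascii", hdr)))
    stop("only ascii PLY is supported")
  nv <- as.integer(sub("^element[[:space:]]+vertex[[:space:]]+", "",
                       grep("^element[[:space:]]+vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element[[:space:]]+face[[:space:]]+", "",
                       grep("^element[[:space:]]+face", hdr, value = TRUE)[1L]))
  body <- trimws(lines[-seq_len(hdr_end)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop("PLY body shorter than declared element counts")
  v <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(l, "[[:space:]]+")[[1L]][1:3])))
  f <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
    tok <- as.integer(strsplit(l, "[[:space:]]+")[[1L]])
    if (tok[1L] != 3L) stop("non-triangular PLY face")
    tok[2:4] + 1L
  }))
  if (is.null(v)) v <- matrix(numeric(0), 0L, 3L)
  if (is.null(f)) f <- matrix(integer(0), 0L, 3L)
  trimesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%s %s %s",
                     fmt_num(mesh$vertices[, 1L]),
                     fmt_num(mesh$vertices[, 2L]),
                     fmt_num(mesh$vertices[, 3L])), con)
  f <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
}

read_stl <- function(path) {
  # sniff ascii vs binary: ascii files are pure printable text, start with
  # "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512L)
  printable <- all(head_raw >= as.raw(0x09) & head_raw <= as.raw(0x7E))
  is_ascii <- FALSE
  if (printable) {
    head_txt <- rawToChar(head_raw)
    is_ascii <- grepl("^[[:space:]]*solid", head_txt) && grepl("facet", head_txt)
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangles(tri)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex[[:space:]]", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("STL vertex count not a multiple of 3")
  xyz <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"),
                               function(t) as.numeric(t[2:4])))
  xyz
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  out <- matrix(NA_real_, nt * 3L, 3L)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    out[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  out
}

# weld an (3m x 3) soup of triangle corners into shared vertices on exact
# coordinate equality
weld_triangles <- function(xyz) {
  key <- paste(fmt_num(xyz[, 1L]), fmt_num(xyz[, 2L]), fmt_num(xyz[, 3L]))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  trimesh(xyz[first, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

write_stl <- function(mesh, path, binary = FALSE) {
  f <- mesh$faces; v <- mesh$vertices
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(charToRaw("kidneysim binary STL"), raw(60L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid kidneysim", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %s %s %s",
                           fmt_num(n[i, 1L]), fmt_num(n[i, 2L]), fmt_num(n[i, 3L])),
                   "    outer loop",
                   sprintf("      vertex %s %s %s",
                           fmt_num(v[f[i, ], 1L]), fmt_num(v[f[i, ], 2L]),
                           fmt_num(v[f[i, ], 3L])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid kidneysim", con)
  }
}
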