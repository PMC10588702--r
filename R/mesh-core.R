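# Triangle-mesh data model and geometric quantities.
#
# A `trimesh` is the geometric substrate for the whole simulator: an n x 3
# matrix of vertex positions (meters), an m x 3 integer matrix of faces
# (1-based vertex indices, counter-clockwise winding seen from outside =
# outward normal), and an optional per-face region label (character, NA =
# unlabelled).

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, n x 3, vertex positions in meters.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle,
#'   counter-clockwise winding seen from outside.
#' @param face_labels optional character vector of length m giving a region
#'   name per face (e.g. `"healthy"`, `"cancerous"`); `NA` = unlabelled.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, face_labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  m <- list(vertices = vertices, faces = faces)
  if (!is.null(face_labels)) {
    face_labels <- as.character(face_labels)
    if (length(face_labels) != nrow(faces))
      stop("face_labels must have one entry per face")
    m$face_labels <- face_labels
  }
  class(m) <- "trimesh"
  validate_trimesh(m)
  m
}

#' Validate trimesh invariants
#'
#' Checks index ranges, non-degenerate index triples and label length.
#' Called by [trimesh()]; exported so loaders and generators can re-check.
#'
#' @param mesh a `trimesh`.
#' @return `mesh`, invisibly; errors describe the first offending face.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinate")
  if (nrow(f) > 0L) {
    bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("face %d references out-of-range vertex index %d",
                   bad[1L, 1L], f[bad[1L, 1L], bad[1L, 2L]]))
    rep_v <- which(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L])
    if (length(rep_v) > 0L)
      stop(sprintf("face %d repeats a vertex index", rep_v[1L]))
  }
  if (!is.null(mesh$face_labels) && length(mesh$face_labels) != nrow(f))
    stop("face_labels length does not match face count")
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$face_labels)) {
    tab <- table(x$face_labels, useNA = "no")
    cat(sprintf(" | labels: %s",
                paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `trimesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_norms <- function(x) sqrt(rowSums(x * x))

# face cross products (un-normalized normals, length = 2*area) at given
# positions; positions defaults to mesh vertices so deformed states can reuse it
face_cross <- function(mesh, positions = mesh$vertices) {
  f <- mesh$faces
  p1 <- positions[f[, 1L], , drop = FALSE]
  cross3(positions[f[, 2L], , drop = FALSE] - p1,
         positions[f[, 3L], , drop = FALSE] - p1)
}

#' Per-face areas
#'
#' Area of each triangle (half the cross-product norm of two edge vectors).
#' Degenerate faces yield 0.
#'
#' @param mesh a `trimesh`.
#' @param positions optional n x 3 matrix of deformed vertex positions.
#' @return numeric vector of areas (m^2), one per face.
#' @export
face_areas <- function(mesh, positions = mesh$vertices) {
  0.5 * row_norms(face_cross(mesh, positions))
}

#' Per-face unit outward normals
#'
#' @inheritParams face_areas
#' @return m x 3 matrix; degenerate faces get the zero vector.
#' @export
face_normals <- function(mesh, positions = mesh$vertices) {
  cr <- face_cross(mesh, positions)
  n <- row_norms(cr)
  ok <- n > 0
  cr[ok, ] <- cr[ok, , drop = FALSE] / n[ok]
  cr[!ok, ] <- 0
  cr
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals, normalized. An isolated
#' vertex (or one with only degenerate incident faces) gets the zero vector
#' and is reported in the `"flagged"` attribute rather than producing NaN.
#'
#' @inheritParams face_areas
#' @return n x 3 matrix of unit normals with attribute `flagged` (integer
#'   indices of zero-normal vertices).
#' @export
vertex_normals <- function(mesh, positions = mesh$vertices) {
  cr <- face_cross(mesh, positions)  # area-weighted face normal = cr / 2
  f <- mesh$faces
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  acc <- rowsum(rbind(cr, cr, cr), group = idx)
  out <- matrix(0, nrow(positions), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  n <- row_norms(out)
  ok <- n > 1e-300
  out[ok, ] <- out[ok, , drop = FALSE] / n[ok]
  structure(out, flagged = which(!ok))
}

#' Edge topology of a triangle mesh
#'
#' Unique undirected edges with rest lengths from the current vertex
#' positions, plus one dihedral record per interior edge: the four vertex
#' indices `x1..x4` of the two adjacent triangles (shared edge `(x1, x2)`,
#' `x3` opposite in the first triangle, `x4` in the second) and the rest
#' dihedral deviation angle `phi12` in radians (0 for a coplanar pair).
#'
#' The `x1..x4` assignment fixes the winding convention used by bending
#' constraints: the triangle `(x1, x3, x2)` is the first adjacent face with
#' its original orientation and `(x1, x2, x4)` the second, so both implied
#' normals are the outward face normals.
#'
#' @param mesh a `trimesh`.
#' @return list of class `edge_topology` with elements `edges` (e x 2 matrix,
#'   i < j), `rest_lengths` (numeric e), `dihedrals` (d x 4 integer matrix
#'   x1..x4), `phi12` (numeric d), `edge_faces` (e x 2 matrix of adjacent face
#'   indices, NA for boundary edges), `boundary` (logical e).
#' @export
build_edge_topology <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  # directed half-edges: (a, b, face, opposite-vertex)
  he_a <- c(f[, 1L], f[, 2L], f[, 3L])
  he_b <- c(f[, 2L], f[, 3L], f[, 1L])
  he_f <- rep.int(seq_len(m), 3L)
  he_o <- c(f[, 3L], f[, 1L], f[, 2L])
  lo <- pmin(he_a, he_b); hi <- pmax(he_a, he_b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  edges <- cbind(lo[first], hi[first])
  eid <- match(key, key[first])
  cnt <- tabulate(eid, nbins = sum(first))
  if (any(cnt > 2L)) {
    e <- which(cnt > 2L)[1L]
    stop(sprintf("non-manifold: edge (%d,%d) shared by %d faces",
                 edges[e, 1L], edges[e, 2L], cnt[e]))
  }
  p <- mesh$vertices
  rest <- row_norms(p[edges[, 2L], , drop = FALSE] - p[edges[, 1L], , drop = FALSE])
  if (any(rest <= 0)) stop("zero-length edge in rest mesh")

  ne <- nrow(edges)
  ef <- matrix(NA_integer_, ne, 2L)
  # directed edge a->b with a < b goes in slot 1, the reverse in slot 2;
  # consistent CCW winding guarantees the two half-edges have opposite order
  slot <- ifelse(he_a < he_b, 1L, 2L)
  if (anyDuplicated(cbind(eid, slot)))
    stop("inconsistent face winding: an edge is traversed twice in the same direction")
  ef[cbind(eid, slot)] <- he_f
  opp <- matrix(NA_integer_, ne, 2L)
  opp[cbind(eid, slot)] <- he_o
  boundary <- is.na(ef[, 1L]) | is.na(ef[, 2L])

  interior <- which(!boundary)
  # convention: x1 = edge lo endpoint, x2 = hi endpoint; face B (slot 1)
  # traverses x1->x2, face A (slot 2) traverses x2->x1. x3 = apex of A,
  # x4 = apex of B, so (x1,x3,x2) ~ face A and (x1,x2,x4) ~ face B as
  # oriented triangles.
  dih <- cbind(edges[interior, 1L], edges[interior, 2L],
               opp[interior, 2L], opp[interior, 1L])
  phi <- if (length(interior) > 0L) {
    fn <- face_normals(mesh)
    nA <- fn[ef[interior, 2L], , drop = FALSE]
    nB <- fn[ef[interior, 1L], , drop = FALSE]
    d <- pmin(pmax(rowSums(nA * nB), -1), 1)
    acos(d)
  } else numeric(0)

  structure(list(edges = edges, rest_lengths = rest,
                 dihedrals = dih, phi12 = phi,
                 edge_faces = ef, boundary = boundary),
            class = "edge_topology")
}

#' @export
print.edge_topology <- function(x, ...) {
  cat(sprintf("edge_topology: %d edges (%d boundary), %d dihedral pairs\n",
              nrow(x$edges), sum(x$boundary), nrow(x$dihedrals)))
  invisible(x)
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the origin.
#' For a closed, consistently CCW-wound mesh this is the enclosed volume.
#' Open meshes produce a warning but still return the signed sum.
#'
#' @inheritParams face_areas
#' @param warn_open warn when the mesh has boundary edges (default `TRUE`).
#' @return signed volume (m^3).
#' @export
mesh_volume <- function(mesh, positions = mesh$vertices, warn_open = TRUE) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  if (warn_open) {
    he <- paste(pmin(c(f[, 1L], f[, 2L], f[, 3L]), c(f[, 2L], f[, 3L], f[, 1L])),
                pmax(c(f[, 1L], f[, 2L], f[, 3L]), c(f[, 2L], f[, 3L], f[, 1L])))
    if (any(tabulate(match(he, unique(he))) != 2L))
      warning("mesh is not closed; signed volume returned anyway")
  }
  p1 <- positions[f[, 1L], , drop = FALSE]
  p2 <- positions[f[, 2L], , drop = FALSE]
  p3 <- positions[f[, 3L], , drop = FALSE]
  sum(rowSums(p1 * cross3(p2, p3))) / 6
}

#' Connected components of a mesh by shared-edge face adjacency
#'
#' @param mesh a `trimesh`.
#' @param drop_edges optional e2 x 2 matrix of vertex-index pairs; face
#'   adjacency across these edges is ignored (the cut model used by
#'   [resect()]).
#' @return list of integer vectors of face indices, ordered by each
#'   component's smallest face index.
#' @export
connected_components <- function(mesh, drop_edges = NULL) {
  m <- n_faces(mesh)
  if (m == 0L) return(list())
  topo <- build_edge_topology(mesh)
  ef <- topo$edge_faces
  keep <- !topo$boundary
  if (!is.null(drop_edges) && nrow(drop_edges) > 0L) {
    dk <- paste(pmin(drop_edges[, 1L], drop_edges[, 2L]),
                pmax(drop_edges[, 1L], drop_edges[, 2L]))
    ek <- paste(topo$edges[, 1L], topo$edges[, 2L])
    keep <- keep & !(ek %in% dk)
  }
  g <- igraph::graph_from_edgelist(ef[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(m)]
  comps <- split(seq_len(m), memb)
  comps <- unname(comps[order(vapply(comps, min, 1L))])
  comps
}

#' Region partition from face labels
#'
#' @param mesh a labelled `trimesh`.
#' @return named list: region name -> integer vector of face indices.
#' @export
region_partition <- function(mesh) {
  if (is.null(mesh$face_labels)) return(structure(list(), names = character(0)))
  lab <- mesh$face_labels
  keep <- !is.na(lab)
  split(which(keep), lab[keep])
}

#' Extract a sub-mesh from a face subset
#'
#' Re-indexes vertices so the result is self-contained; vertices shared with
#' the complement are duplicated (each component keeps its own copy), which
#' is how resection separates the two sides of a cut.
#'
#' @param mesh a `trimesh`.
#' @param face_idx integer vector of face indices to keep.
#' @return a `trimesh` (labels carried over when present).
#' @export
submesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[f], ncol = 3L)
  trimesh(mesh$vertices[used, , drop = FALSE], f2,
          face_labels = if (!is.null(mesh$face_labels)) mesh$face_labels[face_idx])
}
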