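# Deterministic generators for all test geometry: planar sheets, icospheres,
# Loop subdivision, and the labelled kidney phantom (a smooth bean-shaped
# closed surface with an exophytic "cancerous" lobe) that stands in for a
# hand-modelled organ mesh.

#' Planar triangulated grid sheet
#'
#' A sheet in the z = 0 plane with `nx * ny` vertices and
#' `2 (nx-1)(ny-1)` faces, wound counter-clockwise seen from +z.
#'
#' @param nx,ny vertex counts along x and y (both >= 2).
#' @param spacing vertex spacing in meters (> 0).
#' @return an open `trimesh`.
#' @export
make_grid_sheet <- function(nx, ny, spacing = 1) {
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  if (spacing <= 0) stop("spacing must be > 0")
  g <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1L) * nx + i
  faces <- NULL
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    faces <- rbind(faces,
                   cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                   cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  }
  trimesh(v, faces)
}

#' Icosphere
#'
#' Regular icosahedron refined by `subdivision` rounds of edge-midpoint
#' splitting, all vertices projected onto the sphere of radius `radius`.
#' Face count is `20 * 4^subdivision`.
#'
#' @param subdivision integer in `[0, 5]`.
#' @param radius sphere radius in meters.
#' @return a closed `trimesh`.
#' @export
make_icosphere <- function(subdivision = 0L, radius = 1) {
  if (subdivision < 0L || subdivision > 5L) stop("subdivision must be in [0, 5]")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    sub <- midpoint_subdivide(v, f)
    v <- sub$vertices; f <- sub$faces
    v <- v / row_norms(v)
  }
  trimesh(v * radius, f)
}

# split every face into 4 via edge midpoints (shared midpoints welded)
midpoint_subdivide <- function(v, f) {
  ea <- c(f[, 1L], f[, 2L], f[, 3L]); eb <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  eid <- match(key, key[first])
  mid <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  mv <- nrow(v) + eid  # midpoint vertex index per half-edge
  m <- nrow(f)
  m12 <- mv[seq_len(m)]; m23 <- mv[m + seq_len(m)]; m31 <- mv[2L * m + seq_len(m)]
  nf <- rbind(cbind(f[, 1L], m12, m31),
              cbind(f[, 2L], m23, m12),
              cbind(f[, 3L], m31, m23),
              cbind(m12, m23, m31))
  list(vertices = rbind(v, mid), faces = nf,
       edge_mid = cbind(lo[first], hi[first]))
}

#' Loop subdivision
#'
#' Classic Loop scheme: each face splits into four; new edge vertices are
#' the 3/8-3/8-1/8-1/8 stencil (1/2-1/2 on boundary edges), old vertices
#' are smoothed with Loop's beta weights (3/4 + 1/8-neighbor rule on the
#' boundary). Face labels are inherited by the four children of each face.
#'
#' @param mesh a manifold `trimesh`.
#' @param levels number of subdivision rounds (>= 0).
#' @return the refined `trimesh`.
#' @export
loop_subdivide <- function(mesh, levels = 1L) {
  for (lv in seq_len(levels)) mesh <- loop_once(mesh)
  mesh
}

loop_once <- function(mesh) {
  topo <- build_edge_topology(mesh)  # also rejects non-manifold input
  v <- mesh$vertices; f <- mesh$faces
  sub <- midpoint_subdivide(v, f)
  edges <- sub$edge_mid
  ne <- nrow(edges)

  # new edge-vertex positions
  epos <- matrix(NA_real_, ne, 3L)
  ef <- topo$edge_faces
  # topo$edges rows match sub$edge_mid rows (same first-occurrence order)
  stopifnot(all(topo$edges == edges))
  for (e in seq_len(ne)) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    if (topo$boundary[e]) {
      epos[e, ] <- (v[a, ] + v[b, ]) / 2
    } else {
      o1 <- setdiff(f[ef[e, 1L], ], c(a, b))
      o2 <- setdiff(f[ef[e, 2L], ], c(a, b))
      epos[e, ] <- 3 / 8 * (v[a, ] + v[b, ]) + 1 / 8 * (v[o1, ] + v[o2, ])
    }
  }

  # smoothed old-vertex positions
  n <- nrow(v)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1L]]] <- c(adj[[edges[e, 1L]]], edges[e, 2L])
    adj[[edges[e, 2L]]] <- c(adj[[edges[e, 2L]]], edges[e, 1L])
  }
  bverts <- unique(as.integer(edges[topo$boundary, , drop = FALSE]))
  badj <- vector("list", n)
  for (e in which(topo$boundary)) {
    badj[[edges[e, 1L]]] <- c(badj[[edges[e, 1L]]], edges[e, 2L])
    badj[[edges[e, 2L]]] <- c(badj[[edges[e, 2L]]], edges[e, 1L])
  }
  vpos <- v
  for (i in seq_len(n)) {
    if (i %in% bverts) {
      nb <- badj[[i]]
      if (length(nb) == 2L)
        vpos[i, ] <- 3 / 4 * v[i, ] + 1 / 8 * (v[nb[1L], ] + v[nb[2L], ])
    } else {
      nb <- adj[[i]]
      k <- length(nb)
      if (k < 3L) next
      beta <- (1 / k) * (5 / 8 - (3 / 8 + 1 / 4 * cos(2 * pi / k))^2)
      vpos[i, ] <- (1 - k * beta) * v[i, ] + beta * colSums(v[nb, , drop = FALSE])
    }
  }

  newv <- rbind(vpos, epos)
  labels <- if (!is.null(mesh$face_labels)) rep(mesh$face_labels, 4L)
  trimesh(newv, sub$faces, face_labels = labels)
}

#' Kidney-phantom specification
#'
#' @param subdivision icosphere refinement of the base surface (default 3,
#'   ~1,280 faces: sparse enough for interactive-rate physics, smooth
#'   enough for stable dihedral constraints).
#' @param kidney_scale semi-axis scale triple in meters (default
#'   `c(0.055, 0.035, 0.030)`, an adult kidney's half-dimensions).
#' @param tumor_fraction tumor radius as a fraction of the local organ
#'   radius, in `(0, 0.5)`; the default 0.35 emulates a 3-5 cm peripheral
#'   mass on a ~11 cm organ.
#' @param tumor_direction unit direction of the tumor center from the organ
#'   center (normalized internally).
#' @param seed integer seed controlling the smooth indentation jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(subdivision = 3L,
                         kidney_scale = c(0.055, 0.035, 0.030),
                         tumor_fraction = 0.35,
                         tumor_direction = c(1, 0.35, 0.25),
                         seed = 1L) {
  if (tumor_fraction <= 0 || tumor_fraction >= 0.5)
    stop("tumor_fraction must lie in (0, 0.5)")
  d <- as.numeric(tumor_direction)
  structure(list(subdivision = as.integer(subdivision),
                 kidney_scale = as.numeric(kidney_scale),
                 tumor_fraction = tumor_fraction,
                 tumor_direction = d / sqrt(sum(d^2)),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the labelled kidney phantom
#'
#' A closed bean-shaped surface built from a unit icosphere: a seeded smooth
#' radial indentation on the hilum side produces the bean profile, an
#' exophytic lobe of angular radius `asin(tumor_fraction)` bulges outward
#' along `tumor_direction`, and the whole surface is scaled anisotropically
#' by `kidney_scale`. Faces whose unit-sphere centroid direction falls
#' inside the tumor cap are labelled `"cancerous"`, the rest `"healthy"`.
#' Output is bit-identical for identical specs.
#'
#' @param spec a [phantom_spec()].
#' @return a labelled, closed `trimesh`; attribute `"spec"` carries the
#'   generating spec.
#' @export
make_kidney_phantom <- function(spec = phantom_spec()) {
  base <- make_icosphere(spec$subdivision, radius = 1)
  u <- base$vertices  # unit directions
  tdir <- spec$tumor_direction
  theta_t <- asin(spec$tumor_fraction)

  # labels from unit-sphere centroid directions, before any displacement
  cen <- (u[base$faces[, 1L], ] + u[base$faces[, 2L], ] + u[base$faces[, 3L], ]) / 3
  cen <- cen / row_norms(cen)
  ang_f <- acos(pmin(1, pmax(-1, cen %*% tdir)))
  labels <- ifelse(ang_f < theta_t, "cancerous", "healthy")

  # seeded smooth indentation opposite-ish the tumor (hilum side)
  rng <- local_rng(spec$seed)
  idir <- c(0, -1, 0)
  idir <- idir - sum(idir * tdir) * tdir  # keep clear of the tumor cap
  idir <- idir / sqrt(sum(idir^2))
  depth <- 0.18 + 0.04 * rng(1)
  width <- 0.55 + 0.10 * rng(1)
  ang_i <- acos(pmin(1, pmax(-1, u %*% idir)))
  r <- 1 - depth * exp(-(ang_i / width)^2)

  # exophytic tumor bulge: raised-cosine profile inside the cap
  ang_v <- acos(pmin(1, pmax(-1, u %*% tdir)))
  h <- 0.5 * spec$tumor_fraction
  bulge <- ifelse(ang_v < theta_t,
                  h * cos(pi * ang_v / (2 * theta_t))^2, 0)
  r <- r + bulge

  v <- u * as.numeric(r)
  v <- v * matrix(spec$kidney_scale, nrow(v), 3L, byrow = TRUE)
  out <- trimesh(v, base$faces, face_labels = labels)
  attr(out, "spec") <- spec
  out
}

# deterministic uniform stream independent of the global RNG state
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}
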