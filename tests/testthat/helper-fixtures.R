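# Shared fixtures and independent scalar oracles for the suite. All geometry
# is generated in code; nothing is read from disk except round-trip files
# written into tempdir().

# one unit right triangle in z = 0
unit_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(c(1L, 2L, 3L), 1L))
}

# flat quad: two triangles sharing the diagonal (1,2)
flat_quad <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0)),
          rbind(c(1L, 3L, 2L), c(1L, 2L, 4L)))
}

# folded quad: same connectivity, wing 4 lifted
folded_quad <- function(z = 0.8) {
  trimesh(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, z)),
          rbind(c(1L, 3L, 2L), c(1L, 2L, 4L)))
}

# unit cube split into 12 triangles, outward winding
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # x = 0
    c(2, 6, 8), c(2, 8, 4),   # x = 1
    c(1, 5, 6), c(1, 6, 2),   # y = 0
    c(3, 4, 8), c(3, 8, 7),   # y = 1
    c(1, 2, 4), c(1, 4, 3),   # z = 0
    c(5, 7, 8), c(5, 8, 6))   # z = 1
  m <- trimesh(v, f)
  if (mesh_volume(m, warn_open = FALSE) < 0)   # ensure outward winding
    m <- trimesh(v, f[, c(1L, 3L, 2L)])
  m
}

# scalar (non-vectorized) reference: spring + pressure forces, one loop at
# a time -- the brute-force oracle for composite_force
oracle_forces <- function(mesh, topology, positions, k_spring, P) {
  n <- nrow(positions)
  out <- matrix(0, n, 3L)
  for (e in seq_len(nrow(topology$edges))) {
    i <- topology$edges[e, 1L]; j <- topology$edges[e, 2L]
    d <- positions[i, ] - positions[j, ]
    len <- sqrt(sum(d^2))
    if (len == 0) next
    f <- -k_spring * (len - topology$rest_lengths[e]) * d / len
    out[i, ] <- out[i, ] + f
    out[j, ] <- out[j, ] - f
  }
  for (fc in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[fc, ]
    cr <- crossprod_vec(positions[tri[2L], ] - positions[tri[1L], ],
                        positions[tri[3L], ] - positions[tri[1L], ])
    force <- P * cr / 2  # P * area * n_hat
    for (vv in tri) out[vv, ] <- out[vv, ] + force / 3
  }
  out
}

crossprod_vec <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# exhaustive scalar ray cast: loop every face through ray_triangle
oracle_cast <- function(mesh, r) {
  best <- NULL
  for (fc in seq_len(n_faces(mesh))) {
    tri <- mesh$faces[fc, ]
    hit <- ray_triangle(r, mesh$vertices[tri[1L], ], mesh$vertices[tri[2L], ],
                        mesh$vertices[tri[3L], ])
    if (!is.null(hit) && (is.null(best) || hit$t < best$t))
      best <- list(face = fc, t = hit$t, point = hit$point)
  }
  best
}

# hand-rolled two-particle PBD step (predict, project n times, velocity)
oracle_two_particle <- function(x1, x2, v1, v2, d12, dt, iterations) {
  p1 <- x1 + v1 * dt; p2 <- x2 + v2 * dt
  for (it in seq_len(iterations)) {
    d <- p1 - p2
    len <- sqrt(sum(d^2))
    C <- len - d12
    p1 <- p1 - 0.5 * C * d / len
    p2 <- p2 + 0.5 * C * d / len
  }
  list(p1 = p1, p2 = p2, v1 = (p1 - x1) / dt, v2 = (p2 - x2) / dt)
}

dihedral_angle <- function(positions, x1, x2, x3, x4) {
  n1 <- crossprod_vec(positions[x3, ] - positions[x1, ],
                      positions[x2, ] - positions[x1, ])
  n2 <- crossprod_vec(positions[x2, ] - positions[x1, ],
                      positions[x4, ] - positions[x1, ])
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  acos(min(1, max(-1, sum(n1 * n2))))
}

single_stretch_set <- function(i, j, d12, k = 1, breakable = FALSE,
                               threshold = NA_real_) {
  n <- length(i)
  structure(list(
    stretch = data.frame(i = i, j = j, d12 = rep_len(d12, n),
                         k = rep_len(k, n),
                         breakable = rep_len(breakable, n),
                         threshold = rep_len(threshold, n)),
    bend = data.frame(x1 = integer(0), x2 = integer(0), x3 = integer(0),
                      x4 = integer(0), phi12 = numeric(0), k = numeric(0))),
    class = "constraint_set")
}
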