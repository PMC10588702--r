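# Headless interaction layer: ray picking, cut-path marking along triangle
# edges, severing/weakening of constraints along the path, and resection of
# a labelled region.
#
# Cutting never re-meshes: the marked path is realized as a set of existing
# mesh edges ("crossed edges") whose constraints are removed (or made
# breakable), and whose face-to-face adjacency is severed at resection
# time. Vertices on the separating cycle are duplicated when the two sides
# are extracted, so each side becomes an independent mesh.

#' Construct a ray
#'
#' @param origin 3-vector (m).
#' @param direction 3-vector; must be unit length within 1e-9 (normalize
#'   with `normalize = TRUE`).
#' @param normalize normalize `direction` instead of checking it.
#' @return object of class `ray`.
#' @export
ray <- function(origin, direction, normalize = FALSE) {
  direction <- as.numeric(direction)
  len <- sqrt(sum(direction^2))
  if (normalize) {
    if (len == 0) stop("zero-length ray direction")
    direction <- direction / len
  } else if (abs(len - 1) > 1e-9) {
    stop("ray direction must be unit length (or pass normalize = TRUE)")
  }
  structure(list(origin = as.numeric(origin), direction = direction),
            class = "ray")
}

#' Ray-triangle intersection (Moller-Trumbore)
#'
#' @param r a [ray()].
#' @param p0,p1,p2 triangle vertices (3-vectors).
#' @param eps determinant cutoff for rays parallel to the triangle plane.
#' @return `NULL` on a miss, otherwise a list with `t` (ray parameter,
#'   strictly positive), `bary` (barycentric coordinates w.r.t.
#'   `p0, p1, p2`, each in `[0, 1]`, summing to 1) and `point`.
#' @export
ray_triangle <- function(r, p0, p1, p2, eps = 1e-12) {
  e1 <- p1 - p0; e2 <- p2 - p0
  pv <- vcross(r$direction, e2)
  det <- sum(e1 * pv)
  if (abs(det) < eps) return(NULL)
  inv <- 1 / det
  tv <- r$origin - p0
  u <- sum(tv * pv) * inv
  if (u < 0 || u > 1) return(NULL)
  qv <- vcross(tv, e1)
  v <- sum(r$direction * qv) * inv
  if (v < 0 || u + v > 1) return(NULL)
  t <- sum(e2 * qv) * inv
  if (t <= eps) return(NULL)
  list(t = t, bary = c(1 - u - v, u, v), point = r$origin + t * r$direction)
}

#' Cast a ray against a whole mesh
#'
#' Returns the hit with minimal positive `t` over all faces; exact ties are
#' broken by the smaller face index. Implemented as a vectorized
#' Moller-Trumbore sweep over every face.
#'
#' @param mesh a `trimesh`.
#' @param r a [ray()].
#' @return `NULL` on a miss, otherwise list with `face`, `t`, `point`,
#'   `bary`.
#' @export
cast_ray <- function(mesh, r) {
  f <- mesh$faces; V <- mesh$vertices
  if (nrow(f) == 0L) return(NULL)
  p0 <- V[f[, 1L], , drop = FALSE]
  e1 <- V[f[, 2L], , drop = FALSE] - p0
  e2 <- V[f[, 3L], , drop = FALSE] - p0
  dir <- matrix(r$direction, nrow(f), 3L, byrow = TRUE)
  pv <- cross3(dir, e2)
  det <- rowSums(e1 * pv)
  tv <- matrix(r$origin, nrow(f), 3L, byrow = TRUE) - p0
  inv <- ifelse(abs(det) < 1e-12, NA_real_, 1 / det)
  u <- rowSums(tv * pv) * inv
  qv <- cross3(tv, e1)
  v <- rowSums(dir * qv) * inv
  t <- rowSums(e2 * qv) * inv
  ok <- !is.na(inv) & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & t > 1e-12
  if (!any(ok)) return(NULL)
  tmin <- min(t[ok])
  face <- which(ok & t == tmin)[1L]  # smallest face index on ties
  list(face = face, t = tmin, point = r$origin + tmin * r$direction,
       bary = c(1 - u[face] - v[face], u[face], v[face]))
}

#' Mark a cut path across the surface
#'
#' Connects an ordered sequence of surface samples (3D point + face index,
#' as produced by [cast_ray()]) across the mesh: for each consecutive pair
#' on distinct faces, the walk between the faces (direct neighbors, or the
#' shortest face-adjacency walk weighted by centroid distance with
#' deterministic tie-breaking) contributes every shared edge it crosses to
#' `crossed_edges`. The path is closed when the first and last samples lie
#' on the same face or within the closure tolerance.
#'
#' @param mesh a `trimesh`.
#' @param samples data frame or list with columns/elements `x, y, z, face`
#'   (or a list of `list(point=, face=)`).
#' @param topology optional precomputed [build_edge_topology()].
#' @param closure_tol closure tolerance in meters; default 1.5x the mean
#'   edge length.
#' @param plane_tol tolerance for the on-face-plane sanity check (meters);
#'   default 1e-6 x the mesh diagonal.
#' @return object of class `cut_path`: `samples` (k x 3 matrix), `faces`
#'   (integer k), `crossed_edges` (e x 2 matrix of vertex pairs, i < j, in
#'   first-crossing order), `closed` (logical).
#' @export
mark_cut_path <- function(mesh, samples, topology = NULL,
                          closure_tol = NULL, plane_tol = NULL) {
  ss <- normalize_samples(samples)
  pts <- ss$points; fcs <- ss$faces
  if (is.null(topology)) topology <- build_edge_topology(mesh)
  if (is.null(closure_tol)) closure_tol <- 1.5 * mean(topology$rest_lengths)
  if (is.null(plane_tol)) {
    diag <- sqrt(sum((apply(mesh$vertices, 2L, max) -
                      apply(mesh$vertices, 2L, min))^2))
    plane_tol <- max(1e-12, 1e-6 * diag)
  }
  fn <- face_normals(mesh)
  for (k in seq_len(nrow(pts))) {
    fk <- fcs[k]
    if (fk < 1L || fk > n_faces(mesh)) stop(sprintf("sample %d: bad face index", k))
    dplane <- abs(sum((pts[k, ] - mesh$vertices[mesh$faces[fk, 1L], ]) * fn[fk, ]))
    if (dplane > plane_tol)
      stop(sprintf("sample %d lies %.3g m off its face plane (tol %.3g)",
                   k, dplane, plane_tol))
  }

  dual <- face_dual_graph(mesh, topology)
  crossed <- matrix(integer(0), 0L, 2L)
  if (nrow(pts) >= 2L) {
    for (k in seq_len(nrow(pts) - 1L)) {
      fa <- fcs[k]; fb <- fcs[k + 1L]
      if (fa == fb) next
      walk <- face_walk(dual, fa, fb)
      if (length(walk) < 2L)
        stop(sprintf("no surface walk between samples %d and %d", k, k + 1L))
      for (s in seq_len(length(walk) - 1L)) {
        e <- shared_edge(mesh, walk[s], walk[s + 1L])
        crossed <- rbind(crossed, e)
      }
    }
    crossed <- crossed[!duplicated(paste(crossed[, 1L], crossed[, 2L])), ,
                       drop = FALSE]
  }
  closed <- nrow(pts) >= 3L &&
    (fcs[1L] == fcs[length(fcs)] ||
       sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2)) <= closure_tol)
  structure(list(samples = pts, faces = fcs, crossed_edges = crossed,
                 closed = closed, closure_tol = closure_tol),
            class = "cut_path")
}

#' @export
print.cut_path <- function(x, ...) {
  cat(sprintf("cut_path: %d samples, %d crossed edges, %s\n",
              nrow(x$samples), nrow(x$crossed_edges),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

normalize_samples <- function(samples) {
  if (is.data.frame(samples)) {
    list(points = as.matrix(samples[, c("x", "y", "z")]),
         faces = as.integer(samples$face))
  } else if (is.list(samples) && !is.null(samples[[1L]]$point)) {
    list(points = do.call(rbind, lapply(samples, function(s) s$point)),
         faces = vapply(samples, function(s) as.integer(s$face), 1L))
  } else stop("samples must be a data frame (x,y,z,face) or list of point/face")
}

# weighted dual (face-adjacency) graph; deterministic
face_dual_graph <- function(mesh, topology) {
  ef <- topology$edge_faces
  keep <- !topology$boundary
  el <- ef[keep, , drop = FALSE]
  cen <- (mesh$vertices[mesh$faces[, 1L], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2L], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3L], , drop = FALSE]) / 3
  w <- row_norms(cen[el[, 1L], , drop = FALSE] - cen[el[, 2L], , drop = FALSE])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_faces(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- w + 1e-9 * mean(w)  # strictly positive: fewest hops on ties
  g
}

face_walk <- function(dual, fa, fb) {
  sp <- igraph::shortest_paths(dual, from = fa, to = fb, output = "vpath")
  as.integer(sp$vpath[[1L]])
}

shared_edge <- function(mesh, fa, fb) {
  a <- mesh$faces[fa, ]; b <- mesh$faces[fb, ]
  common <- intersect(a, b)
  if (length(common) != 2L)
    stop(sprintf("faces %d and %d do not share an edge", fa, fb))
  c(min(common), max(common))
}

#' Apply a cut to the constraint set
#'
#' Mode `"sever"` removes stretch constraints on every crossed edge and
#' bend constraints hinged on one, immediately. Mode `"weaken"` marks the
#' crossed stretch constraints breakable with the configured threshold so
#' [tear_step()] detaches them under load. Never adds constraints.
#'
#' @param constraints a `constraint_set`.
#' @param cut_path a [mark_cut_path()] result.
#' @param mode `"sever"` or `"weaken"`.
#' @param break_threshold threshold installed by `"weaken"`.
#' @return modified `constraint_set`; crossed edges without a constraint
#'   produce a warning and are skipped.
#' @export
apply_cut <- function(constraints, cut_path, mode = c("sever", "weaken"),
                      break_threshold = 0.4) {
  mode <- match.arg(mode)
  ce <- cut_path$crossed_edges
  if (nrow(ce) == 0L) return(constraints)
  ck <- paste(ce[, 1L], ce[, 2L])
  s <- constraints$stretch
  sk <- paste(pmin(s$i, s$j), pmax(s$i, s$j))
  hit <- sk %in% ck
  missing <- setdiff(ck, sk)
  if (length(missing) > 0L)
    warning(sprintf("%d crossed edge(s) carry no stretch constraint",
                    length(missing)))
  if (mode == "sever") {
    constraints$stretch <- s[!hit, , drop = FALSE]
    b <- constraints$bend
    bk <- paste(pmin(b$x1, b$x2), pmax(b$x1, b$x2))
    constraints$bend <- b[!(bk %in% ck), , drop = FALSE]
  } else {
    constraints$stretch$breakable[hit] <- TRUE
    constraints$stretch$threshold[hit] <- break_threshold
  }
  constraints
}

#' Resect the labelled region enclosed by a closed cut
#'
#' Splits the faces into components by severing face adjacency across every
#' crossed edge. The component with the best majority of
#' `region_label`-labelled faces is returned as the excised piece; all other
#' faces form the remaining piece. Vertices on the separating cycle are
#' duplicated (one copy per side) so both outputs are independent meshes.
#'
#' @param mesh a labelled `trimesh`.
#' @param cut_path a closed [mark_cut_path()] result.
#' @param region_label the region to excise (e.g. `"cancerous"`).
#' @return list with `excised` and `remaining` (`trimesh` objects),
#'   `excised_faces`, `remaining_faces` (original face indices), and
#'   `report` (excised face count, label purity, healthy-face damage count).
#' @export
resect <- function(mesh, cut_path, region_label) {
  if (!isTRUE(cut_path$closed)) stop("cut is not closed")
  if (is.null(mesh$face_labels) || !any(mesh$face_labels == region_label,
                                        na.rm = TRUE))
    stop(sprintf("region label '%s' not present in mesh", region_label))
  comps <- connected_components(mesh, drop_edges = cut_path$crossed_edges)
  if (length(comps) < 2L)
    stop("cut cycle is not separating: mesh remains a single component")
  target <- vapply(comps, function(fs)
    sum(mesh$face_labels[fs] == region_label, na.rm = TRUE), 1L)
  frac <- target / lengths(comps)
  best <- which.max(frac + 1e-12 * target)  # prefer higher purity, then size
  excised_faces <- comps[[best]]
  remaining_faces <- sort(unlist(comps[-best], use.names = FALSE))
  excised <- submesh(mesh, excised_faces)
  remaining <- submesh(mesh, remaining_faces)
  n_lab <- sum(mesh$face_labels == region_label, na.rm = TRUE)
  n_in <- sum(mesh$face_labels[excised_faces] == region_label, na.rm = TRUE)
  report <- list(
    excised_face_count = length(excised_faces),
    label_purity = n_in / length(excised_faces),
    label_recall = n_in / n_lab,
    healthy_damage_count = sum(mesh$face_labels[excised_faces] != region_label,
                               na.rm = TRUE),
    n_components = length(comps))
  list(excised = excised, remaining = remaining,
       excised_faces = excised_faces, remaining_faces = remaining_faces,
       report = report)
}

#' Script an ideal cut along a label boundary
#'
#' Plans the sample sequence a perfectly accurate trainee would produce:
#' a closed loop of surface samples whose marked cut severs every edge
#' separating `region_label` faces from the rest (and nothing that would
#' strand a face). The planner walks the ordered boundary-edge cycle and
#' connects consecutive crossings by the cheapest safe route in the
#' face-adjacency graph: re-crossing an already-severed edge is free, and
#' severing the last free edge of any triangle is forbidden.
#'
#' @param mesh a labelled `trimesh`.
#' @param region_label the region to encircle.
#' @param topology optional precomputed topology.
#' @return data frame with columns `x, y, z, face` suitable for
#'   [mark_cut_path()].
#' @export
plan_boundary_cut <- function(mesh, region_label, topology = NULL) {
  if (is.null(topology)) topology <- build_edge_topology(mesh)
  lab <- mesh$face_labels
  if (is.null(lab)) stop("mesh has no face labels")
  ef <- topology$edge_faces
  interior <- which(!topology$boundary)
  is_b <- interior[lab[ef[interior, 1L]] != lab[ef[interior, 2L]] &
                     ((lab[ef[interior, 1L]] == region_label) |
                        (lab[ef[interior, 2L]] == region_label))]
  if (length(is_b) == 0L) stop("label has no boundary")
  bedges <- topology$edges[is_b, , drop = FALSE]
  cyc <- order_edge_cycle(bedges)
  border_ids <- is_b[cyc$order]
  inside <- ifelse(lab[ef[border_ids, 1L]] == region_label,
                   ef[border_ids, 1L], ef[border_ids, 2L])
  outside <- ifelse(lab[ef[border_ids, 1L]] == region_label,
                    ef[border_ids, 2L], ef[border_ids, 1L])
  nb <- length(border_ids)

  # dual-graph bookkeeping: every interior primal edge is one dual edge
  # between its two faces; boundary(label) edges start out "severed" because
  # every one of them will be crossed
  dual_pairs <- ef[interior, , drop = FALSE]
  dual_keys <- paste(topology$edges[interior, 1L], topology$edges[interior, 2L])
  m <- n_faces(mesh)
  severed <- logical(length(interior))
  severed[match(is_b, interior)] <- TRUE
  sev_count <- tabulate(c(dual_pairs[severed, 1L], dual_pairs[severed, 2L]),
                        nbins = m)

  safe_path <- function(from, to) {
    # cheapest walk from face to face; severed edges cost ~0, fresh edges 1,
    # edges that would strand a triangle are unusable
    usable <- severed | (sev_count[dual_pairs[, 1L]] <= 1L &
                           sev_count[dual_pairs[, 2L]] <= 1L)
    w <- ifelse(severed, 1e-6, 1)
    g <- igraph::graph_from_edgelist(dual_pairs[usable, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = from, to = to, weights = w[usable], output = "vpath"))
    as.integer(sp$vpath[[1L]])
  }
  commit <- function(walk) {
    if (length(walk) < 2L) return(invisible())
    for (s in seq_len(length(walk) - 1L)) {
      e <- shared_edge(mesh, walk[s], walk[s + 1L])
      idx <- match(paste(e[1L], e[2L]), dual_keys)
      if (!severed[idx]) {
        severed[idx] <<- TRUE
        sev_count[dual_pairs[idx, 1L]] <<- sev_count[dual_pairs[idx, 1L]] + 1L
        sev_count[dual_pairs[idx, 2L]] <<- sev_count[dual_pairs[idx, 2L]] + 1L
      }
    }
    invisible()
  }

  seq_faces <- inside[1L]
  cur <- inside[1L]
  for (k in seq_len(nb)) {
    # reach one face of e_k, then step across it (free: pre-severed)
    pa <- safe_path(cur, inside[k])
    pb <- safe_path(cur, outside[k])
    la <- if (length(pa) && pa[length(pa)] == inside[k]) length(pa) else Inf
    lb <- if (length(pb) && pb[length(pb)] == outside[k]) length(pb) else Inf
    if (!is.finite(la) && !is.finite(lb))
      stop(sprintf("boundary cut planner: no safe route to boundary edge %d", k))
    walk <- if (la <= lb) c(pa, outside[k]) else c(pb, inside[k])
    commit(walk)
    for (f in walk) seq_faces <- append_face(seq_faces, f)
    cur <- seq_faces[length(seq_faces)]
  }
  back <- safe_path(cur, inside[1L])
  if (length(back) == 0L || back[length(back)] != inside[1L])
    stop("boundary cut planner: no safe route back to the starting face")
  commit(back)
  for (f in back) seq_faces <- append_face(seq_faces, f)

  # planner guarantee: the implied severed set must separate cleanly
  crossed <- t(vapply(seq_len(length(seq_faces) - 1L),
                      function(s) shared_edge(mesh, seq_faces[s], seq_faces[s + 1L]),
                      integer(2L)))
  crossed <- crossed[!duplicated(paste(crossed[, 1L], crossed[, 2L])), , drop = FALSE]
  comps <- connected_components(mesh, drop_edges = crossed)
  if (length(comps) != 2L)
    stop(sprintf("boundary cut plan yields %d components; label boundary too convoluted",
                 length(comps)))
  cen <- (mesh$vertices[mesh$faces[, 1L], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2L], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3L], , drop = FALSE]) / 3
  data.frame(x = cen[seq_faces, 1L], y = cen[seq_faces, 2L],
             z = cen[seq_faces, 3L], face = seq_faces)
}

append_face <- function(seq_faces, f) {
  if (length(seq_faces) > 0L && seq_faces[length(seq_faces)] == f) seq_faces
  else c(seq_faces, f)
}

face_edge_keys <- function(mesh) {
  f <- mesh$faces
  cbind(paste(pmin(f[, 1L], f[, 2L]), pmax(f[, 1L], f[, 2L])),
        paste(pmin(f[, 2L], f[, 3L]), pmax(f[, 2L], f[, 3L])),
        paste(pmin(f[, 1L], f[, 3L]), pmax(f[, 1L], f[, 3L])))
}

faces_adjacent <- function(mesh, fa, fb) {
  length(intersect(mesh$faces[fa, ], mesh$faces[fb, ])) == 2L
}

# order an edge set (rows i<j) into a single closed vertex cycle; errors if
# the set is not a simple cycle
order_edge_cycle <- function(edges) {
  verts <- sort(unique(as.integer(edges)))
  deg <- tabulate(match(as.integer(edges), verts))
  if (any(deg != 2L))
    stop("boundary edges do not form a simple cycle (vertex degree != 2)")
  n <- nrow(edges)
  used <- rep(FALSE, n)
  order_out <- integer(n)
  cur_e <- 1L
  cur_v <- edges[1L, 2L]
  order_out[1L] <- 1L
  used[1L] <- TRUE
  for (k in 2L:n) {
    cand <- which(!used & (edges[, 1L] == cur_v | edges[, 2L] == cur_v))
    if (length(cand) == 0L)
      stop("boundary edges form more than one cycle")
    nxt <- cand[1L]
    order_out[k] <- nxt
    used[nxt] <- TRUE
    cur_v <- if (edges[nxt, 1L] == cur_v) edges[nxt, 2L] else edges[nxt, 1L]
  }
  if (cur_v != edges[1L, 1L]) stop("boundary edge cycle does not close")
  list(order = order_out)
}
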